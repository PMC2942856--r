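# Classical comparator scores.
#
# Both comparators are likelihood-ratio tests of logistic models that are
# saturated on a genotype-class partition, so the maximised log-likelihood
# has a closed form: the fitted case probability of a class is its observed
# case fraction, and empty classes or zero cells contribute nothing under
# the 0 * log 0 = 0 convention. Degrees of freedom are fixed at the nominal
# model dimension (2 for the three-parameter single-locus model, 3 for the
# four-parameter dominant-coded interaction model) even when empty classes
# reduce the effective dimension, reproducing the standard practice this
# score is meant to represent.

# saturated Bernoulli log-likelihood of case/control cell counts
.sat_ll <- function(n1, n0) {
  n <- n1 + n0
  t1 <- ifelse(n1 > 0, n1 * log(n1 / n), 0)
  t0 <- ifelse(n0 > 0, n0 * log(n0 / n), 0)
  sum(t1 + t0)
}

.lrt_result <- function(lambda, df, partner = NA_integer_) {
  lambda <- max(lambda, 0) # guard tiny negative rounding
  p <- stats::pchisq(lambda, df, lower.tail = FALSE)
  structure(list(statistic = lambda, df = df, p_value = p,
                 score = -log10(p), partner = partner),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: Lambda = %.4f (df = %d), p = %.3g, score = %.3f\n",
              x$statistic, x$df, x$p_value, x$score))
  invisible(x)
}

#' Marginal single-locus likelihood-ratio test
#'
#' Compares the full three-parameter logistic model (one intercept per
#' genotype class 0/1/2) against the intercept-only null; the statistic is
#' referred to a chi-square distribution with 2 degrees of freedom and the
#' score is `-log10(p)`.
#'
#' @param table a [genotype_table()] with phenotype.
#' @param j locus index; `NULL` (default) tests every locus.
#' @return an `lrt_result` for one locus, or a data.frame with columns
#'   `locus`, `statistic`, `p_value`, `score` for all loci.
#' @export
marginal_lrt <- function(table, j = NULL) {
  Z <- table$genotypes; y <- table$phenotype
  if (is.null(y)) stop_bad("table has no phenotype")
  case <- y == 1L
  ll0 <- .sat_ll(sum(case), sum(!case))
  one <- function(jj) {
    n1 <- tabulate(Z[case, jj] + 1L, 3L)
    n0 <- tabulate(Z[!case, jj] + 1L, 3L)
    2 * (.sat_ll(n1, n0) - ll0)
  }
  if (!is.null(j)) return(.lrt_result(one(j), 2L))
  lam <- vapply(seq_len(ncol(Z)), one, numeric(1))
  p <- stats::pchisq(pmax(lam, 0), 2L, lower.tail = FALSE)
  data.frame(locus = seq_len(ncol(Z)), statistic = pmax(lam, 0),
             p_value = p, score = -log10(p))
}

# all-pairs dominant-coded 2x2 interaction LRT statistics (L x L, NA diag)
.gxg_lambda_matrix <- function(Z, y) {
  case <- y == 1L
  D <- matrix(0, nrow(Z), ncol(Z)); D[Z > 0L] <- 1
  Dc <- D[case, , drop = FALSE]; Du <- D[!case, , drop = FALSE]
  n1 <- sum(case); n0 <- sum(!case)
  # cell counts (carrier_j, carrier_k) for all pairs at once
  dd1 <- crossprod(Dc); dd0 <- crossprod(Du)
  cj1 <- matrix(colSums(Dc), ncol(Z), ncol(Z))            # carriers at j
  ck1 <- t(cj1)
  cj0 <- matrix(colSums(Du), ncol(Z), ncol(Z)); ck0 <- t(cj0)
  cell <- function(x1, x0) {
    n <- x1 + x0
    ifelse(x1 > 0, x1 * log(x1 / n), 0) + ifelse(x0 > 0, x0 * log(x0 / n), 0)
  }
  ll_sat <- cell(dd1, dd0) +
    cell(cj1 - dd1, cj0 - dd0) +        # j carrier, k non-carrier
    cell(ck1 - dd1, ck0 - dd0) +        # k carrier, j non-carrier
    cell(n1 - cj1 - ck1 + dd1, n0 - cj0 - ck0 + dd0)
  lam <- 2 * (ll_sat - .sat_ll(n1, n0))
  lam[lam < 0] <- 0
  diag(lam) <- NA_real_
  lam
}

#' Pairwise gene-gene interaction likelihood-ratio score
#'
#' For each partner k != j, the four-parameter dominant-coded logistic model
#' `b0 + b1 I(Zj>0) + b2 I(Zk>0) + b3 I(Zj>0 and Zk>0)` is compared to the
#' null; the statistic is referred to chi-square with 3 degrees of freedom
#' and the per-locus score is the maximum of `-log10(p)` over partners (the
#' arg-max partner is reported).
#'
#' @param table a [genotype_table()] with phenotype and L >= 2.
#' @param j locus index; `NULL` (default) scores every locus.
#' @return an `lrt_result` (with `partner`) for one locus, or a data.frame
#'   with columns `locus`, `statistic`, `p_value`, `score`, `partner`.
#' @export
gxg_lrt_score <- function(table, j = NULL) {
  Z <- table$genotypes; y <- table$phenotype
  if (is.null(y)) stop_bad("table has no phenotype")
  if (ncol(Z) < 2L) stop_bad("need at least two loci")
  lam <- .gxg_lambda_matrix(Z, y)
  one <- function(jj) {
    k <- which.max(lam[jj, ])
    .lrt_result(lam[jj, k], 3L, partner = k)
  }
  if (!is.null(j)) return(one(j))
  res <- lapply(seq_len(ncol(Z)), one)
  data.frame(locus = seq_len(ncol(Z)),
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             score = vapply(res, `[[`, numeric(1), "score"),
             partner = vapply(res, `[[`, integer(1), "partner"))
}
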