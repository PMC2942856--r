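# Closed-form Bayesian scores.
#
# Under a combined model the phenotype likelihood factorises over partition
# classes as independent Bernoulli samples with class-specific disease
# probabilities p_c ~ beta(alpha, alpha). Integrating the p_c out gives the
# marginal likelihood as a product over classes of beta-binomial predictive
# terms:
#   P(Data | M) = prod_c  Gamma(2a)/Gamma(2a + |s_c|)
#                         * prod_b Gamma(a + n_cb)/Gamma(a)
# where n_cb counts individuals in class c with phenotype b. Everything is
# kept in natural-log space (the product underflows around N ~ 1700).
# The structure prior P(M) is proportional to xi^L_M, with L_M the number of
# SNPs in the model; only ratios are ever used, so the normalising constant
# is never computed.

#' Prior specification for the Bayesian association model
#'
#' @param alpha beta hyperparameter of the symmetric `beta(alpha, alpha)`
#'   prior on each class disease probability; the default 3 weights
#'   probabilities towards 0.5, appropriate for balanced case-control data.
#' @param xi structure parameter in (0,1): per-SNP geometric penalty of the
#'   model prior. A value around 1/L is recommended (1/460 at the package's
#'   replicate scale, 1/1000 at chromosome scale).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(alpha = 3, xi = 1 / 460) {
  if (!is.numeric(alpha) || alpha <= 0) stop_bad("alpha must be > 0")
  if (!is.numeric(xi) || xi <= 0 || xi >= 1) stop_bad("xi must lie in (0, 1)")
  structure(list(alpha = alpha, xi = xi), class = "prior_spec")
}

#' Per-class case/control counts of a partition
#'
#' @param partition a partition as returned by [model_partition()].
#' @param phenotype binary vector (1 = case).
#' @return list with integer vectors `n1` (cases) and `n0` (controls), one
#'   entry per structural class; empty classes carry zeros.
#' @export
class_counts <- function(partition, phenotype) {
  if (length(partition$class_of) != length(phenotype))
    stop_bad("partition and phenotype lengths differ")
  d <- partition$n_classes
  lab <- partition$class_of + 1L
  list(n1 = tabulate(lab[phenotype == 1L], nbins = d),
       n0 = tabulate(lab[phenotype == 0L], nbins = d))
}

# vectorised log beta-binomial class term; 0 for an empty class, so empty
# structural classes drop out of the log product automatically.
.bb_term <- function(n1, n0, alpha) {
  lgamma(2 * alpha) - lgamma(2 * alpha + n1 + n0) +
    lgamma(alpha + n1) + lgamma(alpha + n0) - 2 * lgamma(alpha)
}

#' Log marginal likelihood of class counts
#'
#' Natural log of the product over classes of beta-binomial predictive
#' probabilities under `p_c ~ beta(alpha, alpha)`. Invariant to class
#' relabeling and to empty classes.
#'
#' @param counts a [class_counts()] result (or any list with `n1`, `n0`).
#' @param alpha beta hyperparameter, > 0.
#' @return a numeric scalar.
#' @export
log_marginal_likelihood <- function(counts, alpha) {
  if (!is.numeric(alpha) || alpha <= 0) stop_bad("alpha must be > 0")
  sum(.bb_term(counts$n1, counts$n0, alpha))
}

#' Log structure prior of a combined model (unnormalised)
#'
#' `L_M * log(xi)`, where `L_M` is the number of SNPs in the model. The
#' normalising constant cancels in every posterior ratio and in the
#' self-normalised model average, so it is never computed.
#'
#' @param model a [combined_model()] (or an integer SNP count).
#' @param xi structure parameter in (0,1).
#' @return a numeric scalar.
#' @export
log_prior <- function(model, xi) {
  if (!is.numeric(xi) || xi <= 0 || xi >= 1) stop_bad("xi must lie in (0, 1)")
  n_loci <- if (inherits(model, "combined_model")) model$n_loci
            else as.integer(model)
  n_loci * log(xi)
}

#' Score a combined model on a data set
#'
#' @param model a [combined_model()].
#' @param table a [genotype_table()] with phenotype.
#' @param prior a [prior_spec()].
#' @return list with `log_ml`, `log_prior` and their sum `log_post`
#'   (the unnormalised log posterior).
#' @export
score_model <- function(model, table, prior) {
  cc <- class_counts(model_partition(model, table), table$phenotype)
  lml <- log_marginal_likelihood(cc, prior$alpha)
  lpr <- log_prior(model, prior$xi)
  list(log_ml = lml, log_prior = lpr, log_post = lml + lpr)
}

# ---- all-pairs / all-singles elementary marginal likelihoods -------------
#
# The workhorse behind top-K selection and the pairwise Bayes-factor score.
# Nine genotype-pair count matrices per phenotype group are obtained with
# crossproducts of 0/1 indicator matrices, then every two-locus model kind
# is scored elementwise on L x L matrices. Column-blocked to bound memory on
# long sequences.

.single_locus_logml <- function(Z, y, alpha) {
  case <- y == 1L
  n1 <- sapply(0:2, function(a) colSums(Z[case, , drop = FALSE] == a))
  n0 <- sapply(0:2, function(a) colSums(Z[!case, , drop = FALSE] == a))
  if (is.null(dim(n1))) { n1 <- matrix(n1, 1L); n0 <- matrix(n0, 1L) }
  m1 <- rowSums(.bb_term(n1, n0, alpha))
  m2 <- .bb_term(n1[, 1L], n0[, 1L], alpha) +
        .bb_term(n1[, 2L] + n1[, 3L], n0[, 2L] + n0[, 3L], alpha)
  list(m1 = m1, m2 = m2)
}

.pairwise_logml <- function(Z, y, alpha, block = 1024L) {
  L <- ncol(Z)
  case <- y == 1L
  I <- lapply(0:2, function(a) {
    M <- matrix(0, nrow(Z), L); M[Z == a] <- 1; M
  })
  Ic <- lapply(I, function(M) M[case, , drop = FALSE])
  Iu <- lapply(I, function(M) M[!case, , drop = FALSE])
  m3 <- matrix(NA_real_, L, L); m4 <- m3; m5 <- m3
  Ncase <- sum(case); Nctrl <- sum(!case)
  for (start in seq(1L, L, by = block)) {
    cols <- start:min(start + block - 1L, L)
    C1 <- vector("list", 9L); C0 <- vector("list", 9L)
    for (a in 1:3) for (b in 1:3) {
      idx <- (a - 1L) * 3L + b
      C1[[idx]] <- crossprod(Ic[[a]], Ic[[b]][, cols, drop = FALSE])
      C0[[idx]] <- crossprod(Iu[[a]], Iu[[b]][, cols, drop = FALSE])
    }
    s3 <- 0
    for (idx in 1:9) s3 <- s3 + .bb_term(C1[[idx]], C0[[idx]], alpha)
    m3[, cols] <- s3
    # dominant 2x2 collapse: cells (0,0), (0,d), (d,0), (d,d)
    dd1 <- C1[[5L]] + C1[[6L]] + C1[[8L]] + C1[[9L]]
    dd0 <- C0[[5L]] + C0[[6L]] + C0[[8L]] + C0[[9L]]
    m4[, cols] <- .bb_term(C1[[1L]], C0[[1L]], alpha) +
      .bb_term(C1[[2L]] + C1[[3L]], C0[[2L]] + C0[[3L]], alpha) +
      .bb_term(C1[[4L]] + C1[[7L]], C0[[4L]] + C0[[7L]], alpha) +
      .bb_term(dd1, dd0, alpha)
    m5[, cols] <- .bb_term(dd1, dd0, alpha) +
      .bb_term(Ncase - dd1, Nctrl - dd0, alpha)
  }
  diag(m3) <- NA_real_; diag(m4) <- NA_real_; diag(m5) <- NA_real_
  list(m3 = m3, m4 = m4, m5 = m5)
}

#' Marginal likelihoods of every elementary model
#'
#' Scores all 2L single-locus and 3 C(L,2) two-locus elementary models in
#' one vectorised pass.
#'
#' @param table a [genotype_table()] with phenotype.
#' @param alpha beta hyperparameter.
#' @param block column block size bounding memory for long sequences.
#' @return list with vectors `m1`, `m2` (length L) and symmetric L x L
#'   matrices `m3`, `m4`, `m5` (diagonal `NA`) of log marginal likelihoods,
#'   plus `m0`, the null-model log marginal likelihood.
#' @export
elementary_logml <- function(table, alpha = 3, block = 1024L) {
  Z <- table$genotypes; y <- table$phenotype
  if (is.null(y)) stop_bad("table has no phenotype")
  singles <- .single_locus_logml(Z, y, alpha)
  pairs <- if (ncol(Z) >= 2L) .pairwise_logml(Z, y, alpha, block)
           else list(m3 = NULL, m4 = NULL, m5 = NULL)
  m0 <- .bb_term(sum(y == 1L), sum(y == 0L), alpha)
  c(singles, pairs, list(m0 = m0))
}

#' Pairwise gene-gene Bayes-factor score of one locus
#'
#' For each partner k != j the data probability under "association at
#' (j, k)" is the equally weighted mixture (1/3 each) of the marginal
#' likelihoods of the three two-locus elementary models M3, M4, M5 at
#' (j, k); the score is the log Bayes factor of the best partner against
#' the null model. `mixture = "max"` replaces the average by the maximum
#' over the three model kinds.
#'
#' @param table a [genotype_table()] with phenotype and L >= 2.
#' @param j locus index; `NULL` (default) scores every locus.
#' @param alpha beta hyperparameter.
#' @param mixture `"average"` (default) or `"max"`.
#' @param logml optional precomputed [elementary_logml()] result.
#' @return if `j` is given, a list with `score` and `partner`; otherwise a
#'   data.frame with columns `locus`, `score`, `partner`.
#' @export
gxg_bayes_factor_score <- function(table, j = NULL, alpha = 3,
                                   mixture = c("average", "max"),
                                   logml = NULL) {
  mixture <- match.arg(mixture)
  if (ncol(table$genotypes) < 2L) stop_bad("need at least two loci")
  if (is.null(logml)) logml <- elementary_logml(table, alpha)
  stack <- array(c(logml$m3, logml$m4, logml$m5),
                 dim = c(dim(logml$m3), 3L))
  mix <- if (mixture == "average") {
    m <- pmax(stack[, , 1L], stack[, , 2L], stack[, , 3L])
    m + log(exp(stack[, , 1L] - m) + exp(stack[, , 2L] - m) +
              exp(stack[, , 3L] - m)) - log(3)
  } else pmax(stack[, , 1L], stack[, , 2L], stack[, , 3L])
  bf <- mix - logml$m0
  one <- function(jj) {
    row <- bf[jj, ]
    k <- which.max(row) # NA diagonal never wins
    list(score = row[k], partner = k)
  }
  if (!is.null(j)) return(one(j))
  res <- lapply(seq_len(nrow(bf)), one)
  data.frame(locus = seq_len(nrow(bf)),
             score = vapply(res, `[[`, numeric(1), "score"),
             partner = vapply(res, `[[`, integer(1), "partner"))
}
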