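# Four-step model-averaging learner:
#   1. score every elementary model in closed form;
#   2. keep the K best plus all single-locus models (the pool Me1);
#   3. run a non-reversible Metropolis-Hastings search over conflict-free
#      combinations of pool models, starting from the empty model, with
#      operators ADD / REMOVE / SWITCH at probabilities (0.5, 0.45, 0.05)
#      and acceptance min{1, post(M*)/post(M)} (no proposal-ratio term);
#   4. renormalise the exact unnormalised posteriors over the set M* of
#      distinct models visited and read off per-SNP inclusion posteriors.
#
# Because every visited model's score is exact, the estimator only needs M*
# to cover the non-negligible posterior mass; every state whose score is
# computed (current or proposed, accepted or not) is recorded in M*.

#' Search configuration
#'
#' @param K number of top-ranked elementary models retained in the pool.
#' @param n_iter number of search iterations.
#' @param operator_probs probabilities of the (add, remove, switch)
#'   operators; must sum to 1.
#' @param seed integer seed for the search RNG.
#' @param prior a [prior_spec()].
#' @param profile optional convenience preset: `"replicate"` sets
#'   K = 5000, n_iter = 200000; `"chromosome"` sets K = 50000,
#'   n_iter = 3500000 (explicit `K`/`n_iter` arguments win).
#' @return an object of class `search_config`.
#' @export
search_config <- function(K = 5000L, n_iter = 200000L,
                          operator_probs = c(0.5, 0.45, 0.05),
                          seed = 1L, prior = prior_spec(),
                          profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("replicate", "chromosome"))
    if (profile == "chromosome") {
      if (missing(K)) K <- 50000L
      if (missing(n_iter)) n_iter <- 3500000L
    }
  }
  if (abs(sum(operator_probs) - 1) > 1e-12 || length(operator_probs) != 3L)
    stop_bad("operator_probs must be 3 probabilities summing to 1")
  if (K < 1L || n_iter < 1L) stop_bad("K and n_iter must be >= 1")
  structure(list(K = as.integer(K), n_iter = as.integer(n_iter),
                 operator_probs = operator_probs, seed = as.integer(seed),
                 prior = prior),
            class = "search_config")
}

# pool representation: integer matrix with columns kind, l1, l2 (l2 = 0 for
# single-locus models), one row per elementary model.
.pool_matrix <- function(models) {
  t(vapply(models, function(e)
    c(e$kind, e$loci[1L], if (length(e$loci) == 2L) e$loci[2L] else 0L),
    integer(3)))
}

.pool_to_models <- function(pool) {
  lapply(seq_len(nrow(pool)), function(i) {
    loci <- pool[i, 2L:3L]
    elementary_model(pool[i, 1L], loci[loci > 0L])
  })
}

#' Select the top-K elementary models (the search pool)
#'
#' Ranks every elementary model by its unnormalised log posterior
#' (closed-form marginal likelihood plus structure prior), keeps the K best,
#' and always unions in all 2L single-locus models. Ties are broken by
#' canonical model order (kind, then loci), so the pool is deterministic.
#'
#' @param table a [genotype_table()] with phenotype and L >= 2.
#' @param config a [search_config()].
#' @param logml optional precomputed [elementary_logml()] result.
#' @return integer matrix (columns `kind`, `l1`, `l2`) with attribute
#'   `log_post` giving each pool model's unnormalised log posterior.
#' @export
select_top_k <- function(table, config = search_config(), logml = NULL) {
  L <- ncol(table$genotypes)
  if (L < 2L) stop_bad("need at least two loci")
  prior <- config$prior
  if (is.null(logml)) logml <- elementary_logml(table, prior$alpha)
  lp1 <- log(prior$xi); lp2 <- 2 * log(prior$xi)
  ut <- which(upper.tri(logml$m3), arr.ind = TRUE) # j < k
  cand <- rbind(
    cbind(1L, seq_len(L), 0L), cbind(2L, seq_len(L), 0L),
    cbind(3L, ut[, 1L], ut[, 2L]),
    cbind(4L, ut[, 1L], ut[, 2L]),
    cbind(5L, ut[, 1L], ut[, 2L]))
  score <- c(logml$m1 + lp1, logml$m2 + lp1,
             logml$m3[ut] + lp2, logml$m4[ut] + lp2, logml$m5[ut] + lp2)
  ord <- order(-score, cand[, 1L], cand[, 2L], cand[, 3L])
  keep <- ord[seq_len(min(config$K, length(ord)))]
  keep <- union(keep, which(cand[, 1L] %in% 1:2)) # all single-locus models
  pool <- cand[keep, , drop = FALSE]
  colnames(pool) <- c("kind", "l1", "l2")
  attr(pool, "log_post") <- score[keep]
  pool
}

# per-pool-row canonical tokens and expanded component codes, precomputed so
# the search loop only concatenates and sorts small vectors.
.pool_prep <- function(pool) {
  P <- nrow(pool)
  tok <- vector("list", P); srt <- vector("list", P); cmp <- vector("list", P)
  for (i in seq_len(P)) {
    k <- pool[i, 1L]; a <- pool[i, 2L]; b <- pool[i, 3L]
    if (k == 1L || k == 2L) {
      tok[[i]] <- sprintf("M%d(%d)", k, a); srt[[i]] <- a + k / 10
      cmp[[i]] <- matrix(c(k, a, 0L), 1L)
    } else if (k == 3L) {
      tok[[i]] <- c(sprintf("M1(%d)", a), sprintf("M1(%d)", b))
      srt[[i]] <- c(a + 0.1, b + 0.1)
      cmp[[i]] <- rbind(c(1L, a, 0L), c(1L, b, 0L))
    } else if (k == 4L) {
      tok[[i]] <- c(sprintf("M2(%d)", a), sprintf("M2(%d)", b))
      srt[[i]] <- c(a + 0.2, b + 0.2)
      cmp[[i]] <- rbind(c(2L, a, 0L), c(2L, b, 0L))
    } else {
      tok[[i]] <- sprintf("M5(%d,%d)", a, b); srt[[i]] <- a + 0.5
      cmp[[i]] <- matrix(c(5L, a, b), 1L)
    }
  }
  loci <- lapply(seq_len(P), function(i) {
    l <- pool[i, 2L:3L]; l[l > 0L]
  })
  list(tok = tok, srt = srt, cmp = cmp, loci = loci)
}

#' Non-reversible stochastic search over combined models
#'
#' Starts from the empty model M0. At each iteration one operator is drawn:
#' ADD inserts a uniformly chosen pool model, first deleting all components
#' sharing a locus with it; REMOVE deletes a uniformly chosen component
#' (a self-loop proposal when the state is M0); SWITCH is REMOVE then ADD.
#' A proposal is accepted with probability `min{1, exp(lp* - lp)}` where
#' `lp` is the cached unnormalised log posterior. Every state whose score is
#' evaluated is recorded in the visited set, keyed by its canonical model.
#'
#' @param table a [genotype_table()] with phenotype.
#' @param pool a pool matrix from [select_top_k()] (or a list of
#'   [elementary_model()]s).
#' @param config a [search_config()].
#' @return an object of class `scored_model_set`: list with `models` (one
#'   entry per distinct visited model: `key`, `loci`, `n_loci`, `log_ml`,
#'   `log_prior`, `log_post`, `components`), `trace` (current log posterior
#'   per iteration), `accept_rate`, `n_iter` and `L`.
#' @export
run_search <- function(table, pool, config = search_config()) {
  if (is.list(pool) && !is.matrix(pool)) pool <- .pool_matrix(pool)
  if (nrow(pool) == 0L) stop_bad("empty model pool")
  Z <- table$genotypes; y <- table$phenotype
  if (is.null(y)) stop_bad("table has no phenotype")
  case <- y == 1L
  D <- Z > 0L; storage.mode(D) <- "integer"
  alpha <- config$prior$alpha; lxi <- log(config$prior$xi)
  prep <- .pool_prep(pool)
  P <- nrow(pool)

  score_state <- function(rows) {
    # canonical key
    if (length(rows) == 0L) {
      key <- "M0"
    } else {
      tk <- unlist(prep$tok[rows]); sk <- unlist(prep$srt[rows])
      key <- paste(tk[order(sk)], collapse = "+")
    }
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    lab <- integer(nrow(Z)); d <- 1L; n_loci <- 0L
    for (r in rows) {
      cm <- prep$cmp[[r]]
      for (ci in seq_len(nrow(cm))) {
        cls <- switch(cm[ci, 1L],
                      Z[, cm[ci, 2L]],
                      D[, cm[ci, 2L]],
                      NULL, NULL,
                      D[, cm[ci, 2L]] * D[, cm[ci, 3L]])
        dc <- if (cm[ci, 1L] == 1L) 3L else 2L
        lab <- lab * dc + cls
        d <- d * dc
      }
      n_loci <- n_loci + length(prep$loci[[r]])
    }
    n1 <- tabulate(lab[case] + 1L, nbins = d)
    n0 <- tabulate(lab[!case] + 1L, nbins = d)
    lml <- sum(.bb_term(n1, n0, alpha))
    ent <- list(key = key, rows = rows,
                loci = if (n_loci) sort(unlist(prep$loci[rows])) else integer(0),
                n_loci = n_loci, log_ml = lml, log_prior = n_loci * lxi,
                log_post = lml + n_loci * lxi)
    assign(key, ent, envir = cache)
    ent
  }

  cache <- new.env(parent = emptyenv())
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(config$seed)

  state <- integer(0)
  cur <- score_state(state)
  n_iter <- config$n_iter
  trace <- numeric(n_iter)
  ops <- sample.int(3L, n_iter, replace = TRUE, prob = config$operator_probs)
  u_acc <- stats::runif(n_iter)
  n_accept <- 0L

  propose_add <- function(st) {
    new <- sample.int(P, 1L)
    nl <- prep$loci[[new]]
    if (length(st)) {
      conflict <- vapply(st, function(r) any(prep$loci[[r]] %in% nl),
                         logical(1))
      st <- st[!conflict]
    }
    c(st, new)
  }
  propose_remove <- function(st) {
    if (length(st) == 0L) return(st) # self-loop on M0
    st[-sample.int(length(st), 1L)]
  }

  for (it in seq_len(n_iter)) {
    prop_state <- switch(ops[it],
                         propose_add(state),
                         propose_remove(state),
                         propose_add(propose_remove(state)))
    prop <- score_state(prop_state)
    if (u_acc[it] < exp(prop$log_post - cur$log_post)) {
      state <- prop_state
      cur <- prop
      n_accept <- n_accept + 1L
    }
    trace[it] <- cur$log_post
  }

  models <- as.list(cache)
  models <- models[order(names(models))]
  structure(list(models = unname(models), trace = trace,
                 accept_rate = n_accept / n_iter, n_iter = n_iter,
                 L = ncol(Z)),
            class = "scored_model_set")
}

#' @export
print.scored_model_set <- function(x, ...) {
  cat(sprintf("scored_model_set: %d distinct models from %d iterations (accept rate %.2f)\n",
              length(x$models), x$n_iter, x$accept_rate))
  invisible(x)
}

#' Per-SNP inclusion posteriors from a visited-model set
#'
#' Self-normalises the exact unnormalised posteriors over the distinct
#' visited models; the inclusion posterior of locus j is the posterior mass
#' of models containing j, and the BMA score is the log posterior odds
#' `log(p / (1 - p))`. Loci contained in no visited model are flagged
#' `visited = FALSE` and given probability 0 and score `-Inf`.
#'
#' @param visited a `scored_model_set` from [run_search()] (or any list of
#'   model entries with `loci` and `log_post`), or a list with those fields.
#' @param L number of loci (taken from `visited$L` when present).
#' @return data.frame with columns `locus`, `p_incl`, `s_bma`, `visited`.
#' @export
snp_posteriors <- function(visited, L = visited$L) {
  models <- if (inherits(visited, "scored_model_set")) visited$models
            else visited
  if (length(models) == 0L) stop_bad("empty visited-model set")
  lp <- vapply(models, `[[`, numeric(1), "log_post")
  p <- numeric(L); s <- rep(-Inf, L); seen <- logical(L)
  locs <- lapply(models, `[[`, "loci")
  by_locus <- vector("list", L)
  for (m in seq_along(models)) for (j in locs[[m]])
    by_locus[[j]] <- c(by_locus[[j]], m)
  denom <- logsumexp(lp)
  for (j in seq_len(L)) {
    idx <- by_locus[[j]]
    if (is.null(idx)) next
    seen[j] <- TRUE
    lin <- logsumexp(lp[idx])
    lout <- logsumexp(lp[-idx])
    p[j] <- exp(lin - denom)
    s[j] <- lin - lout # log posterior odds, stable even for p near 0 or 1
  }
  data.frame(locus = seq_len(L), p_incl = p, s_bma = s, visited = seen)
}

#' Naive elementary-only model averaging
#'
#' The inclusion posterior computed over `{M0} union pool`, each pool model
#' standing alone as a one-component combined model, with no search over
#' combinations. Provided as the degraded baseline that motivates combined
#' models: when two true interactions compete, single-interaction averaging
#' assigns almost all mass to the stronger one.
#'
#' @param table a [genotype_table()] with phenotype.
#' @param pool a pool matrix from [select_top_k()] or list of
#'   [elementary_model()]s.
#' @param prior a [prior_spec()].
#' @return data.frame as in [snp_posteriors()].
#' @export
naive_bma <- function(table, pool, prior = prior_spec()) {
  if (is.list(pool) && !is.matrix(pool)) pool <- .pool_matrix(pool)
  prep <- .pool_prep(pool)
  models <- vector("list", nrow(pool) + 1L)
  models[[1L]] <- list(key = "M0", loci = integer(0), n_loci = 0L,
                       log_post = .null_log_post(table, prior))
  for (i in seq_len(nrow(pool))) {
    loci <- prep$loci[[i]]
    em <- elementary_model(pool[i, 1L], loci)
    sc <- score_model(combined_model(list(em)), table, prior)
    models[[i + 1L]] <- list(key = canonical_key(combined_model(list(em))),
                             loci = sort(loci), n_loci = length(loci),
                             log_ml = sc$log_ml, log_prior = sc$log_prior,
                             log_post = sc$log_post)
  }
  # distinct models only: M3(j,k) and a hypothetical duplicate share a key
  keys <- vapply(models, `[[`, character(1), "key")
  models <- models[!duplicated(keys)]
  snp_posteriors(models, L = ncol(table$genotypes))
}

.null_log_post <- function(table, prior) {
  y <- table$phenotype
  .bb_term(sum(y == 1L), sum(y == 0L), prior$alpha)
}

#' Full BMA association scan
#'
#' The end-to-end learner: elementary scoring, top-K pool selection,
#' stochastic search, and per-SNP inclusion posteriors.
#'
#' @param table a [genotype_table()] with phenotype.
#' @param config a [search_config()].
#' @return list with `posteriors` (data.frame from [snp_posteriors()]),
#'   `visited` (the `scored_model_set`), `pool`, and `map_model` (the
#'   highest-posterior visited model's key).
#' @export
bma_scan <- function(table, config = search_config()) {
  logml <- elementary_logml(table, config$prior$alpha)
  pool <- select_top_k(table, config, logml = logml)
  visited <- run_search(table, pool, config)
  post <- snp_posteriors(visited)
  post$locus_id <- table$locus_ids
  lp <- vapply(visited$models, `[[`, numeric(1), "log_post")
  list(posteriors = post, visited = visited, pool = pool,
       map_model = visited$models[[which.max(lp)]]$key)
}
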