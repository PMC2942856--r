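test_that("top-K selection agrees with brute-force ranking and is saturating", {
  tab <- rand_table(100, 3, seed = 17)
  prior <- prior_spec(alpha = 3, xi = 1 / 3)
  cfg <- search_config(K = 2, prior = prior)

  all_models <- enumerate_elementary(3L)
  brute <- vapply(all_models, function(em)
    score_model(combined_model(list(em)), tab, prior)$log_post, numeric(1))
  kinds <- vapply(all_models, `[[`, integer(1), "kind")
  l1 <- vapply(all_models, function(e) e$loci[1], integer(1))
  l2 <- vapply(all_models, function(e) e$loci[length(e$loci)], integer(1))
  ord <- order(-brute, kinds, l1, l2)
  expected_rows <- union(ord[1:2], which(kinds <= 2L))

  pool <- select_top_k(tab, cfg)
  key_of <- function(k, a, b) sprintf("%d_%d_%d", k, a, b)
  got_keys <- sort(key_of(pool[, 1], pool[, 2], pool[, 3]))
  exp_keys <- sort(key_of(kinds[expected_rows], l1[expected_rows],
                          ifelse(kinds[expected_rows] <= 2L, 0L, l2[expected_rows])))
  expect_identical(got_keys, exp_keys)
  expect_equal(sort(attr(pool, "log_post")), sort(brute[expected_rows]))

  # saturation: K >= |Me| returns every elementary model
  pool_all <- select_top_k(tab, search_config(K = 100, prior = prior))
  expect_identical(nrow(pool_all), 15L)

  # deterministic ordering across repeated calls
  expect_identical(pool, select_top_k(tab, cfg))
})

test_that("the search is reproducible and never occupies a conflicting state", {
  tab <- rand_table(120, 4, seed = 23)
  cfg <- search_config(K = 20, n_iter = 3000, seed = 99,
                       prior = prior_spec(3, 1 / 4))
  pool <- select_top_k(tab, cfg)
  res1 <- run_search(tab, pool, cfg)
  res2 <- run_search(tab, pool, cfg)
  expect_identical(res1$trace, res2$trace)
  expect_identical(vapply(res1$models, `[[`, character(1), "key"),
                   vapply(res2$models, `[[`, character(1), "key"))

  # every visited model is conflict-free (no locus twice) and its cached
  # score equals a fresh recomputation
  prior <- cfg$prior
  for (m in res1$models) {
    expect_false(anyDuplicated(m$loci) > 0)
    cm <- parse_model(m$key)
    sc <- score_model(cm, tab, prior)
    expect_equal(m$log_ml, sc$log_ml)
    expect_equal(m$log_post, sc$log_post)
    expect_identical(m$n_loci, cm$n_loci)
  }
  # M0 (the initial state) is always part of the visited set
  expect_true("M0" %in% vapply(res1$models, `[[`, character(1), "key"))
})

test_that("inclusion posteriors renormalise exactly over the visited set", {
  # only the null model visited: no locus is ever included
  m0 <- list(list(key = "M0", loci = integer(0), log_post = -10))
  p <- snp_posteriors(m0, L = 3)
  expect_identical(p$p_incl, c(0, 0, 0))
  expect_identical(p$s_bma, rep(-Inf, 3))
  expect_false(any(p$visited))

  # equal unnormalised posteriors for M0 and M2(1): probability 1/2, odds 0
  two <- list(list(key = "M0", loci = integer(0), log_post = -5),
              list(key = "M2(1)", loci = 1L, log_post = -5))
  p2 <- snp_posteriors(two, L = 2)
  expect_equal(p2$p_incl[1], 0.5)
  expect_equal(p2$s_bma[1], 0)
  expect_identical(p2$p_incl[2], 0)

  # random sets: matches brute-force linear-space summation
  set.seed(6)
  for (rep in 1:5) {
    n <- 12L
    ms <- lapply(seq_len(n), function(i)
      list(key = as.character(i),
           loci = sort(sample(1:5, sample(0:3, 1))),
           log_post = runif(1, -30, -10)))
    p <- snp_posteriors(ms, L = 5)
    w <- exp(vapply(ms, `[[`, numeric(1), "log_post"))
    for (j in 1:5) {
      has <- vapply(ms, function(m) j %in% m$loci, logical(1))
      expect_equal(p$p_incl[j], sum(w[has]) / sum(w), tolerance = 1e-12)
    }
  }
})

test_that("the visited-set posterior converges to exhaustive enumeration", {
  # small space: total-variation distance between the normalised posterior
  # over visited models and the exact enumeration over all conflict-free
  # combinations shrinks with chain length
  tab <- interaction_table(150, 3, seed = 55)
  prior <- prior_spec(3, 1 / 3)
  cfg <- search_config(K = 30, n_iter = 100000, seed = 7, prior = prior)
  pool <- select_top_k(tab, cfg)
  visited <- run_search(tab, pool, cfg)

  pool_models <- bmagene:::.pool_to_models(pool)
  exact <- enumerate_combined(pool_models, tab, prior)
  lp_exact <- vapply(exact, `[[`, numeric(1), "log_post")
  p_exact <- exp(lp_exact - logsumexp(lp_exact))
  names(p_exact) <- vapply(exact, `[[`, character(1), "key")

  lp_vis <- vapply(visited$models, `[[`, numeric(1), "log_post")
  p_vis <- exp(lp_vis - logsumexp(lp_vis))
  names(p_vis) <- vapply(visited$models, `[[`, character(1), "key")

  expect_true(all(names(p_vis) %in% names(p_exact)))
  tv <- sum(abs(p_exact - ifelse(is.na(p_vis[names(p_exact)]), 0,
                                 p_vis[names(p_exact)]))) / 2
  expect_lt(tv, 0.01)
})

test_that("naive elementary-only averaging equals direct summation", {
  tab <- rand_table(90, 3, seed = 13)
  prior <- prior_spec(3, 1 / 3)
  pool <- enumerate_elementary(3L)
  got <- naive_bma(tab, pool, prior)

  # direct summation over {M0} + the 15 elementary models, deduplicated by
  # canonical model (M3 == M1+M1 and M4 == M2+M2 as model identities)
  entries <- list(list(key = "M0", loci = integer(0),
                       log_post = score_model(combined_model(), tab, prior)$log_post))
  for (em in pool) {
    cm <- combined_model(list(em))
    entries <- c(entries, list(list(key = canonical_key(cm), loci = sort(em$loci),
                                    log_post = score_model(cm, tab, prior)$log_post)))
  }
  entries <- entries[!duplicated(vapply(entries, `[[`, character(1), "key"))]
  expected <- snp_posteriors(entries, L = 3)
  expect_equal(got$p_incl, expected$p_incl, tolerance = 1e-12)

  # appending a zero-weight (-Inf) model changes nothing
  entries2 <- c(entries, list(list(key = "ghost", loci = 1L, log_post = -Inf)))
  expect_equal(snp_posteriors(entries2, L = 3)$p_incl, expected$p_incl)
})

test_that("weakening the structure penalty never shifts mass to smaller models", {
  tab <- rand_table(100, 4, seed = 44)
  cfg <- search_config(K = 25, n_iter = 5000, seed = 3, prior = prior_spec(3, 0.05))
  pool <- select_top_k(tab, cfg)
  visited <- run_search(tab, pool, cfg)
  lml <- vapply(visited$models, `[[`, numeric(1), "log_ml")
  nl <- vapply(visited$models, `[[`, integer(1), "n_loci")
  share_big <- function(xi) {
    lp <- lml + nl * log(xi)
    sum(exp(lp - logsumexp(lp))[nl >= 2L])
  }
  xis <- c(0.01, 0.05, 0.2, 0.5)
  shares <- vapply(xis, share_big, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("a proposal with equal score is always accepted", {
  # acceptance probability is min(1, exp(0)) = 1 for an equal-score
  # proposal; the REMOVE self-loop on M0 exercises exactly this path, so a
  # chain on a null-only pool never rejects
  Z <- matrix(0L, 40, 2) # monomorphic: every model scores like M0
  tab <- genotype_table(Z, rep(0:1, 20))
  cfg <- search_config(K = 7, n_iter = 500, seed = 1, prior = prior_spec(3, 0.5))
  pool <- select_top_k(tab, cfg)
  res <- run_search(tab, pool, cfg)
  # all models share the null marginal likelihood, so acceptance reduces to
  # the prior ratio; ADD moves can still be rejected but equal-score REMOVE
  # and self-loops never are: the trace never jumps upward spontaneously
  expect_true(all(is.finite(res$trace)))
  lml <- vapply(res$models, `[[`, numeric(1), "log_ml")
  expect_equal(lml, rep(lml[1], length(lml)))
})
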