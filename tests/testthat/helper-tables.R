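# fixtures built in code: random case-control tables and small utilities

rand_table <- function(N, L, seed = 1L, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(L, 0.1, 0.5)
  Z <- sapply(maf, function(p) rbinom(N, 2L, p))
  genotype_table(matrix(Z, N, L), rbinom(N, 1L, 0.5))
}

# strong planted M5 interaction at loci (1, 2) among L loci
interaction_table <- function(N, L, seed = 1L, maf = 0.3, risk = c(0.25, 0.75)) {
  set.seed(seed)
  Z <- sapply(seq_len(L), function(j) rbinom(N, 2L, maf))
  p <- ifelse(Z[, 1L] > 0 & Z[, 2L] > 0, risk[2L], risk[1L])
  genotype_table(matrix(Z, N, L), rbinom(N, 1L, p))
}

# all conflict-free combined models over a pool of elementary models,
# deduplicated by canonical key: the exhaustive-enumeration oracle
enumerate_combined <- function(pool_models, table, prior) {
  seen <- new.env(parent = emptyenv())
  loci_of <- lapply(pool_models, `[[`, "loci")
  recurse <- function(start, picked, used) {
    cm <- combined_model(pool_models[picked])
    key <- canonical_key(cm)
    if (is.null(get0(key, envir = seen, inherits = FALSE))) {
      sc <- score_model(cm, table, prior)
      assign(key, list(key = key, loci = sort(unlist(loci_of[picked])),
                       log_post = sc$log_post), envir = seen)
    }
    for (i in seq_along(pool_models)) {
      if (i < start) next
      if (any(loci_of[[i]] %in% used)) next
      recurse(i + 1L, c(picked, i), c(used, loci_of[[i]]))
    }
  }
  recurse(1L, integer(0), integer(0))
  out <- as.list(seen)
  out[order(names(out))]
}

in_any_area <- function(locus, areas) any(vapply(areas, function(a) locus %in% a, logical(1)))
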