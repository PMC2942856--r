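# Case-control simulation engine.
#
# A synthetic genotype pool stands in for the non-public cohort genotypes
# the study design assumes: haplotypes follow a first-order Markov
# allele-copying process with block-structured linkage disequilibrium, and
# genotypes are the sum of two independent haplotypes (Hardy-Weinberg).
# From a pool, each replicate selects four hidden causal SNPs (in disjoint
# regions, empirical MAF within +-1% of target), takes the 20 closest
# flanking SNPs with MAF > 0.1 on each side, deletes the causal column,
# interleaves three 100-SNP null intervals between the four 40-SNP disease
# areas (L = 460), generates disease statuses from one of three generative
# penetrance models calibrated to the target prevalence, keeps all cases and
# an equal number of uniformly sampled controls.

#' Simulation configuration
#'
#' Defaults are the package's study conditions: pool of 2131 individuals,
#' 40% prevalence, four causal areas of 40 retained SNPs, three null
#' intervals of 100 SNPs, flanking-SNP MAF floor 0.1.
#'
#' @param generative_model `"multiplicative"`, `"threshold"` or `"triplet"`.
#' @param grr genotype relative risk (>= 1).
#' @param maf target causal minor-allele frequency, in (0, 0.5].
#' @param prevalence target mean disease probability.
#' @param n_pool individuals in the source pool.
#' @param n_snps SNPs in the source pool (`NULL`: 2000 at replicate scale,
#'   9400 at chromosome scale).
#' @param flank flanking SNPs retained per side of a causal SNP.
#' @param null_interval_len,n_null_intervals null-interval geometry
#'   (`NULL`: 100 x 3 at replicate scale, ~1708 x 5 at chromosome scale).
#' @param maf_floor_flank minimum MAF for flanking SNPs.
#' @param maf_tol match tolerance for the causal SNP's empirical MAF.
#' @param scale `"replicate"` (L = 460) or `"chromosome"` (L ~ 8700).
#' @param block_len mean LD-block length in SNPs (geometric).
#' @param r_range range of the uniform distribution of adjacent-haplotype
#'   allele correlations within a block (0 across block boundaries).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(generative_model = c("multiplicative", "threshold", "triplet"),
                       grr = 1.6, maf = 0.2, prevalence = 0.40,
                       n_pool = 2131L, n_snps = NULL, flank = 20L,
                       null_interval_len = NULL, n_null_intervals = NULL,
                       maf_floor_flank = 0.1, maf_tol = 0.01,
                       scale = c("replicate", "chromosome"),
                       block_len = 15, r_range = c(0.2, 0.95), seed = 1L) {
  generative_model <- match.arg(generative_model)
  scale <- match.arg(scale)
  if (grr < 1) stop_bad("grr must be >= 1")
  if (maf <= 0 || maf > 0.5) stop_bad("maf must lie in (0, 0.5]")
  if (prevalence <= 0 || prevalence >= 1) stop_bad("prevalence must lie in (0, 1)")
  if (is.null(n_snps)) n_snps <- if (scale == "replicate") 2000L else 10000L
  if (is.null(null_interval_len))
    null_interval_len <- if (scale == "replicate") 100L else 1708L
  if (is.null(n_null_intervals))
    n_null_intervals <- if (scale == "replicate") 3L else 5L
  structure(list(generative_model = generative_model, grr = grr, maf = maf,
                 prevalence = prevalence, n_pool = as.integer(n_pool),
                 n_snps = as.integer(n_snps), flank = as.integer(flank),
                 null_interval_len = as.integer(null_interval_len),
                 n_null_intervals = as.integer(n_null_intervals),
                 maf_floor_flank = maf_floor_flank, maf_tol = maf_tol,
                 scale = scale, block_len = block_len, r_range = r_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-SNP target MAFs: a broad uniform component plus narrow windows around
# the canonical causal targets so every target always has candidate SNPs,
# with slow within-block drift and occasional fresh redraws for local
# heterogeneity (so e.g. a MAF-0.05 causal SNP can have MAF > 0.1 flanks).
.draw_maf_profile <- function(L, targets = c(0.05, 0.1, 0.2)) {
  fresh <- function(n) {
    comp <- sample.int(length(targets) + 1L, n, replace = TRUE,
                       prob = c(0.55, rep(0.45 / length(targets), length(targets))))
    out <- stats::runif(n, 0.02, 0.5)
    for (t in seq_along(targets)) {
      idx <- comp == t + 1L
      out[idx] <- stats::runif(sum(idx), targets[t] - 0.009, targets[t] + 0.009)
    }
    out
  }
  maf <- numeric(L)
  maf[1L] <- fresh(1L)
  redraw <- stats::runif(L) < 0.15
  jitter <- stats::rnorm(L, 0, 0.25)
  for (j in 2L:L) {
    maf[j] <- if (redraw[j]) fresh(1L)
              else min(0.5, max(0.02, maf[j - 1L] * exp(jitter[j])))
  }
  maf
}

# max positive r keeping both conditional Bernoulli probabilities
# P(x2 = 1 | x1 = 0/1) inside [0, 1]; equals 1 when the two MAFs agree
.r_feasible <- function(p1, p2) {
  q1 <- 1 - p1; q2 <- 1 - p2
  pmin(sqrt(p1 * q2 / (q1 * p2)), sqrt(q1 * p2 / (p1 * q2)))
}

.sim_haplotypes <- function(n, maf, r) {
  L <- length(maf)
  H <- matrix(0L, n, L)
  H[, 1L] <- stats::rbinom(n, 1L, maf[1L])
  for (j in 2L:L) {
    p <- maf[j]
    if (r[j] == 0) {
      H[, j] <- stats::rbinom(n, 1L, p)
    } else {
      pprev <- maf[j - 1L]
      cond <- p + r[j] * sqrt(p * (1 - p) / (pprev * (1 - pprev))) *
        (H[, j - 1L] - pprev)
      H[, j] <- stats::rbinom(n, 1L, pmin(1, pmax(0, cond)))
    }
  }
  H
}

#' Synthesize a genotype pool with block LD structure
#'
#' Haplotypes follow a first-order Markov allele-copying process: within an
#' LD block (geometric length, mean `block_len`) the adjacent-pair allele
#' correlation is drawn from `uniform(r_range)` (clipped to the feasible
#' range given the two MAFs); across block boundaries the correlation is 0.
#' Genotypes are sums of two independent haplotypes. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a phenotype-free [genotype_table()] with attributes `maf_target`
#'   (per-SNP generative MAF), `block` (per-SNP block index) and `r`
#'   (per-adjacent-pair correlation used, `r[1] = 0`).
#' @export
synthesize_pool <- function(config = sim_config()) {
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(config$seed)
  L <- config$n_snps; n <- config$n_pool
  maf <- .draw_maf_profile(L)
  # geometric block boundaries
  newblk <- stats::runif(L) < 1 / config$block_len
  newblk[1L] <- TRUE
  block <- cumsum(newblk)
  r <- stats::runif(L, config$r_range[1L], config$r_range[2L])
  r[newblk] <- 0
  feas <- c(0, .r_feasible(maf[-L], maf[-1L]))
  r <- pmin(r, 0.999 * feas)
  Z <- .sim_haplotypes(n, maf, r) + .sim_haplotypes(n, maf, r)
  tab <- genotype_table(Z, phenotype = NULL,
                        locus_ids = sprintf("snp%05d", seq_len(L)))
  attr(tab, "maf_target") <- maf
  attr(tab, "block") <- block
  attr(tab, "r") <- r
  tab
}

#' Risk multiplier of each individual under a generative disease model
#'
#' The three penetrance models over the four causal genotypes
#' `(Z1, Z2, Z3, Z4)`:
#' multiplicative, `GRR^(I(Z1>0) + I(Z2>0) + I(Z3>0) + I(Z4>0))`;
#' threshold, `GRR^I(Z1>0 and Z2>0) * GRR^I(Z3>0 and Z4>0)`;
#' triplet, `GRR^(I(Z1>0 and Z2=0) * Z3) * GRR^(I(Z4>0)/2)`.
#'
#' @param G N x 4 matrix of genotypes at the causal loci.
#' @param model generative model name.
#' @param grr genotype relative risk.
#' @return numeric vector of length N (each >= 1).
#' @export
risk_multiplier <- function(G, model, grr) {
  G <- as.matrix(G)
  if (ncol(G) != 4L) stop_bad("risk_multiplier needs 4 causal genotype columns")
  expo <- switch(model,
    multiplicative = rowSums(G > 0L),
    threshold = (G[, 1L] > 0L & G[, 2L] > 0L) + (G[, 3L] > 0L & G[, 4L] > 0L),
    triplet = (G[, 1L] > 0L & G[, 2L] == 0L) * G[, 3L] + (G[, 4L] > 0L) / 2,
    stop_bad("unknown generative model '%s'", model))
  grr^expo
}

#' Disease probability under a generative model
#'
#' `min(1, beta0 * risk_multiplier)`; the cap guards settings (e.g.
#' multiplicative GRR = 2) where the calibrated baseline times the maximal
#' multiplier exceeds 1.
#'
#' @param G N x 4 causal genotype matrix (or a length-4 vector).
#' @param config a [sim_config()] (or a model name with `grr` supplied).
#' @param beta0 baseline risk, > 0.
#' @param grr used when `config` is a model name.
#' @return numeric vector of probabilities.
#' @export
disease_probability <- function(G, config, beta0, grr = NULL) {
  if (is.null(dim(G))) G <- matrix(G, ncol = 4L)
  model <- if (inherits(config, "sim_config")) config$generative_model else config
  g <- if (inherits(config, "sim_config")) config$grr else grr
  if (beta0 <= 0) stop_bad("beta0 must be > 0")
  pmin(1, beta0 * risk_multiplier(G, model, g))
}

#' Calibrate the baseline risk to a target prevalence
#'
#' Solves `mean(min(1, beta0 * f_i)) = prevalence` over the pool by monotone
#' bisection, where `f_i` is each individual's risk multiplier. Without any
#' capped individual this reduces to `beta0 = prevalence / mean(f)`.
#'
#' @param G pool genotypes at the four causal loci (N x 4).
#' @param config a [sim_config()].
#' @param tol bisection tolerance on the attained prevalence.
#' @return `beta0` (numeric scalar).
#' @export
calibrate_beta0 <- function(G, config, tol = 1e-9) {
  f <- risk_multiplier(G, config$generative_model, config$grr)
  target <- config$prevalence
  b <- target / mean(f)
  if (max(b * f) <= 1) return(b) # closed form: no capping active
  lo <- 0; hi <- 1 # f >= 1 so beta0 = 1 attains prevalence 1 >= target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    prev <- mean(pmin(1, mid * f))
    if (abs(prev - target) < tol) return(mid)
    if (prev < target) lo <- mid else hi <- mid
  }
  stop_bad("prevalence %.3f unattainable by bisection", target)
}

# flanking SNP indices: the `flank` closest on each side with MAF above the
# floor, or NULL if the pool runs out on either side.
.flank_indices <- function(causal, eligible, flank) {
  left <- eligible[eligible < causal]
  right <- eligible[eligible > causal]
  if (length(left) < flank || length(right) < flank) return(NULL)
  sort(c(utils::tail(left, flank), utils::head(right, flank)))
}

#' Build one simulated case-control replicate from a pool
#'
#' Implements the full area construction, phenotype generation and
#' case-control sampling described at the top of this file. The hidden
#' causal SNPs are excluded from the emitted genotype columns; their
#' positions fall in the gap between the 20th and 21st retained SNPs of
#' their areas.
#'
#' @param pool a pool [genotype_table()] from [synthesize_pool()].
#' @param config a [sim_config()].
#' @param seed replicate seed (defaults to `config$seed`).
#' @param max_tries rejection limit for replicates with too few non-cases.
#' @return an object of class `replicate_dataset`: list with `table` (cases
#'   and controls at the retained SNPs), `causal_areas` (list of index
#'   ranges), `causal_gap_position` (per area, the number of retained SNPs
#'   preceding the hidden causal position), and `truth` (generative model,
#'   grr, maf, pool column indices of the causal SNPs, their empirical MAFs,
#'   `beta0`, `n_cases_pool`).
#' @export
build_replicate <- function(pool, config, seed = config$seed,
                            max_tries = 25L) {
  stopifnot(inherits(pool, "genotype_table"))
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  for (try in seq_len(max_tries)) {
    set.seed(derive_seed(seed, try - 1L))
    rep <- .build_replicate_once(pool, config)
    if (!is.null(rep)) return(rep)
  }
  stop_bad("failed to build a replicate in %d attempts (insufficient eligible SNPs or non-cases)",
           max_tries)
}

.build_replicate_once <- function(pool, config) {
  Z <- pool$genotypes
  maf <- minor_allele_freq(pool)
  L <- ncol(Z)
  eligible_flank <- which(maf > config$maf_floor_flank)
  candidates <- which(abs(maf - config$maf) <= config$maf_tol)
  candidates <- candidates[candidates > config$flank &
                           candidates <= L - config$flank]
  if (length(candidates) < 4L) return(NULL)

  n_areas <- 4L
  causal <- integer(0)
  areas <- list()
  used <- rep(FALSE, L)
  # at chromosome scale the null intervals are consecutive slices of one
  # reserved stretch (the stand-in for a whole null chromosome); areas are
  # drawn from the rest. At replicate scale null intervals are placed
  # randomly afterwards.
  null_zone <- NULL
  if (config$scale == "chromosome") {
    zone_len <- config$n_null_intervals * config$null_interval_len
    if (zone_len >= L) return(NULL)
    null_zone <- (L - zone_len + 1L):L
    used[null_zone] <- TRUE
  }
  min_gap <- 10L # emulates "different chromosomes": disjoint, separated regions
  for (cand in candidates[sample.int(length(candidates))]) {
    if (length(causal) == n_areas) break
    fl <- .flank_indices(cand, eligible_flank, config$flank)
    if (is.null(fl)) next
    span <- (min(fl) - min_gap):(max(fl) + min_gap)
    span <- span[span >= 1L & span <= L]
    if (any(used[span]) || used[cand]) next
    used[span] <- TRUE
    causal <- c(causal, cand)
    areas <- c(areas, list(fl))
  }
  if (length(causal) < n_areas) return(NULL)
  ord <- order(causal)
  causal <- causal[ord]; areas <- areas[ord]

  # null intervals: consecutive slices of the reserved zone, or random
  # untouched stretches
  nulls <- list()
  len <- config$null_interval_len
  if (!is.null(null_zone)) {
    for (i in seq_len(config$n_null_intervals))
      nulls <- c(nulls, list(null_zone[((i - 1L) * len + 1L):(i * len)]))
  } else {
    free <- which(!used)
    for (i in seq_len(config$n_null_intervals)) {
      starts <- free[(free + len - 1L) <= L]
      starts <- starts[vapply(starts, function(s) all(!used[s:(s + len - 1L)]),
                              logical(1))]
      if (length(starts) == 0L) return(NULL)
      s <- starts[sample.int(length(starts), 1L)]
      used[s:(s + len - 1L)] <- TRUE
      nulls <- c(nulls, list(s:(s + len - 1L)))
    }
  }

  # disease statuses over the whole pool
  G <- Z[, causal, drop = FALSE]
  beta0 <- calibrate_beta0(G, config)
  pi_i <- disease_probability(G, config, beta0)
  y <- stats::rbinom(length(pi_i), 1L, pi_i)
  cases <- which(y == 1L)
  noncases <- which(y == 0L)
  if (length(noncases) < length(cases)) return(NULL) # redraw with next seed
  controls <- sort(noncases[sample.int(length(noncases), length(cases))])

  # interleave: area-first when there are fewer nulls than areas
  # (replicate layout), null-first otherwise (chromosome layout)
  cols <- integer(0)
  area_ranges <- vector("list", n_areas)
  gap_pos <- integer(n_areas)
  area_first <- length(nulls) < n_areas
  for (i in seq_len(max(n_areas, length(nulls)))) {
    pieces <- if (area_first) list(areas[i][[1]] %||% NULL, nulls[i][[1]] %||% NULL)
              else list(nulls[i][[1]] %||% NULL, areas[i][[1]] %||% NULL)
    for (piece in pieces) {
      if (is.null(piece)) next
      if (identical(piece, areas[i][[1]])) {
        area_ranges[[i]] <- (length(cols) + 1L):(length(cols) + length(piece))
        gap_pos[i] <- sum(piece < causal[i])
      }
      cols <- c(cols, piece)
    }
  }

  idx <- c(cases, controls)
  tab <- genotype_table(Z[idx, cols, drop = FALSE],
                        phenotype = c(rep(1L, length(cases)),
                                      rep(0L, length(controls))),
                        locus_ids = pool$locus_ids[cols])
  structure(list(table = tab,
                 causal_areas = area_ranges,
                 causal_gap_position = gap_pos,
                 truth = list(generative_model = config$generative_model,
                              grr = config$grr, maf = config$maf,
                              causal_pool_index = causal,
                              causal_maf = maf[causal],
                              beta0 = beta0,
                              n_cases_pool = length(cases))),
            class = "replicate_dataset")
}

#' @export
print.replicate_dataset <- function(x, ...) {
  cat(sprintf("replicate_dataset: %s model, GRR %.1f, MAF %.2f; %d x %d; %d pool cases\n",
              x$truth$generative_model, x$truth$grr, x$truth$maf,
              nrow(x$table$genotypes), ncol(x$table$genotypes),
              x$truth$n_cases_pool))
  invisible(x)
}

#' Generate a batch of replicates from one pool
#'
#' The pool is synthesized once (mirroring the reuse of a single cohort's
#' genotypes across replicates) and per-replicate seeds are derived from the
#' master seed with [derive_seed()].
#'
#' @param config a [sim_config()]; `config$seed` is the master seed.
#' @param n_replicates number of replicates.
#' @param pool optional pre-built pool (synthesized from `config` if absent).
#' @return list of `replicate_dataset`s.
#' @export
simulate_replicates <- function(config, n_replicates, pool = NULL) {
  if (is.null(pool)) pool <- synthesize_pool(config)
  lapply(seq_len(n_replicates), function(i)
    build_replicate(pool, config, seed = derive_seed(config$seed, 1000L + i)))
}
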