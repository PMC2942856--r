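test_that("pool synthesis is deterministic and respects the independence limit", {
  cfg <- sim_config(n_pool = 300L, n_snps = 200L, seed = 5)
  p1 <- synthesize_pool(cfg)
  p2 <- synthesize_pool(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_true(all(p1$genotypes %in% 0:2))

  # r = 0 everywhere: adjacent-SNP genotype correlation within sampling error of 0
  cfg0 <- sim_config(n_pool = 2000L, n_snps = 60L, r_range = c(0, 0), seed = 8)
  pool0 <- synthesize_pool(cfg0)
  cors <- sapply(2:60, function(j)
    cor(pool0$genotypes[, j - 1], pool0$genotypes[, j]))
  expect_lt(max(abs(cors)), 4 / sqrt(2000))
})

test_that("the haplotype Markov chain attains its target adjacent correlation", {
  # constant MAF, r = 0.9 everywhere: empirical adjacent-haplotype allele
  # correlation within 3 SEs of 0.9 (Markov moment oracle)
  set.seed(14)
  L <- 40L; n <- 2000L
  maf <- rep(0.3, L)
  r <- c(0, rep(0.9, L - 1L))
  H <- bmagene:::.sim_haplotypes(n, maf, r)
  cors <- sapply(2:L, function(j) cor(H[, j - 1], H[, j]))
  se <- (1 - 0.9^2) / sqrt(n) # asymptotic SE of a correlation estimate
  expect_lt(abs(mean(cors) - 0.9), 3 * se)
})

test_that("replicates have the documented area geometry and sampling balance", {
  cfg <- sim_config("threshold", grr = 1.6, maf = 0.2, seed = 33)
  pool <- synthesize_pool(cfg)
  rep1 <- build_replicate(pool, cfg, seed = 12)
  tab <- rep1$table

  # 4 x 40 area SNPs + 3 x 100 null SNPs = 460, areas at the stated intervals
  expect_identical(ncol(tab$genotypes), 460L)
  expect_identical(rep1$causal_areas,
                   list(1:40, 141:180, 281:320, 421:460))
  # the hidden causal SNP sits between retained SNPs 20 and 21 of its area
  expect_identical(rep1$causal_gap_position, rep(20L, 4))
  # causal columns are excluded from the emitted data
  causal_ids <- pool$locus_ids[rep1$truth$causal_pool_index]
  expect_false(any(causal_ids %in% tab$locus_ids))
  # equal numbers of cases and controls
  expect_identical(sum(tab$phenotype == 1L), sum(tab$phenotype == 0L))
  # flanking SNPs all clear the MAF floor; causal MAF matches the target
  area_maf <- minor_allele_freq(pool)[match(tab$locus_ids[unlist(rep1$causal_areas)],
                                            pool$locus_ids)]
  expect_true(all(area_maf > cfg$maf_floor_flank))
  expect_true(all(abs(rep1$truth$causal_maf - cfg$maf) <= cfg$maf_tol + 1e-12))
  # area SNPs cover 160/460 of the sequence
  expect_equal(length(unlist(rep1$causal_areas)) / ncol(tab$genotypes), 160 / 460)
  # determinism
  rep2 <- build_replicate(pool, cfg, seed = 12)
  expect_identical(rep1$table$genotypes, rep2$table$genotypes)
  expect_identical(rep1$truth$causal_pool_index, rep2$truth$causal_pool_index)
})

test_that("chromosome-scale replicates interleave areas between five null slices", {
  cfg <- sim_config("threshold", grr = 2.0, maf = 0.2, scale = "chromosome",
                    n_pool = 400L, n_snps = 2500L, null_interval_len = 300L,
                    seed = 21)
  pool <- synthesize_pool(cfg)
  rep1 <- build_replicate(pool, cfg, seed = 4)
  # layout: null, area, null, area, null, area, null, area, null
  expect_identical(ncol(rep1$table$genotypes), 5L * 300L + 4L * 40L)
  starts <- vapply(rep1$causal_areas, min, integer(1))
  expect_identical(starts, 300L + (0:3) * 340L + 1L)
  expect_identical(rep1$causal_gap_position, rep(20L, 4))
  expect_identical(sum(rep1$table$phenotype == 1L),
                   sum(rep1$table$phenotype == 0L))
})

test_that("generative penetrance models follow their indicator algebra", {
  b0 <- 0.2; grr <- 1.6
  # all four genotypes 0: baseline risk under every model
  for (m in c("multiplicative", "threshold", "triplet"))
    expect_equal(disease_probability(c(0, 0, 0, 0), m, b0, grr = grr), b0)
  # threshold: one active pair multiplies the risk once
  expect_equal(disease_probability(c(1, 2, 0, 0), "threshold", b0, grr = grr),
               b0 * grr)
  expect_equal(disease_probability(c(1, 2, 1, 2), "threshold", b0, grr = grr),
               b0 * grr^2)
  # multiplicative: one factor per carrier locus
  expect_equal(disease_probability(c(1, 0, 2, 1), "multiplicative", b0, grr = grr),
               b0 * grr^3)
  # triplet: exponent I(Z1>0, Z2=0) * Z3, plus half-exponent main effect at Z4
  expect_equal(disease_probability(c(1, 0, 2, 0), "triplet", b0, grr = grr),
               b0 * grr^2)
  expect_equal(disease_probability(c(1, 1, 2, 0), "triplet", b0, grr = grr), b0)
  expect_equal(disease_probability(c(0, 0, 0, 1), "triplet", b0, grr = grr),
               b0 * grr^0.5)
  # probabilities are capped at 1
  expect_equal(disease_probability(c(1, 1, 1, 1), "multiplicative", 0.5, grr = 2), 1)
  # GRR = 1 degenerates to the baseline for every model
  G <- matrix(sample(0:2, 40, TRUE), 10, 4)
  for (m in c("multiplicative", "threshold", "triplet"))
    expect_equal(disease_probability(G, m, b0, grr = 1), rep(b0, 10))
})

test_that("baseline-risk calibration hits the target prevalence", {
  cfg <- sim_config("multiplicative", grr = 2, maf = 0.2, prevalence = 0.4)
  # null effect: beta0 equals the prevalence
  G0 <- matrix(0L, 50, 4)
  expect_equal(calibrate_beta0(G0, cfg), 0.4)
  # closed form without capping: f = 2 on half the pool, 1 on the other half
  cfg_thr <- sim_config("threshold", grr = 2, maf = 0.2, prevalence = 0.4)
  G <- rbind(matrix(c(1L, 1L, 0L, 0L), 25, 4, byrow = TRUE),
             matrix(0L, 25, 4))
  expect_equal(calibrate_beta0(G, cfg_thr), 0.4 / 1.5)
  # with capping active, bisection still attains the prevalence; rarer
  # causal alleles concentrate the risk so the top multipliers exceed 1/b0
  set.seed(2)
  Gbig <- matrix(rbinom(8000, 2, 0.15), ncol = 4)
  b0 <- calibrate_beta0(Gbig, cfg)
  pi_i <- disease_probability(Gbig, cfg, b0)
  expect_lt(abs(mean(pi_i) - 0.4), 1e-6)
  expect_gt(max(cfg$grr^rowSums(Gbig > 0) * b0), 1) # the cap really binds here
})

test_that("the pool case count concentrates near prevalence x pool size", {
  cfg <- sim_config("threshold", grr = 1.6, maf = 0.2, n_pool = 2131L,
                    n_snps = 1200L, seed = 71)
  reps <- simulate_replicates(cfg, 8)
  cases <- vapply(reps, function(r) r$truth$n_cases_pool, numeric(1))
  # per-replicate binomial SD is ~22.6; the mean of 8 replicates has SE ~8
  expect_lt(abs(mean(cases) - 0.4 * 2131), 3 * sqrt(2131 * 0.4 * 0.6 / 8))
})
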