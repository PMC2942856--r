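# Evaluation metrics for simulated replicates.
#
# A method's per-SNP scores are judged by how the ranked SNP list covers the
# hidden disease-associated areas: the area-detection curve records the
# false-positive count (SNPs outside all areas) at the first attainment of
# each number of distinct areas detected. Both axes are normalised to unity
# for the AUC. Location accuracy is the marker distance from the top-ranked
# SNP to the nearest hidden causal position (sentinel 20 when the top SNP
# is outside every area). Paired methods are compared by win/loss counts
# with a two-sided binomial test.

# deterministic score ranking: descending score, ties by ascending locus
# index; -Inf sentinel scores sort last (among themselves by index).
.rank_snps <- function(scores) {
  order(-scores, seq_along(scores))
}

#' Area-detection curve of a score vector
#'
#' Walking down the ranked SNP list, an area counts as detected at the first
#' SNP inside it and every SNP outside all areas increments the
#' false-positive count; the curve records the FP count at the first
#' attainment of k = 0..n_areas detected areas. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores per-SNP numeric vector (`-Inf` allowed).
#' @param areas list of integer index ranges (the causal areas), or a
#'   `replicate_dataset`.
#' @return an object of class `detection_curve`: list with `fp` (length
#'   `n_areas + 1`, FP counts at k = 0..n_areas), `n_areas`, `n_outside`
#'   and `ranking`.
#' @export
detection_curve <- function(scores, areas) {
  if (inherits(areas, "replicate_dataset")) areas <- areas$causal_areas
  L <- length(scores)
  area_of <- integer(L) # 0 = outside
  for (a in seq_along(areas)) area_of[areas[[a]]] <- a
  ranking <- .rank_snps(scores)
  n_areas <- length(areas)
  fp <- integer(n_areas + 1L)
  found <- logical(n_areas)
  k <- 0L; nfp <- 0L
  for (j in ranking) {
    a <- area_of[j]
    if (a == 0L) {
      nfp <- nfp + 1L
    } else if (!found[a]) {
      found[a] <- TRUE
      k <- k + 1L
      fp[k + 1L] <- nfp
    }
    if (k == n_areas) break
  }
  structure(list(fp = fp, n_areas = n_areas,
                 n_outside = sum(area_of == 0L), ranking = ranking),
            class = "detection_curve")
}

#' Mean and percentile detection curves over replicates
#'
#' Per number of detected areas k: the mean and the 2.5th/97.5th empirical
#' percentiles (type-7 linear interpolation) of the FP counts across
#' replicates.
#'
#' @param curves list of [detection_curve()]s with equal `n_areas`.
#' @return list with vectors `mean`, `p2.5`, `p97.5` (length `n_areas + 1`)
#'   and `n_curves`.
#' @export
mean_and_percentile_curves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  fp <- do.call(rbind, lapply(curves, `[[`, "fp"))
  list(mean = colMeans(fp),
       p2.5 = apply(fp, 2L, stats::quantile, probs = 0.025, names = FALSE),
       p97.5 = apply(fp, 2L, stats::quantile, probs = 0.975, names = FALSE),
       n_curves = length(curves))
}

#' Normalised area under a detection curve
#'
#' Axes normalised to unity (x = FP / n_outside, y = k / n_areas); the area
#' of the left-continuous step function through the curve's points, extended
#' at the attained y to x = 1. A perfect ranking gives 1; finding every area
#' only after all outside SNPs gives 0.
#'
#' @param curve a [detection_curve()].
#' @param n_outside,n_areas overrides (default: taken from the curve).
#' @return numeric in \[0, 1\].
#' @export
auc <- function(curve, n_outside = curve$n_outside,
                n_areas = curve$n_areas) {
  x <- curve$fp / n_outside
  y <- seq(0L, n_areas) / n_areas
  a <- 0
  for (k in seq_len(n_areas)) a <- a + y[k] * (x[k + 1L] - x[k])
  a + y[n_areas + 1L] * (1 - x[n_areas + 1L])
}

#' Location accuracy of a score vector
#'
#' Marker distance from the top-ranked SNP to the nearest hidden causal
#' position. Within an area of 40 retained SNPs the causal position sits in
#' the gap after the 20th SNP, so a SNP at within-area position p has
#' distance `21 - p` (p <= 20) or `p - 20` (p >= 21), i.e. 1..20; a
#' top-ranked SNP outside all areas scores the sentinel 20. In
#' `triplet_mode` the area of the fourth causal SNP (the only one with a
#' main effect under the triplet generative model) is excluded from the
#' arg-max.
#'
#' @param scores per-SNP numeric vector.
#' @param truth a `replicate_dataset` (or a list with `causal_areas` and
#'   `causal_gap_position`).
#' @param triplet_mode logical; exclude the fourth causal area's SNPs from
#'   the ranking.
#' @return integer distance in markers (1..20).
#' @export
location_accuracy <- function(scores, truth, triplet_mode = FALSE) {
  areas <- truth$causal_areas
  gap <- truth$causal_gap_position
  consider <- rep(TRUE, length(scores))
  if (triplet_mode) consider[areas[[length(areas)]]] <- FALSE
  idx <- which(consider)
  top <- idx[.rank_snps(scores[idx])[1L]]
  for (a in seq_along(areas)) {
    pos <- match(top, areas[[a]])
    if (!is.na(pos)) {
      g <- gap[a]
      return(if (pos <= g) g + 1L - pos else pos - g)
    }
  }
  20L
}

#' Pairwise win/loss comparison of two methods
#'
#' Counts, across paired replicates, how often method A beats method B on
#' the chosen criterion (ties ignored), and classifies the cell: `white`
#' when `|a - b| < 5`; otherwise the side with more wins colours the cell
#' (`red`-ish for A, `blue`-ish for B), dark when the two-sided binomial
#' test of a wins in a+b trials against p = 0.5 rejects at level 0.05 and
#' light otherwise.
#'
#' @param metric_a,metric_b paired per-replicate metric vectors.
#' @param higher_is_better logical: `TRUE` for AUC, `FALSE` for location
#'   distance.
#' @return list with `wins_a`, `wins_b`, `p_value` and `category` (one of
#'   `"red"`, `"light-red"`, `"white"`, `"light-blue"`, `"blue"`).
#' @export
compare_methods <- function(metric_a, metric_b, higher_is_better = TRUE) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_a - metric_b
  if (!higher_is_better) d <- -d
  a <- sum(d > 0); b <- sum(d < 0)
  p <- if (a + b == 0) 1 else stats::binom.test(a, a + b, 0.5)$p.value
  category <- if (abs(a - b) < 5) "white"
    else if (a > b) { if (p < 0.05) "red" else "light-red" }
    else { if (p < 0.05) "blue" else "light-blue" }
  list(wins_a = a, wins_b = b, p_value = p, category = category)
}

#' Summary row for one simulation setting
#'
#' Across a setting's replicates: the range (min, max) of the per-replicate
#' maximum score among disease-area SNPs, and the proportion of replicates
#' whose overall top-ranked SNP lies inside a disease area.
#'
#' @param score_list list of per-SNP score vectors, one per replicate.
#' @param truth_list matching list of `replicate_dataset`s.
#' @return list with `max_score_range` (length 2) and `accuracy`.
#' @export
setting_summary <- function(score_list, truth_list) {
  stopifnot(length(score_list) == length(truth_list), length(score_list) >= 1L)
  max_in_area <- numeric(length(score_list))
  top_hit <- logical(length(score_list))
  for (i in seq_along(score_list)) {
    s <- score_list[[i]]
    mask <- rep(FALSE, length(s))
    for (a in truth_list[[i]]$causal_areas) mask[a] <- TRUE
    max_in_area[i] <- max(s[mask])
    top_hit[i] <- mask[.rank_snps(s)[1L]]
  }
  list(max_score_range = range(max_in_area), accuracy = mean(top_hit))
}
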