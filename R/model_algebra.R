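# Elementary penetrance models and their combination algebra.
#
# The five elementary models on one or two loci:
#   M1(j)   full single-locus model, 3 disease-probability classes (Z = 0/1/2)
#   M2(j)   dominant single-locus model, 2 classes (Z = 0 vs Z > 0)
#   M3(j,k) full two-locus model, 9 classes (all genotype pairs)
#   M4(j,k) dominant two-locus model with main effects, 4 classes
#   M5(j,k) dominant two-locus model without main effects, 2 classes
#           (both loci carry a minor allele vs not)
# A combined model is a conflict-free set of elementary models (no locus in
# two components); its partition of individuals is the product (all
# intersections) of the component partitions.

.EM_ARITY   <- c(1L, 1L, 2L, 2L, 2L)
.EM_CLASSES <- c(3L, 2L, 9L, 4L, 2L)

#' Construct an elementary penetrance model
#'
#' @param kind model kind: one of `"M1"`..`"M5"` or an integer 1..5.
#' @param loci one locus index (M1, M2) or two distinct locus indices
#'   (M3, M4, M5); two-locus indices are stored in ascending order.
#' @return an object of class `elementary_model` with fields `kind`
#'   (integer 1..5) and `loci`.
#' @export
elementary_model <- function(kind, loci) {
  if (is.character(kind)) kind <- match(kind, paste0("M", 1:5))
  kind <- as.integer(kind)
  if (is.na(kind) || kind < 1L || kind > 5L)
    stop_bad("elementary model kind must be M1..M5")
  loci <- as.integer(loci)
  if (length(loci) != .EM_ARITY[kind])
    stop_bad("M%d takes %d locus index/indices, got %d",
             kind, .EM_ARITY[kind], length(loci))
  if (any(loci < 1L)) stop_bad("locus indices must be >= 1")
  if (length(loci) == 2L) {
    if (loci[1L] == loci[2L]) stop_bad("two-locus model needs distinct loci")
    loci <- sort(loci)
  }
  structure(list(kind = kind, loci = loci), class = "elementary_model")
}

#' @export
format.elementary_model <- function(x, ...) {
  sprintf("M%d(%s)", x$kind, paste(x$loci, collapse = ","))
}

#' @export
print.elementary_model <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Partition induced by an elementary model
#'
#' Class labels are 0-based; the structural class count is 3, 2, 9, 4 or 2
#' for M1..M5 (empty classes are retained).
#'
#' @param model an [elementary_model()].
#' @param table a [genotype_table()] (or a bare genotype matrix).
#' @return a list with `class_of` (integer vector, length N, values in
#'   `0..n_classes-1`) and `n_classes`.
#' @export
elementary_partition <- function(model, table) {
  Z <- if (inherits(table, "genotype_table")) table$genotypes else table
  j <- model$loci[1L]
  if (any(model$loci > ncol(Z)))
    stop_bad("locus index out of range (L = %d)", ncol(Z))
  cls <- switch(model$kind,
    Z[, j],
    as.integer(Z[, j] > 0L),
    { k <- model$loci[2L]; 3L * Z[, j] + Z[, k] },
    { k <- model$loci[2L]; 2L * as.integer(Z[, j] > 0L) + as.integer(Z[, k] > 0L) },
    { k <- model$loci[2L]; as.integer(Z[, j] > 0L & Z[, k] > 0L) })
  list(class_of = as.integer(cls), n_classes = .EM_CLASSES[model$kind])
}

# canonical expansion: M3(j,k) -> {M1(j), M1(k)}, M4(j,k) -> {M2(j), M2(k)}.
# Both sides induce the identical product partition, so model identity (and
# hence the visited-model set and all scores) treats them as one model.
.expand_component <- function(em) {
  if (em$kind == 3L)
    list(elementary_model(1L, em$loci[1L]), elementary_model(1L, em$loci[2L]))
  else if (em$kind == 4L)
    list(elementary_model(2L, em$loci[1L]), elementary_model(2L, em$loci[2L]))
  else list(em)
}

#' Construct a combined association model
#'
#' Components must have pairwise-disjoint loci. The stored form is canonical:
#' M3 and M4 components are expanded into their M1/M2 single-locus
#' equivalents (which induce the same partition), and components are sorted
#' by first locus. The empty set is the null model M0.
#'
#' @param components list of [elementary_model()]s (possibly empty).
#' @return an object of class `combined_model` with fields `components`
#'   (canonical), `n_loci` and `n_classes` (structural class count, the
#'   product over components).
#' @export
combined_model <- function(components = list()) {
  if (inherits(components, "elementary_model")) components <- list(components)
  loci <- unlist(lapply(components, `[[`, "loci"))
  if (anyDuplicated(loci))
    stop_bad("combined model components must not include overlapping loci (locus %d repeated)",
             loci[duplicated(loci)][1L])
  comps <- unlist(lapply(components, .expand_component), recursive = FALSE)
  if (length(comps)) {
    ord <- order(vapply(comps, function(e) e$loci[1L], integer(1)),
                 vapply(comps, `[[`, integer(1), "kind"),
                 vapply(comps, function(e) e$loci[length(e$loci)], integer(1)))
    comps <- comps[ord]
  }
  d <- prod(vapply(comps, function(e) .EM_CLASSES[e$kind], integer(1)))
  if (d <= .Machine$integer.max) d <- as.integer(d)
  structure(list(components = comps,
                 n_loci = length(loci),
                 n_classes = d),
            class = "combined_model")
}

#' Canonical text key of a combined model
#'
#' Equal keys identify models that induce identical partitions on every
#' genotype table (M3/M4 components are first expanded to their M1/M2
#' equivalents). The null model's key is `"M0"`.
#'
#' @param model a [combined_model()].
#' @return a character scalar, e.g. `"M2(3)+M5(12,47)"`.
#' @export
canonical_key <- function(model) {
  if (length(model$components) == 0L) return("M0")
  paste(vapply(model$components, format, character(1)), collapse = "+")
}

#' @export
format.combined_model <- function(x, ...) canonical_key(x)

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("%s  [%d loci, %d classes]\n",
              canonical_key(x), x$n_loci, x$n_classes))
  invisible(x)
}

#' Parse the compact model notation
#'
#' Inverse of [canonical_key()]; accepts any `+`-separated list of
#' `Mk(j[,l])` terms, or `"M0"`.
#'
#' @param text e.g. `"M5(12,47)+M2(3)"`.
#' @return a [combined_model()].
#' @export
parse_model <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (text == "M0") return(combined_model())
  parts <- strsplit(text, "+", fixed = TRUE)[[1L]]
  comps <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^M([1-5])\\(([0-9]+)(,([0-9]+))?\\)$", p))[[1L]]
    if (length(m) == 0L) stop_bad("cannot parse model term '%s'", p)
    loci <- as.integer(c(m[3L], if (nzchar(m[5L])) m[5L]))
    elementary_model(as.integer(m[2L]), loci)
  })
  combined_model(comps)
}

#' Combine elementary models and compute the product partition
#'
#' The partition classes are all intersections of the component classes;
#' labels use mixed-radix encoding of the component class indices in
#' canonical component order, so the structural class count is the product
#' of the component class counts. Empty classes are retained.
#'
#' @param models list of [elementary_model()]s (or a [combined_model()]).
#' @param table a [genotype_table()].
#' @return list with `model` (the canonical [combined_model()]) and
#'   `partition` (as in [elementary_partition()]).
#' @export
combine <- function(models, table) {
  cm <- if (inherits(models, "combined_model")) models else combined_model(models)
  list(model = cm, partition = model_partition(cm, table))
}

#' Partition of individuals under a combined model
#'
#' @param model a [combined_model()].
#' @param table a [genotype_table()] (or a bare genotype matrix).
#' @return list with `class_of` (0-based integer labels) and `n_classes`.
#' @export
model_partition <- function(model, table) {
  Z <- if (inherits(table, "genotype_table")) table$genotypes else table
  lab <- integer(nrow(Z))
  d <- 1L
  for (em in model$components) {
    p <- elementary_partition(em, Z)
    lab <- lab * p$n_classes + p$class_of
    d <- d * p$n_classes
  }
  list(class_of = lab, n_classes = d)
}

#' Enumerate all distinct elementary models for L loci
#'
#' Returns the 2L single-locus models plus the 3 C(L,2) two-locus models;
#' `|Me| = 2L + 3L(L-1)/2` in total. For L = 1 only the two single-locus
#' models exist.
#'
#' @param table a [genotype_table()], or an integer L.
#' @return list of [elementary_model()]s.
#' @export
enumerate_elementary <- function(table) {
  L <- if (inherits(table, "genotype_table")) ncol(table$genotypes)
       else as.integer(table)
  out <- vector("list", 2L * L + if (L >= 2L) 3L * L * (L - 1L) / 2L else 0L)
  i <- 0L
  for (kind in 1:2) for (j in seq_len(L)) {
    i <- i + 1L; out[[i]] <- elementary_model(kind, j)
  }
  if (L >= 2L) {
    for (kind in 3:5) for (j in seq_len(L - 1L)) for (k in (j + 1L):L) {
      i <- i + 1L; out[[i]] <- elementary_model(kind, c(j, k))
    }
  }
  out
}
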