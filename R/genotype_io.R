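#' Construct and validate a genotype table
#'
#' A `genotype_table` holds an N x L matrix of minor-allele counts (0, 1, 2),
#' an optional binary phenotype (1 = case), unique locus identifiers, and a
#' logical mask marking entries that were missing in the source data.
#' Missing entries are stored as `NA` in `genotypes` until imputed.
#'
#' @param genotypes integer matrix, N individuals x L loci, entries in
#'   \{0, 1, 2\} or `NA` where `missing_mask` is `TRUE`.
#' @param phenotype binary vector of length N (`NULL` for a phenotype-free
#'   pool, e.g. the output of [synthesize_pool()]).
#' @param locus_ids character vector of L unique locus names; defaults to
#'   `snp1..snpL`.
#' @param missing_mask logical N x L matrix; defaults to `is.na(genotypes)`.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(genotypes, phenotype = NULL, locus_ids = NULL,
                           missing_mask = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(missing_mask)) missing_mask <- is.na(genotypes)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(genotypes)))
    stop_bad("missing_mask dimensions do not match genotypes")
  if (is.null(locus_ids))
    locus_ids <- paste0("snp", seq_len(ncol(genotypes)))
  locus_ids <- as.character(locus_ids)
  if (length(locus_ids) != ncol(genotypes))
    stop_bad("locus_ids length %d does not match L = %d",
             length(locus_ids), ncol(genotypes))
  if (anyDuplicated(locus_ids))
    stop_bad("duplicate locus id: %s", locus_ids[duplicated(locus_ids)][1L])
  obs <- genotypes[!missing_mask]
  if (anyNA(obs) || length(obs) && !all(obs %in% 0:2))
    stop_bad("non-missing genotype entries must be 0, 1 or 2")
  if (!is.null(phenotype)) {
    phenotype <- as.integer(phenotype)
    if (length(phenotype) != nrow(genotypes))
      stop_bad("phenotype length %d does not match N = %d",
               length(phenotype), nrow(genotypes))
    if (anyNA(phenotype) || !all(phenotype %in% 0:1))
      stop_bad("phenotype entries must be exactly 0 or 1")
  }
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 locus_ids = locus_ids, missing_mask = missing_mask),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  if (!is.null(x$phenotype))
    cat(sprintf("  cases: %d, controls: %d\n",
                sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  if (any(x$missing_mask))
    cat(sprintf("  missing entries: %d\n", sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$genotypes)

.missing_tokens <- c("NA", "-1")

#' Read case-control genotype data
#'
#' Two plain-text dialects are supported.
#' `tsv`: a header line `id<TAB>phenotype<TAB><locus ids...>` followed by one
#' row per individual with genotype tokens 0/1/2 and `NA` or `-1` for missing.
#' `plink_text`: a PLINK `.raw`-style additive-coded matrix (whitespace
#' separated; header with `IID` and `PHENOTYPE` columns, genotype columns
#' after the standard six; phenotypes coded 1/2 are recoded to 0/1).
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"plink_text"`.
#' @return a [genotype_table()] with missing entries flagged in
#'   `missing_mask`.
#' @export
read_genotype_table <- function(path, format = c("tsv", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  if (format == "tsv") .read_tsv_genotypes(path) else .read_plink_raw(path)
}

.read_tsv_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_bad("%s: need a header line and >= 1 row", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "id" || header[2L] != "phenotype")
    stop_bad("%s: header must start with 'id<TAB>phenotype<TAB>...'", path)
  locus_ids <- header[-(1:2)]
  if (anyDuplicated(locus_ids))
    stop_bad("%s: duplicate locus id '%s' in header",
             path, locus_ids[duplicated(locus_ids)][1L])
  L <- length(locus_ids)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n <- length(rows)
  geno <- matrix(NA_integer_, n, L)
  pheno <- integer(n)
  for (i in seq_len(n)) {
    row <- rows[[i]]
    if (length(row) != L + 2L)
      stop_bad("%s: row %d has %d fields, expected %d",
               path, i + 1L, length(row), L + 2L)
    if (!row[2L] %in% c("0", "1"))
      stop_bad("%s: row %d, column 2: phenotype token '%s' is not 0/1",
               path, i + 1L, row[2L])
    pheno[i] <- as.integer(row[2L])
    g <- row[-(1:2)]
    bad <- which(!g %in% c("0", "1", "2", .missing_tokens))
    if (length(bad))
      stop_bad("%s: row %d, column %d: genotype token '%s' is not 0/1/2/NA",
               path, i + 1L, bad[1L] + 2L, g[bad[1L]])
    g[g %in% .missing_tokens] <- NA_character_
    geno[i, ] <- as.integer(g)
  }
  genotype_table(geno, pheno, locus_ids)
}

.read_plink_raw <- function(path) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cn <- names(raw)
  if (!"PHENOTYPE" %in% cn)
    stop_bad("%s: PLINK text file lacks a PHENOTYPE column", path)
  first_geno <- match("PHENOTYPE", cn) + 1L
  if (first_geno > length(cn)) stop_bad("%s: no genotype columns", path)
  geno_cols <- cn[first_geno:length(cn)]
  geno <- as.matrix(raw[, geno_cols, drop = FALSE])
  dimnames(geno) <- NULL
  storage.mode(geno) <- "integer"
  pheno <- raw$PHENOTYPE
  if (all(pheno %in% c(1L, 2L))) pheno <- pheno - 1L  # PLINK 1/2 coding
  if (!all(pheno %in% 0:1))
    stop_bad("%s: PHENOTYPE values must be 0/1 or 1/2", path)
  if (!all(geno[!is.na(geno)] %in% 0:2))
    stop_bad("%s: genotype columns must hold additive codes 0/1/2", path)
  genotype_table(geno, pheno, geno_cols)
}

#' Write a genotype table in the TSV dialect
#'
#' Missing entries (if any) are written as `NA`.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(table$phenotype))
    stop_bad("cannot write a table without phenotype in the TSV dialect")
  g <- table$genotypes
  gs <- matrix(as.character(g), nrow(g), ncol(g))
  gs[is.na(g)] <- "NA"
  lines <- c(paste(c("id", "phenotype", table$locus_ids), collapse = "\t"),
             vapply(seq_len(nrow(g)), function(i) {
               paste(c(paste0("ind", i), table$phenotype[i], gs[i, ]),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Per-locus allele frequency of the coded (minor) allele
#'
#' Computed from non-missing genotypes only.
#'
#' @param table a [genotype_table()].
#' @return numeric vector of length L.
#' @export
allele_freq <- function(table) {
  g <- table$genotypes
  g[table$missing_mask] <- NA_integer_
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-locus minor allele frequency
#'
#' `min(f, 1 - f)` of the coded-allele frequency, so the value is always in
#' `[0, 0.5]` even if the coded allele drifted above frequency 0.5.
#'
#' @inheritParams allele_freq
#' @return numeric vector of length L.
#' @export
minor_allele_freq <- function(table) {
  f <- allele_freq(table)
  pmin(f, 1 - f)
}

#' Impute missing genotypes from marginal allele frequencies
#'
#' Each missing genotype is replaced by the sum of two independent allele
#' draws from the locus's empirical (non-missing) allele frequency, i.e. a
#' Hardy-Weinberg pairing of alleles drawn from the marginal allele
#' distribution of that SNP. Deterministic given `seed`. A complete table is
#' returned unchanged (and the RNG untouched).
#'
#' @param table a [genotype_table()].
#' @param seed integer seed.
#' @return a [genotype_table()] with `missing_mask` all `FALSE`.
#' @export
impute_missing <- function(table, seed = 1L) {
  stopifnot(inherits(table, "genotype_table"))
  if (!any(table$missing_mask)) return(table)
  g <- table$genotypes
  f <- allele_freq(table)
  need <- which(colSums(table$missing_mask) > 0L)
  if (any(!is.finite(f[need])))
    stop_bad("locus '%s' is entirely missing; cannot impute",
             table$locus_ids[need[!is.finite(f[need])][1L]])
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  for (j in need) {
    miss <- which(table$missing_mask[, j])
    g[miss, j] <- stats::rbinom(length(miss), 2L, f[j])
  }
  genotype_table(g, table$phenotype, table$locus_ids,
                 matrix(FALSE, nrow(g), ncol(g)))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
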