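#' Species-by-sample abundance tables
#'
#' `abundance_table()` builds the package's universal exchange object: a
#' non-negative integer count matrix with species as rows and samples as
#' columns, per-sample sequencing depths, and an optional cohort label per
#' sample (e.g. `"H"` / `"U"`).
#'
#' Depths are the per-sample totals of *classified reads*, i.e. the column
#' sums of the raw counts. They are stored separately so that zeroing
#' entries with [apply_cutoff()] leaves the relative-abundance denominator
#' unchanged: relative abundances are always counts divided by the original
#' classified-read total of the sample, never renormalized unless
#' explicitly requested.
#'
#' @param counts non-negative integer matrix, species x samples.
#' @param species_ids,sample_ids optional character labels; default to the
#'   dimnames of `counts` or generated `sp###` / `smp###` labels.
#' @param cohort optional per-sample cohort label (length 1 or R).
#' @param depths per-sample classified-read totals; defaults to
#'   `colSums(counts)`. Must be >= the column sums.
#'
#' @return An object of class `"abundance_table"`: a list with elements
#'   `counts`, `depths`, `cohort`, and `kappa` (the cutoff last applied,
#'   0 for raw tables).
#' @seealso [rel_abundance()], [apply_cutoff()], [read_table()]
#' @export
abundance_table <- function(counts, species_ids = NULL, sample_ids = NULL,
                            cohort = NULL, depths = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be numeric")
  if (any(!is.finite(counts))) stop("`counts` must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at row %d, column %d", bad[1L], bad[2L]))
  }
  counts <- round(counts)
  S <- nrow(counts)
  R <- ncol(counts)
  if (S == 0L || R == 0L) stop("empty table")
  if (is.null(species_ids)) {
    species_ids <- rownames(counts)
    if (is.null(species_ids)) species_ids <- sprintf("sp%03d", seq_len(S))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(counts)
    if (is.null(sample_ids)) sample_ids <- sprintf("smp%03d", seq_len(R))
  }
  if (anyDuplicated(species_ids)) stop("duplicate species IDs")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  dimnames(counts) <- list(species_ids, sample_ids)
  if (is.null(depths)) depths <- colSums(counts)
  depths <- as.numeric(depths)
  if (length(depths) != R) stop("`depths` must have one entry per sample")
  if (any(depths <= 0)) stop("all sample depths must be positive")
  if (any(colSums(counts) > depths + 1e-6)) {
    stop("`depths` must be >= the column sums of `counts`")
  }
  if (!is.null(cohort)) {
    cohort <- as.character(cohort)
    if (length(cohort) == 1L) cohort <- rep(cohort, R)
    if (length(cohort) != R) stop("`cohort` must have one label per sample")
  }
  structure(
    list(counts = counts, depths = depths, cohort = cohort, kappa = 0),
    class = "abundance_table"
  )
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' @export
print.abundance_table <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("abundance_table: %d species x %d samples\n", d[1L], d[2L]))
  cat(sprintf("  depths: %s .. %s reads/sample\n",
              format(min(x$depths), big.mark = ","),
              format(max(x$depths), big.mark = ",")))
  if (!is.null(x$cohort)) {
    tb <- table(x$cohort)
    cat("  cohorts:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (x$kappa > 0) cat(sprintf("  cutoff applied: kappa = %g\n", x$kappa))
  invisible(x)
}

#' Relative abundances of a count table
#'
#' Counts divided by the per-sample classified-read totals (`depths`).
#' Before any cutoff each column sums to 1; after [apply_cutoff()] the
#' removed mass is *not* redistributed, matching the convention of setting
#' sub-threshold abundances to zero without renormalization.
#'
#' @param x an [abundance_table()].
#' @return numeric matrix of the same shape as `x$counts`.
#' @export
rel_abundance <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  sweep(x$counts, 2L, x$depths, "/")
}

#' Zero out species abundances below a relative-abundance cutoff
#'
#' Entries with relative abundance below `kappa` are set to zero; all other
#' counts and the stored depths are unchanged, so downstream relative
#' abundances are not renormalized (set `renormalize = TRUE` to instead
#' recompute depths from the surviving counts). Species left with all-zero
#' rows are retained, so table dimensions are stable across cutoffs.
#'
#' The three cutoffs used throughout are available from [kappa_defaults()].
#'
#' @param x an [abundance_table()].
#' @param kappa relative-abundance threshold, >= 0.
#' @param renormalize recompute depths from the post-cutoff column sums?
#'   Default `FALSE`.
#' @return an [abundance_table()] with sub-threshold entries zeroed and
#'   `kappa` recorded.
#' @export
apply_cutoff <- function(x, kappa, renormalize = FALSE) {
  stopifnot(inherits(x, "abundance_table"), kappa >= 0)
  if (kappa == 0) return(x)
  v <- rel_abundance(x)
  cts <- x$counts
  cts[v < kappa] <- 0
  out <- x
  out$counts <- cts
  if (renormalize) {
    cs <- colSums(cts)
    if (any(cs <= 0)) stop("renormalization impossible: a sample lost all reads")
    out$depths <- cs
  }
  out$kappa <- max(x$kappa, kappa)
  out
}

#' The three standard relative-abundance cutoffs
#'
#' Low, medium and high detection cutoffs used to probe the effect of
#' false-positive species on macroecological patterns.
#'
#' @return named numeric vector `c(low = 4.5e-7, mid = 9e-6, high = 1.8e-4)`.
#' @export
kappa_defaults <- function() {
  c(low = 4.5e-7, mid = 9e-6, high = 1.8e-4)
}

# Drop species never observed (used before matched model generation, where
# the species pool is the gamma diversity of the data).
drop_absent_species <- function(x) {
  keep <- rowSums(x$counts) > 0
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}
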