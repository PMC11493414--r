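#' Read a species-by-sample count table
#'
#' TSV dialect: species as rows, samples as columns, first column the
#' species IDs, header line the sample IDs, tab-separated integer counts.
#' Column sums become the per-sample depths. BIOM 2.x files are read via
#' the `biomformat` package when available.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @param cohort optional per-sample cohort labels (length 1 or R, in
#'   column order).
#' @return an [abundance_table()].
#' @export
read_table <- function(path, format = c("auto", "tsv", "biom"),
                       cohort = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(abundance_table(m, cohort = cohort))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("empty table: need an ID column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("counts must be numeric")
  rownames(m) <- ids
  abundance_table(m, cohort = cohort)
}

#' Write a count table as TSV
#'
#' Inverse of [read_table()]'s TSV dialect; `write_table` then
#' `read_table` is the identity on valid tables, and round-trips valid
#' TSV inputs byte-identically. Cohort labels are not part of the format;
#' pass them to [read_table()] separately.
#'
#' @param x an [abundance_table()].
#' @param path output file.
#' @param id_column header of the species-ID column.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, id_column = "species_id") {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pattern curves as tidy TSV
#'
#' One row per curve point with columns `kind`, `kappa`, `cohort`, `x`,
#' `y`.
#'
#' @param curves a [pattern_curve()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pattern_curves <- function(curves, path) {
  if (inherits(curves, "pattern_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serializes the free parameters, the implied noise width, the MAD and
#' Taylor diagnostics, and the dimensions of a fitted model.
#'
#' @param fit a `model_fit` from [fit_model()].
#' @param path output file.
#' @param seed optional seed to record alongside the fit.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  rec <- list(
    model = fit$model,
    free_params = as.list(unlist(fit[free_params(fit)])),
    zeta = fit$zeta, sigma = fit$sigma,
    mad = list(family = fit$mad_fit$family, mu = fit$mad_fit$mu,
               lam = fit$mad_fit$lam, se_lam = fit$mad_fit$se_lam,
               bic_ratio = fit$mad_fit$bic_ratio,
               delta_bic = fit$mad_fit$delta_bic,
               n = fit$mad_fit$n, n_excluded = fit$mad_fit$n_excluded),
    taylor = list(zeta_free = fit$taylor_fit$zeta, A_free = fit$taylor_fit$A,
                  A_fixed = fit$taylor_fit$A_fixed,
                  r2_free = fit$taylor_fit$r2_free,
                  r2_fixed = fit$taylor_fit$r2_fixed,
                  ratio = fit$taylor_fit$ratio),
    S = fit$S, R = fit$R, seed = seed,
    package_version = as.character(utils::packageVersion("gutmacro"))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run configuration for the command-line pipeline
#'
#' Validates and freezes the knobs of a pipeline run; every CLI output
#' embeds the resolved configuration (and its MD5 hash) so runs are
#' reproducible byte-for-byte under the same seed.
#'
#' @param input input table path (or `NA` for generation runs).
#' @param models models to fit/compare.
#' @param cutoffs relative-abundance cutoffs, non-negative and sorted.
#' @param n_realizations realizations per comparison cell.
#' @param seed integer seed recorded in all outputs.
#' @param output_dir directory for outputs.
#' @param cohort optional cohort labels or label file.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(input = NA_character_,
                       models = c("mssd", "pslg", "md"),
                       cutoffs = kappa_defaults(), n_realizations = 500,
                       seed = 1L, output_dir = ".", cohort = NULL) {
  if (any(cutoffs < 0)) stop("cutoffs must be non-negative")
  if (is.unsorted(cutoffs)) stop("cutoffs must be sorted increasingly")
  structure(
    list(input = input, models = models, cutoffs = cutoffs,
         n_realizations = n_realizations, seed = as.integer(seed),
         output_dir = output_dir, cohort = cohort),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat("  input:", x$input, "\n")
  cat("  models:", paste(x$models, collapse = ","), "\n")
  cat("  cutoffs:", paste(signif(x$cutoffs, 3), collapse = ","), "\n")
  cat("  n_realizations:", x$n_realizations, " seed:", x$seed, "\n")
  cat("  hash:", config_hash(x), "\n")
  invisible(x)
}

#' MD5 hash of a run configuration
#'
#' @param config a [run_config()].
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}
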