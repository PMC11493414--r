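#' Macroecological pattern curves
#'
#' Lightweight container for an empirical or model-generated pattern: a
#' pattern kind, abscissa/ordinate arrays, and metadata (the cutoff under
#' which the table was thresholded and the cohort label).
#'
#' @param kind one of `"MAD"`, `"TL"`, `"SAD"`, `"AO"`, `"OCCUPANCY"`,
#'   `"SAR"`, `"DIVERSITY"`.
#' @param x,y coordinate arrays (equal length, finite `y`).
#' @param kappa cutoff under which the source table was computed.
#' @param cohort cohort label or `NA`.
#' @param ... extra named metadata (e.g. bin `edges`), stored as-is.
#' @return object of class `"pattern_curve"`.
#' @export
pattern_curve <- function(kind, x, y, kappa = 0, cohort = NA_character_, ...) {
  kind <- match.arg(kind, c("MAD", "TL", "SAD", "AO", "OCCUPANCY", "SAR",
                            "DIVERSITY"))
  stopifnot(length(x) == length(y), all(is.finite(y)))
  structure(
    c(list(kind = kind, x = as.numeric(x), y = as.numeric(y),
           kappa = kappa, cohort = cohort), list(...)),
    class = "pattern_curve"
  )
}

#' @export
print.pattern_curve <- function(x, ...) {
  cat(sprintf("pattern_curve: %s, %d points (kappa = %g, cohort = %s)\n",
              x$kind, length(x$x), x$kappa, x$cohort))
  invisible(x)
}

#' @export
as.data.frame.pattern_curve <- function(x, ...) {
  data.frame(kind = x$kind, kappa = x$kappa, cohort = x$cohort,
             x = x$x, y = x$y)
}

#' @export
plot.pattern_curve <- function(x, ..., log = if (x$kind %in% c("SAD", "AO")) "x" else "") {
  plot(x$x, x$y, type = "b", log = log, xlab = "x", ylab = "y",
       main = x$kind, ...)
  invisible(x)
}

table_cohort <- function(x) {
  if (is.null(x$cohort)) return(NA_character_)
  u <- unique(x$cohort)
  if (length(u) == 1L) u else NA_character_
}

#' Per-species mean relative abundance
#'
#' Arithmetic mean of the relative abundances across samples, zeros
#' included. Species that are all-zero (e.g. after a cutoff) get mean 0
#' and are excluded from downstream MAD fits.
#'
#' @param x an [abundance_table()].
#' @return named numeric vector, one entry per species.
#' @export
mean_abundance <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rowMeans(rel_abundance(x))
}

#' Per-species occupancy
#'
#' Fraction of samples in which a species has nonzero (post-cutoff)
#' abundance.
#'
#' @param x an [abundance_table()].
#' @return named numeric vector in `[0, 1]`.
#' @export
occupancy <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rowMeans(x$counts > 0)
}

#' Taylor's law points: across-sample mean and variance per species
#'
#' Computes, for each species, the mean and unbiased (n-1) variance of
#' its relative abundance across samples (zeros counted as true zeros).
#' Species with occupancy below `min_occupancy` are excluded by default:
#' for rare species, present in only a few samples, sampling noise blurs
#' the distinction between Poisson-like and Taylor-like scaling.
#'
#' @param x an [abundance_table()] with at least 2 samples.
#' @param min_occupancy occupancy threshold in `[0, 1]`; default 0.5.
#' @return data.frame with columns `species`, `mean`, `variance`,
#'   `occupancy`.
#' @export
taylor_points <- function(x, min_occupancy = 0.5) {
  stopifnot(inherits(x, "abundance_table"))
  if (ncol(x$counts) < 2L) stop("need at least 2 samples for a variance")
  if (min_occupancy < 0 || min_occupancy > 1) {
    stop("min_occupancy must lie in [0, 1]")
  }
  v <- rel_abundance(x)
  m <- rowMeans(v)
  s2 <- rowSums((v - m)^2) / (ncol(v) - 1L)
  occ <- rowMeans(x$counts > 0)
  keep <- occ >= min_occupancy
  data.frame(species = rownames(x$counts)[keep], mean = m[keep],
             variance = s2[keep], occupancy = occ[keep],
             row.names = NULL)
}

#' Alpha and gamma diversity
#'
#' `alpha`: number of species with nonzero counts in each sample (local
#' richness). `gamma`: number of species present in at least one sample
#' (metacommunity richness). Both depend strongly on the cutoff applied
#' beforehand.
#'
#' @param x an [abundance_table()].
#' @return list with `alpha` (length-R integer vector) and `gamma`
#'   (integer scalar).
#' @export
diversity <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  pres <- x$counts > 0
  list(alpha = colSums(pres), gamma = sum(rowSums(pres) > 0))
}

# Log-spaced bin edges covering positive values, with tiny padding so the
# extremes fall inside the outer bins.
log_edges <- function(vals, n_bins) {
  r <- range(vals)
  if (r[1L] == r[2L]) r <- r * c(0.5, 2)
  exp(seq(log(r[1L]) - 1e-9, log(r[2L]) + 1e-9, length.out = n_bins + 1L))
}

bin_index <- function(vals, edges) {
  findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Abundance-occupancy curve
#'
#' Relates a species' mean relative abundance to the fraction of samples
#' where it is detected (the intensity-sparsity relation). Returns the
#' binned summary curve (log-spaced bins over the positive mean
#' abundances, mean occupancy per bin; empty bins are dropped, not
#' interpolated) with the per-species scatter attached as the `points`
#' element and the bin `edges` recorded for reproducibility.
#'
#' @param x an [abundance_table()].
#' @param n_bins number of log-spaced bins (default 20).
#' @param edges optional explicit bin edges (overrides `n_bins`), e.g. to
#'   evaluate a model table on the empirical binning.
#' @return a [pattern_curve()] of kind `"AO"`; `x` holds geometric bin
#'   centers, `y` mean occupancy per bin.
#' @export
ao_curve <- function(x, n_bins = 20, edges = NULL) {
  vbar <- mean_abundance(x)
  occ <- occupancy(x)
  keep <- vbar > 0
  vbar <- vbar[keep]; occ <- occ[keep]
  if (!length(vbar)) stop("no species present")
  if (is.null(edges)) edges <- log_edges(vbar, n_bins)
  idx <- bin_index(vbar, edges)
  ybin <- tapply(occ, idx, mean)
  bins <- as.integer(names(ybin))
  centers <- sqrt(edges[-1L] * edges[-length(edges)])
  pattern_curve("AO", x = centers[bins], y = as.numeric(ybin),
                kappa = x$kappa, cohort = table_cohort(x),
                edges = edges, bins = bins,
                points = data.frame(mean = vbar, occupancy = occ))
}

#' Species abundance distribution
#'
#' Empirical distribution of nonzero relative abundances, log-binned.
#' With `scope = "metacommunity"` the per-sample relative abundances of
#' all species are pooled across samples; with `scope = "sample"` each
#' sample's histogram is computed on common bins and the bin masses are
#' averaged. In both cases the returned masses sum to 1.
#'
#' @param x an [abundance_table()].
#' @param scope `"metacommunity"` (pooled) or `"sample"` (averaged).
#' @param n_bins number of log-spaced bins.
#' @param edges optional explicit bin edges.
#' @return a [pattern_curve()] of kind `"SAD"`; `x` holds geometric bin
#'   centers, `y` the probability mass per (non-empty) bin.
#' @export
sad <- function(x, scope = c("metacommunity", "sample"), n_bins = 20,
                edges = NULL) {
  scope <- match.arg(scope)
  v <- rel_abundance(x)
  pos <- v[v > 0]
  if (!length(pos)) stop("no nonzero abundances")
  if (is.null(edges)) edges <- log_edges(pos, n_bins)
  centers <- sqrt(edges[-1L] * edges[-length(edges)])
  if (scope == "metacommunity") {
    idx <- bin_index(pos, edges)
    mass <- tabulate(idx, nbins = length(centers)) / length(pos)
  } else {
    per_sample <- apply(v, 2L, function(col) {
      p <- col[col > 0]
      if (!length(p)) return(rep(0, length(centers)))
      tabulate(bin_index(p, edges), nbins = length(centers)) / length(p)
    })
    mass <- rowMeans(per_sample)
  }
  keep <- mass > 0
  pattern_curve("SAD", x = centers[keep], y = mass[keep],
                kappa = x$kappa, cohort = table_cohort(x),
                edges = edges, bins = which(keep), scope = scope)
}

#' Metagenomic species-area relation
#'
#' Accumulates samples in random order and tracks the number of unique
#' species in the aggregated community, normalized by the gamma
#' diversity, as a function of the cumulative number of classified
#' reads. Both coordinates are averaged over `n_permutations` random
#' sample orderings; the final ordinate equals 1 exactly.
#'
#' @param x an [abundance_table()].
#' @param n_permutations number of random orderings to average (default 50).
#' @param seed optional integer seed.
#' @return a [pattern_curve()] of kind `"SAR"`; `x` holds mean cumulative
#'   reads, `y` mean normalized richness, one point per number of
#'   aggregated samples.
#' @export
sar_curve <- function(x, n_permutations = 50, seed = NULL) {
  stopifnot(inherits(x, "abundance_table"), n_permutations >= 1)
  pres <- x$counts > 0
  R <- ncol(pres)
  gam <- sum(rowSums(pres) > 0)
  if (gam == 0L) stop("no species present")
  with_seed(seed, {
    xs <- matrix(0, nrow = R, ncol = n_permutations)
    ys <- matrix(0, nrow = R, ncol = n_permutations)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(R)
      first <- apply(pres[, ord, drop = FALSE], 1L, function(z) match(TRUE, z))
      new_per_k <- tabulate(first[!is.na(first)], nbins = R)
      xs[, p] <- cumsum(x$depths[ord])
      ys[, p] <- cumsum(new_per_k) / gam
    }
    pattern_curve("SAR", x = rowMeans(xs), y = rowMeans(ys),
                  kappa = x$kappa, cohort = table_cohort(x),
                  n_permutations = n_permutations)
  })
}
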