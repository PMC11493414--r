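#' R-squared-like score between an empirical and a model pattern
#'
#' The standard coefficient-of-determination form
#' \deqn{1 - \sum_k (y^{emp}_k - y^{mod}_k)^2 /
#'           \sum_k (y^{emp}_k - \bar{y}^{emp})^2,}
#' computed after aligning the model curve onto the empirical abscissa by
#' linear interpolation in `log(x)` (extrapolation clamped to the nearest
#' model value). Identical curves score 1, a model curve equal to the
#' empirical mean scores 0, and badly wrong models can score arbitrarily
#' negative values.
#'
#' @param empirical,model [pattern_curve()] objects (or lists with `x`
#'   and `y`), `empirical` with non-constant `y`.
#' @return scalar score, at most 1.
#' @export
r2_like_score <- function(empirical, model) {
  ye <- empirical$y
  sstot <- sum((ye - mean(ye))^2)
  if (sstot == 0) stop("empirical pattern has zero variance: score undefined")
  if (length(model$x) == length(empirical$x) &&
      isTRUE(all.equal(model$x, empirical$x))) {
    ym <- model$y
  } else if (length(model$x) == 1L) {
    ym <- rep(model$y, length(empirical$x))
  } else {
    ym <- approx(log(model$x), model$y, xout = log(empirical$x),
                 rule = 2)$y
  }
  1 - sum((ye - ym)^2) / sstot
}

#' Rank-paired observed vs predicted occupancy
#'
#' Simulated species carry arbitrary labels, so occupancies are compared
#' after sorting both the empirical and the simulated species by their
#' mean relative abundance and pairing them by rank. With several model
#' tables, the predicted occupancy at each rank is averaged across
#' tables.
#'
#' @param empirical_table an [abundance_table()].
#' @param model_tables one [abundance_table()] or a list of them, each
#'   with the same number of species as `empirical_table`.
#' @return list with `pairs` (data.frame `observed`, `predicted`, sorted
#'   by increasing empirical mean abundance) and `score` (the
#'   [r2_like_score()] of predicted against observed occupancy).
#' @export
predicted_occupancy <- function(empirical_table, model_tables) {
  if (inherits(model_tables, "abundance_table")) {
    model_tables <- list(model_tables)
  }
  S <- nrow(empirical_table$counts)
  obs <- occupancy(empirical_table)[order(mean_abundance(empirical_table))]
  preds <- vapply(model_tables, function(tab) {
    if (nrow(tab$counts) != S) {
      stop("species-count mismatch between empirical and model tables")
    }
    occupancy(tab)[order(mean_abundance(tab))]
  }, numeric(S))
  pred <- rowMeans(preds)
  pairs <- data.frame(observed = unname(obs), predicted = unname(pred))
  score <- r2_like_score(list(x = seq_len(S), y = pairs$observed),
                         list(x = seq_len(S), y = pairs$predicted))
  list(pairs = pairs, score = score)
}

# Patterns of one table, evaluated on the empirical binning where the
# pattern is binned, plus everything needed for scoring.
score_one <- function(pattern, emp, emp_patt, tab_k, sar_permutations,
                      sar_seed) {
  switch(pattern,
    AO = r2_like_score(emp_patt$AO, ao_curve(tab_k, edges = emp_patt$AO$edges)),
    SAD = r2_like_score(emp_patt$SAD, sad(tab_k, edges = emp_patt$SAD$edges)),
    SAR = r2_like_score(emp_patt$SAR,
                        sar_curve(tab_k, n_permutations = sar_permutations,
                                  seed = sar_seed)),
    OCCUPANCY = predicted_occupancy(emp, list(tab_k))$score,
    DIVERSITY = {
      dv <- diversity(tab_k)
      ym <- c(sort(dv$alpha), dv$gamma)
      ye <- emp_patt$DIVERSITY
      r2_like_score(list(x = seq_along(ye), y = ye),
                    list(x = seq_along(ym), y = ym))
    },
    stop("unknown pattern: ", pattern)
  )
}

#' Compare generative models against a count table
#'
#' The model-comparison protocol: each model is fitted to the (uncut)
#' table, `n_realizations` matched tables are generated per model (same
#' species pool `S = gamma`, same number of samples, and the empirical
#' per-sample depth vector verbatim), each relative-abundance cutoff is
#' applied to both the empirical and the simulated tables, every
#' requested pattern is computed on both, scored with
#' [r2_like_score()] (occupancy via [predicted_occupancy()], diversity
#' on the sorted per-sample alpha vector with gamma appended), and the
#' scores are averaged over realizations. If the table carries more than
#' one cohort label, each cohort is processed independently.
#'
#' The whole run is deterministic under a fixed `seed`, and the output
#' does not depend on the order in which models are listed.
#'
#' @param table an [abundance_table()] with no cutoff applied.
#' @param models subset of `c("mssd", "pslg", "md")`.
#' @param cutoffs relative-abundance cutoffs (default [kappa_defaults()]).
#' @param n_realizations model realizations per cell (default 500; use
#'   ~20 for quick profiles).
#' @param seed optional integer master seed.
#' @param patterns subset of
#'   `c("AO", "OCCUPANCY", "SAR", "SAD", "DIVERSITY")`.
#' @param sar_permutations sample orderings per SAR curve.
#' @param mad_family passed to [fit_model()].
#' @return a `score_report` data.frame: `cohort`, `model`, `pattern`,
#'   `kappa`, `score_mean`, `score_sd`, `n_realizations`.
#' @export
compare_models <- function(table, models = c("mssd", "pslg", "md"),
                           cutoffs = kappa_defaults(), n_realizations = 500,
                           seed = NULL,
                           patterns = c("AO", "OCCUPANCY", "SAR", "SAD",
                                        "DIVERSITY"),
                           sar_permutations = 20,
                           mad_family = "log_laplace") {
  stopifnot(inherits(table, "abundance_table"), n_realizations >= 1)
  models <- sort(match.arg(models, several.ok = TRUE))
  patterns <- match.arg(patterns, several.ok = TRUE)
  if (is.null(names(cutoffs))) names(cutoffs) <- sprintf("kappa=%g", cutoffs)
  cohorts <- if (is.null(table$cohort)) NA_character_ else unique(table$cohort)
  rows <- list()
  for (co in cohorts) {
    sub <- table
    if (!is.na(co)) {
      keep <- table$cohort == co
      sub$counts <- table$counts[, keep, drop = FALSE]
      sub$depths <- table$depths[keep]
      sub$cohort <- table$cohort[keep]
    }
    emp0 <- drop_absent_species(sub)
    seeds <- matrix(derive_seeds(seed, length(models) * (n_realizations + 1L)),
                    nrow = length(models),
                    dimnames = list(models, NULL))
    # empirical patterns per cutoff (SAR seed shared across models)
    emp_cut <- lapply(cutoffs, function(k) apply_cutoff(emp0, k))
    emp_patt <- lapply(seq_along(cutoffs), function(ki) {
      ek <- emp_cut[[ki]]
      out <- list()
      if ("AO" %in% patterns) out$AO <- ao_curve(ek)
      if ("SAD" %in% patterns) out$SAD <- sad(ek)
      if ("SAR" %in% patterns) {
        out$SAR <- sar_curve(ek, n_permutations = sar_permutations,
                             seed = seeds[1L, n_realizations + 1L])
      }
      if ("DIVERSITY" %in% patterns) {
        dv <- diversity(ek)
        out$DIVERSITY <- c(sort(dv$alpha), dv$gamma)
      }
      out
    })
    for (mo in models) {
      fit <- fit_model(emp0, model = mo, mad_family = mad_family)
      sc <- array(NA_real_,
                  dim = c(length(patterns), length(cutoffs), n_realizations),
                  dimnames = list(patterns, names(cutoffs), NULL))
      for (i in seq_len(n_realizations)) {
        tab <- sample_model(fit, seed = seeds[mo, i])
        for (ki in seq_along(cutoffs)) {
          tab_k <- apply_cutoff(tab, cutoffs[[ki]])
          for (pa in patterns) {
            sc[pa, ki, i] <- score_one(pa, emp_cut[[ki]], emp_patt[[ki]],
                                       tab_k, sar_permutations,
                                       sar_seed = seeds[mo, i])
          }
        }
      }
      for (ki in seq_along(cutoffs)) {
        for (pa in patterns) {
          rows[[length(rows) + 1L]] <- data.frame(
            cohort = co, model = mo, pattern = pa,
            kappa = unname(cutoffs[[ki]]),
            score_mean = mean(sc[pa, ki, ]),
            score_sd = if (n_realizations > 1L) sd(sc[pa, ki, ]) else NA_real_,
            n_realizations = n_realizations
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_report", class(out))
  out
}

#' @export
print.score_report <- function(x, digits = 3, ...) {
  cat("Model-vs-data R2-like scores (mean over realizations)\n")
  wide <- score_report_wide(x, digits = digits)
  print.data.frame(wide, row.names = FALSE)
  invisible(x)
}

# Wide layout: rows cohort x model, columns pattern x kappa.
score_report_wide <- function(x, digits = 3) {
  x <- as.data.frame(x)
  x$col <- sprintf("%s.k%g", x$pattern, x$kappa)
  ids <- unique(x[, c("cohort", "model")])
  cols <- unique(x$col)
  out <- ids
  for (cc in cols) {
    out[[cc]] <- vapply(seq_len(nrow(ids)), function(i) {
      m <- x$score_mean[x$cohort == ids$cohort[i] & x$model == ids$model[i] &
                          x$col == cc]
      if (length(m)) round(m, digits) else NA_real_
    }, numeric(1L))
  }
  out
}

#' Write a score report as a wide TSV
#'
#' Rows are cohort x model, columns pattern x cutoff, mirroring the
#' usual presentation of pattern-score tables.
#'
#' @param x a `score_report` from [compare_models()].
#' @param path output file.
#' @param digits rounding for the scores.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(x, path, digits = 4) {
  wide <- score_report_wide(x, digits = digits)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
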