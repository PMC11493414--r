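#' Specification of a constrained compositional generative model
#'
#' Bundles one of the three generative models with its free parameters and
#' the dimensions of the tables it generates:
#'
#' * `"md"` — Multinomial Dirichlet: Dirichlet compositions with
#'   `alpha_i = xbar_i / A` (Taylor exponent `zeta = 1`, Poisson-like
#'   mean-variance scaling), then multinomial sampling at depth `N_r`.
#' * `"mssd"` — Multinomial Symmetric Scaled Dirichlet: Symmetric Scaled
#'   Dirichlet compositions (`alpha = 1/A` constant, `beta_i` proportional
#'   to `1/xbar_i`; `zeta = 2`), then multinomial sampling. Strictly
#'   compositional. Because the law is invariant under rescaling of the
#'   rates, the MAD location `mu` drops out and the model has exactly two
#'   free parameters, `lam` and `A`.
#' * `"pslg"` — Poisson Stochastic Logistic Growth: independent Gamma
#'   abundances with the `zeta = 2` parameters and mean abundances
#'   normalized to sum to one, then independent Poisson sampling of
#'   counts; compositional only on average.
#'
#' The free-parameter count is 3 (`mu`, `lam`, `A`) for MD and PSLG and 2
#' (`lam`, `A`) for MSSD; see [free_params()].
#'
#' @param model `"mssd"`, `"pslg"` or `"md"`.
#' @param lam MAD scale (log-abundance units), > 0.
#' @param A Taylor's law amplitude, > 0.
#' @param mu MAD location (log-abundance units). Required for MD and PSLG;
#'   ignored by MSSD (defaults to 0 there).
#' @param S number of species.
#' @param R number of samples.
#' @param depths per-sample read totals `N_r` (length 1 or R).
#' @param mad_family MAD family used when drawing mean abundances.
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(model = c("mssd", "pslg", "md"), lam, A, mu = NULL,
                       S, R, depths,
                       mad_family = c("log_laplace", "log_normal")) {
  model <- match.arg(model)
  mad_family <- match.arg(mad_family)
  if (lam <= 0) stop("lam must be > 0")
  if (A <= 0) stop("A must be > 0")
  if (is.null(mu)) {
    if (model != "mssd") stop("mu is required for MD and PSLG")
    mu <- 0
  }
  S <- as.integer(S); R <- as.integer(R)
  if (S < 2L || R < 1L) stop("need S >= 2 species and R >= 1 samples")
  depths <- rep_len(as.numeric(depths), R)
  if (any(depths < 1)) stop("depths must be positive read totals")
  zeta <- if (model == "md") 1 else 2
  structure(
    list(model = model, mu = mu, lam = lam, A = A, zeta = zeta,
         S = S, R = R, depths = depths, mad_family = mad_family),
    class = "model_spec"
  )
}

#' Names of the independently fitted parameters of a model
#'
#' @param spec a [model_spec()].
#' @return character vector: `c("mu","lam","A")` for MD and PSLG,
#'   `c("lam","A")` for MSSD.
#' @export
free_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model == "mssd") c("lam", "A") else c("mu", "lam", "A")
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- c(mssd = "Multinomial Symmetric Scaled Dirichlet",
           pslg = "Poisson Stochastic Logistic Growth",
           md = "Multinomial Dirichlet")[[x$model]]
  cat(sprintf("model_spec: %s (zeta = %d)\n", lab, x$zeta))
  fp <- free_params(x)
  vals <- unlist(x[fp])
  cat("  free parameters:",
      paste(sprintf("%s = %.4g", fp, vals), collapse = ", "), "\n")
  if (x$zeta == 2) {
    cat(sprintf("  implied noise width sigma = %.4g\n", sigma_from_A(x$A)))
  }
  cat(sprintf("  dimensions: S = %d species, R = %d samples, depths %s..%s\n",
              x$S, x$R, format(min(x$depths), big.mark = ","),
              format(max(x$depths), big.mark = ",")))
  invisible(x)
}

# Draw the S mean abundances of one realization from the spec's MAD.
draw_mad_means <- function(spec) {
  rmad(spec$S, family = spec$mad_family, mu = spec$mu, lam = spec$lam)
}

#' Generate a count table from a fitted or hand-built model
#'
#' The operative sampling procedure shared by the three models:
#' 1. take the free parameters (`mu`, `lam`, `A`) from the spec;
#' 2. draw `S` mean abundances from the MAD;
#' 3. build the per-species Gamma parameters via [params_from_taylor()]
#'    with the model's Taylor exponent;
#' 4. draw `R` compositions (Dirichlet / Symmetric Scaled Dirichlet /
#'    independent Gammas);
#' 5. sample counts (multinomial at depth `N_r` for MD and MSSD, Poisson
#'    with intensity `N_r v_i` for PSLG).
#'
#' Cutoffs are *not* applied here: generation always uses the full
#' composition, and thresholding is applied afterwards with
#' [apply_cutoff()], mirroring the order of the data-processing pipeline.
#'
#' `sample_md()`, `sample_mssd()` and `sample_pslg()` are strict wrappers
#' that additionally check the spec's model tag.
#'
#' @param spec a [model_spec()].
#' @param seed optional integer seed.
#' @param xbar optional vector of `S` mean abundances, bypassing step 2
#'   (useful for controlled experiments).
#' @return an [abundance_table()]; for MD/MSSD column sums equal the
#'   depths exactly, for PSLG only on average (realized column sums are
#'   stored as depths, the intended `N_r` as attribute `target_depths`).
#' @export
sample_model <- function(spec, seed = NULL, xbar = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    if (is.null(xbar)) xbar <- draw_mad_means(spec)
    if (length(xbar) != spec$S) stop("xbar must have length S")
    if (any(xbar <= 0)) stop("xbar must be positive")
    depths <- spec$depths
    if (spec$model == "pslg") {
      vbar <- xbar / sum(xbar)  # mean abundances constrained to sum to 1
      gp <- params_from_taylor(vbar, spec$A, zeta = 2)
      v <- t(sample_scaled_dirichlet_raw(gp, spec$R))
      cts <- matrix(rpois(spec$S * spec$R,
                          lambda = sweep(v, 2L, depths, "*")),
                    nrow = spec$S)
      tab <- abundance_table(cts, cohort = NULL)
      attr(tab, "target_depths") <- depths
      return(tab)
    }
    if (spec$model == "md") {
      # alpha_i = xbar_i / A with xbar on the relative-abundance scale
      # (data-fitted means sum to one); MSSD is invariant to this rescaling.
      xbar <- xbar / sum(xbar)
    }
    gp <- params_from_taylor(xbar, spec$A, zeta = spec$zeta)
    v <- t(sample_scaled_dirichlet(gp, spec$R))
    cts <- matrix(0, nrow = spec$S, ncol = spec$R)
    for (r in seq_len(spec$R)) {
      cts[, r] <- rmultinom(1L, size = depths[r], prob = v[, r])
    }
    abundance_table(cts, depths = depths)
  })
}

# Independent Gamma draws *without* normalization (PSLG abundances).
sample_scaled_dirichlet_raw <- function(params, n_samples) {
  S <- length(params$alpha)
  matrix(rgamma(n_samples * S, shape = rep(params$alpha, each = n_samples),
                rate = rep(params$beta, each = n_samples)),
         nrow = n_samples, ncol = S)
}

#' @rdname sample_model
#' @export
sample_md <- function(spec, seed = NULL, xbar = NULL) {
  stopifnot(spec$model == "md")
  sample_model(spec, seed = seed, xbar = xbar)
}

#' @rdname sample_model
#' @export
sample_mssd <- function(spec, seed = NULL, xbar = NULL) {
  stopifnot(spec$model == "mssd")
  sample_model(spec, seed = seed, xbar = xbar)
}

#' @rdname sample_model
#' @export
sample_pslg <- function(spec, seed = NULL, xbar = NULL) {
  stopifnot(spec$model == "pslg")
  sample_model(spec, seed = seed, xbar = xbar)
}

#' Simulate method for fitted model specifications
#'
#' Generates `nsim` independent count tables from the model, in the sense
#' of [stats::simulate()].
#'
#' @param object a [model_spec()].
#' @param nsim number of tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [abundance_table()] objects.
#' @export
simulate.model_spec <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- derive_seeds(seed, nsim)
  lapply(seq_len(nsim), function(i) {
    sample_model(object, seed = if (is.null(seed)) NULL else seeds[i])
  })
}
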