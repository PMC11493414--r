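#' Scaled Dirichlet log density
#'
#' Density on the open (S-1)-simplex of the relative abundances
#' \eqn{v_i = x_i / \sum_j x_j} of independent Gamma variables
#' \eqn{x_i \sim \Gamma(\alpha_i, \beta_i)}:
#' \deqn{P(v|\alpha,\beta) = \frac{1}{Z(\alpha,\beta)}
#'   \frac{\prod_i v_i^{\alpha_i - 1}}{(\sum_i \beta_i v_i)^{\alpha_0}},}
#' with \eqn{\alpha_0 = \sum_i \alpha_i} and normalization
#' \eqn{Z = B(\alpha) / \prod_i \beta_i^{\alpha_i}} (S-variate Beta
#' function). The density is invariant under a common rescaling of the
#' rates (`beta -> c * beta`), and reduces to the ordinary Dirichlet when
#' all rates are equal.
#'
#' @param v composition: vector (or matrix, one composition per row) on
#'   the open simplex.
#' @param params a [gamma_params()] of matching dimension.
#' @param tol tolerance on `sum(v) == 1`.
#' @return log density value(s).
#' @export
scaled_dirichlet_logpdf <- function(v, params, tol = 1e-8) {
  stopifnot(inherits(params, "gamma_params"))
  a <- params$alpha; b <- params$beta
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != length(a)) stop("dimension mismatch between v and params")
  if (any(v <= 0)) stop("v must lie in the open simplex (all components > 0)")
  if (any(abs(rowSums(v) - 1) > tol)) stop("v components must sum to 1")
  a0 <- sum(a)
  log_z <- sum(lgamma(a)) - lgamma(a0) - sum(a * log(b))
  out <- drop(log(v) %*% (a - 1)) - a0 * log(drop(v %*% b)) - log_z
  unname(out)
}

#' Sample from the Scaled Dirichlet distribution
#'
#' Draws compositions by normalizing independent Gamma variables
#' \eqn{x_i \sim \Gamma(\alpha_i, \beta_i)}, the construction under which
#' the joint law of \eqn{v = x/\sum x} is exactly the Scaled Dirichlet of
#' [scaled_dirichlet_logpdf()].
#'
#' @param params a [gamma_params()].
#' @param n_samples number of compositions to draw.
#' @param seed optional integer seed.
#' @return `n_samples` x S matrix; each row sums to 1.
#' @export
sample_scaled_dirichlet <- function(params, n_samples, seed = NULL) {
  stopifnot(inherits(params, "gamma_params"), n_samples >= 1)
  S <- length(params$alpha)
  with_seed(seed, {
    x <- matrix(rgamma(n_samples * S, shape = rep(params$alpha, each = n_samples),
                       rate = rep(params$beta, each = n_samples)),
                nrow = n_samples, ncol = S)
    x / rowSums(x)
  })
}
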