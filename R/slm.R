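#' Stochastic logistic model parameters
#'
#' Container for the per-species parameters of the stochastic logistic
#' model (SLM)
#' \deqn{dx/dt = (x/\tau)(1 - x/K) + \sqrt{\sigma/\tau}\, x\, \xi(t),}
#' where `K` is the carrying capacity (relative-abundance scale), `sigma`
#' the width of the environmental noise and `tau` the growth timescale.
#' `tau` only sets the relaxation speed; every stationary quantity in the
#' package ignores it and it is consumed only by [simulate_slm()].
#'
#' A stationary distribution exists only for `0 < sigma < 2`; at
#' stationarity the abundance of each species fluctuates across samples
#' following a Gamma distribution (see [gamma_from_slm()]).
#'
#' @param K carrying capacity, > 0 (vectorized over species).
#' @param sigma environmental noise width, in (0, 2).
#' @param tau growth timescale, > 0; irrelevant at stationarity.
#' @return object of class `"slm_params"`.
#' @export
slm_params <- function(K, sigma, tau = 1) {
  n <- max(length(K), length(sigma), length(tau))
  K <- rep_len(as.numeric(K), n)
  sigma <- rep_len(as.numeric(sigma), n)
  tau <- rep_len(as.numeric(tau), n)
  if (any(K <= 0)) stop("K must be > 0")
  if (any(sigma <= 0) || any(sigma >= 2)) {
    stop("sigma must lie in (0, 2): no stationary distribution otherwise")
  }
  if (any(tau <= 0)) stop("tau must be > 0")
  structure(list(K = K, sigma = sigma, tau = tau), class = "slm_params")
}

#' Gamma (shape, rate) parameters of abundance fluctuations
#'
#' @param alpha Gamma shape per species, > 0.
#' @param beta Gamma rate per species, > 0 (units of inverse relative
#'   abundance).
#' @return object of class `"gamma_params"`.
#' @export
gamma_params <- function(alpha, beta) {
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(as.numeric(alpha), n)
  beta <- rep_len(as.numeric(beta), n)
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(beta <= 0)) stop("beta must be > 0")
  structure(list(alpha = alpha, beta = beta), class = "gamma_params")
}

#' Stationary Gamma distribution of the stochastic logistic model
#'
#' Maps ecological parameters (K, sigma) to the (shape, rate) of the
#' stationary abundance-fluctuation distribution:
#' \deqn{\alpha = (2-\sigma)/\sigma, \qquad \beta = 2/(\sigma K),}
#' with implied mean \eqn{K(1-\sigma/2)} and variance
#' \eqn{K^2 (\sigma/2)(1-\sigma/2)}. For `sigma < 1` the shape exceeds 1
#' and the distribution is modal away from zero; for `sigma > 1` it
#' diverges at zero, so rarity (and local extinction under sampling) is
#' much more likely.
#'
#' @param params an [slm_params()].
#' @return a [gamma_params()].
#' @export
gamma_from_slm <- function(params) {
  stopifnot(inherits(params, "slm_params"))
  gamma_params(alpha = (2 - params$sigma) / params$sigma,
               beta = 2 / (params$sigma * params$K))
}

#' Recover (K, sigma) from stationary Gamma parameters
#'
#' Inverse of [gamma_from_slm()]: `sigma = 2/(alpha+1)`,
#' `K = 2/(sigma*beta)`.
#'
#' @param params a [gamma_params()].
#' @param tau growth timescale for the returned [slm_params()].
#' @return an [slm_params()].
#' @export
slm_from_gamma <- function(params, tau = 1) {
  stopifnot(inherits(params, "gamma_params"))
  sigma <- 2 / (params$alpha + 1)
  slm_params(K = 2 / (sigma * params$beta), sigma = sigma, tau = tau)
}

#' Environmental noise width from the Taylor amplitude
#'
#' Under Taylor's law with exponent 2 the Gamma shape is constant across
#' species and equals `1/A`, so `alpha = (2 - sigma)/sigma = 1/A` inverts
#' to `sigma = 2A/(1 + A)`. The map is strictly increasing with range
#' (0, 2); `A = 1` corresponds to the `sigma = 1` boundary separating
#' modal (healthy-like) from zero-diverging (dysbiotic-like) abundance
#' fluctuation distributions.
#'
#' @param A Taylor's law amplitude, > 0.
#' @return noise width sigma in (0, 2).
#' @seealso [A_from_sigma()]
#' @export
sigma_from_A <- function(A) {
  if (any(A <= 0)) stop("A must be > 0")
  2 * A / (1 + A)
}

#' @rdname sigma_from_A
#' @param sigma noise width in (0, 2).
#' @export
A_from_sigma <- function(sigma) {
  if (any(sigma <= 0) || any(sigma >= 2)) stop("sigma must lie in (0, 2)")
  sigma / (2 - sigma)
}

#' Per-species Gamma parameters from Taylor's law
#'
#' Given the mean abundances and a Taylor's law
#' \eqn{\sigma_x^2 = A \bar{x}^\zeta}, the 2S Gamma parameters reduce to
#' \deqn{\alpha_i = \bar{x}_i^{2-\zeta}/A, \qquad
#'       \beta_i = \bar{x}_i^{1-\zeta}/A.}
#' For `zeta = 2` all shapes collapse to the constant `1/A` (the Symmetric
#' Scaled Dirichlet case); for `zeta = 1` all rates are equal and cancel,
#' leaving the ordinary Dirichlet.
#'
#' @param mean_abundances per-species mean (relative) abundances, > 0.
#' @param A Taylor amplitude, > 0.
#' @param zeta Taylor exponent, 1 or 2.
#' @return a [gamma_params()].
#' @export
params_from_taylor <- function(mean_abundances, A, zeta) {
  if (any(mean_abundances <= 0)) stop("mean abundances must be > 0")
  if (length(A) != 1L || A <= 0) stop("A must be a single value > 0")
  if (!zeta %in% c(1, 2)) stop("zeta must be 1 or 2")
  gamma_params(alpha = mean_abundances^(2 - zeta) / A,
               beta = mean_abundances^(1 - zeta) / A)
}

#' Simulate the stochastic logistic model
#'
#' Integrates the SLM under the Ito convention with an Euler-Maruyama
#' scheme applied to the exactly transformed log-abundance equation
#' \deqn{d\log x = [(1 - x/K)/\tau - \sigma/(2\tau)]\,dt +
#'       \sqrt{\sigma/\tau}\,dW,}
#' which preserves positivity and remains stable when `sigma > 1` and
#' trajectories spend long stretches near zero. The stationary histogram
#' is consistent with the analytic Gamma of [gamma_from_slm()].
#'
#' @param params an [slm_params()] describing one species.
#' @param dt integration step, in units of `tau` (must satisfy `dt << tau`).
#' @param t_max total integration time.
#' @param seed optional integer seed.
#' @param n_reps number of independent replica trajectories.
#' @param x0 initial abundance (> 0); defaults to `K`.
#' @param record_every record the state every this many steps.
#' @return list with `time` (recorded times) and `x` (matrix, one column
#'   per replica).
#' @export
simulate_slm <- function(params, dt, t_max, seed = NULL, n_reps = 1L,
                         x0 = NULL, record_every = 1L) {
  stopifnot(inherits(params, "slm_params"))
  K <- params$K[1L]; sigma <- params$sigma[1L]; tau <- params$tau[1L]
  if (dt <= 0 || dt > tau / 10) stop("need 0 < dt <= tau/10")
  if (is.null(x0)) x0 <- K
  if (any(x0 <= 0)) stop("x0 must be > 0")
  n_steps <- max(1L, ceiling(t_max / dt))
  n_rec <- n_steps %/% record_every
  with_seed(seed, {
    y <- rep_len(log(x0), n_reps)
    out <- matrix(NA_real_, nrow = n_rec, ncol = n_reps)
    sig_dw <- sqrt(sigma / tau * dt)
    drift0 <- (1 - sigma / 2) / tau
    j <- 0L
    for (s in seq_len(n_steps)) {
      y <- y + (drift0 - exp(y) / (K * tau)) * dt + sig_dw * rnorm(n_reps)
      if (!all(is.finite(y))) {
        stop("SLM integration diverged; reduce dt")
      }
      if (s %% record_every == 0L) {
        j <- j + 1L
        out[j, ] <- exp(y)
      }
    }
    list(time = dt * record_every * seq_len(n_rec), x = out)
  })
}

#' Approximate stationary sample of the stochastic logistic model
#'
#' Runs `n` independent replicas of [simulate_slm()] for `burn`
#' relaxation times and returns the final abundances: an i.i.d. sample
#' from the (numerically) stationary law, suitable for comparison with
#' the analytic Gamma distribution.
#'
#' @inheritParams simulate_slm
#' @param n number of independent stationary draws.
#' @param burn burn-in, in units of `tau`.
#' @return numeric vector of length `n`.
#' @export
slm_stationary_sample <- function(params, n, dt = 0.01, burn = 30,
                                  seed = NULL) {
  tau <- params$tau[1L]
  sim <- simulate_slm(params, dt = dt * tau, t_max = burn * tau,
                      seed = seed, n_reps = n,
                      record_every = max(1L, ceiling(burn / dt) ))
  as.numeric(sim$x[nrow(sim$x), ])
}
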