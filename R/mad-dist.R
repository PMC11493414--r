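#' Heavy-tailed mean abundance distributions
#'
#' The across-species distribution of mean (relative) abundances (MAD) is
#' modeled on the log scale: `log(xbar)` follows either a Laplace
#' (`"log_laplace"`) or a Normal (`"log_normal"`) law with location `mu`
#' and scale `lam`. Both yield heavy-tailed abundance distributions; the
#' Log-Laplace tail is the heavier (its moments beyond order `1/lam`
#' diverge).
#'
#' @param n number of draws.
#' @param family `"log_laplace"` or `"log_normal"`.
#' @param mu location of `log(xbar)`.
#' @param lam scale of `log(xbar)`, > 0.
#' @return `rmad`: positive numeric vector of mean abundances.
#'   `dmad_log`: density of `y = log(xbar)` at `y`.
#' @export
rmad <- function(n, family = c("log_laplace", "log_normal"), mu, lam) {
  family <- match.arg(family)
  if (lam <= 0) stop("lam must be > 0")
  z <- switch(family,
    log_laplace = rexp(n) * sample(c(-1, 1), n, replace = TRUE),
    log_normal = rnorm(n)
  )
  exp(mu + lam * z)
}

#' @rdname rmad
#' @param y log mean abundances.
#' @export
dmad_log <- function(y, family = c("log_laplace", "log_normal"), mu, lam) {
  family <- match.arg(family)
  switch(family,
    log_laplace = exp(-abs(y - mu) / lam) / (2 * lam),
    log_normal = dnorm(y, mean = mu, sd = lam)
  )
}
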