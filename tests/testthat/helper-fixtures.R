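# Small deterministic fixtures and independent oracles shared by tests.

toy_table <- function() {
  # 3 species x 2 samples; species 3 absent everywhere
  abundance_table(
    matrix(c(1, 0, 2, 3, 0, 0), nrow = 3, byrow = TRUE,
           dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  )
}

random_table <- function(S = 5, R = 4, max_count = 50, seed = 1) {
  gutmacro:::with_seed(seed, {
    m <- matrix(rpois(S * R, max_count / 2), nrow = S)
    m[1L, ] <- m[1L, ] + 1L  # guarantee positive depths
    abundance_table(m)
  })
}

mssd_test_table <- function(S = 300, R = 80, lam = 1.4, A = 0.5,
                            depth = 1e5, seed = 7) {
  spec <- model_spec("mssd", lam = lam, A = A, mu = -9, S = S, R = R,
                     depths = depth)
  sample_mssd(spec, seed = seed)
}

# Dirichlet log density (independent of the package's scaled form).
dirichlet_logpdf <- function(v, alpha) {
  sum((alpha - 1) * log(v)) - (sum(lgamma(alpha)) - lgamma(sum(alpha)))
}

# Numeric CDF of the first component of an S=2 scaled Dirichlet, built by
# quadrature on the package density (used as a distributional oracle for
# the sampler).
sd2_cdf <- function(params, n_grid = 4001) {
  grid <- seq(1e-7, 1 - 1e-7, length.out = n_grid)
  dens <- exp(scaled_dirichlet_logpdf(cbind(grid, 1 - grid), params))
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  function(q) approx(grid, cdf, xout = q, rule = 2)$y
}

# Numeric CDF of v1 for an S=3 scaled Dirichlet: for each v1, integrate
# the density over v2 in (0, 1 - v1), then accumulate over v1.
sd3_cdf_v1 <- function(params, n_grid = 201) {
  v1s <- seq(1e-5, 1 - 1e-5, length.out = n_grid)
  marg <- vapply(v1s, function(v1) {
    f <- function(v2) {
      vv <- cbind(v1, v2, 1 - v1 - v2)
      exp(scaled_dirichlet_logpdf(vv, params))
    }
    integrate(f, 1e-9, 1 - v1 - 1e-9, rel.tol = 1e-8)$value
  }, numeric(1L))
  cdf <- cumsum(marg)
  cdf <- cdf / cdf[length(cdf)]
  function(q) approx(v1s, cdf, xout = q, rule = 2)$y
}

ks_distance <- function(x, cdf_fun) {
  n <- length(x)
  Fx <- cdf_fun(sort(x))
  max(pmax(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n)))
}
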