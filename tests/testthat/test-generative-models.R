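test_that("stationary Gamma parameters follow from the SLM parameters", {
  g <- gamma_from_slm(slm_params(K = 1, sigma = 1))
  expect_equal(g$alpha, 1)
  expect_equal(g$beta, 2)

  g <- gamma_from_slm(slm_params(K = 10, sigma = 2 / 3))
  expect_equal(g$alpha, 2)
  expect_equal(g$beta, 0.3)

  # sampling oracle vs closed-form first moment K(1 - sigma/2)
  g <- gamma_from_slm(slm_params(K = 5, sigma = 0.8))
  draws <- gutmacro:::with_seed(1, rgamma(1e6, shape = g$alpha, rate = g$beta))
  expect_equal(mean(draws), 5 * (1 - 0.4), tolerance = 0.005)

  expect_error(slm_params(K = 1, sigma = 2), "sigma")
  expect_error(slm_params(K = 1, sigma = 0), "sigma")
  expect_error(slm_params(K = -1, sigma = 0.5), "K")
})

test_that("gamma_from_slm and its moment inversion are mutually inverse", {
  for (sigma in c(0.1, 0.5, 1, 1.5, 1.9)) {
    for (K in c(0.01, 1, 50)) {
      p <- slm_params(K = K, sigma = sigma)
      back <- slm_from_gamma(gamma_from_slm(p))
      expect_equal(back$K, K, tolerance = 1e-12)
      expect_equal(back$sigma, sigma, tolerance = 1e-12)
    }
  }
})

test_that("Taylor's law reduction yields the constrained Gamma parameters", {
  g <- params_from_taylor(0.01, A = 0.5, zeta = 2)
  expect_equal(g$alpha, 2)
  expect_equal(g$beta, 200)

  # zeta = 2: all shapes collapse to the constant 1/A
  xbar <- c(1e-5, 3e-4, 0.02, 0.4)
  g <- params_from_taylor(xbar, A = 0.25, zeta = 2)
  expect_true(all(g$alpha == 4))
  expect_equal(g$beta, 1 / (0.25 * xbar))

  # zeta = 1: shapes scale with the mean, rates constant
  g <- params_from_taylor(0.01, A = 0.01, zeta = 1)
  expect_equal(g$alpha, 1)
  g <- params_from_taylor(xbar, A = 0.01, zeta = 1)
  expect_equal(length(unique(g$beta)), 1L)

  expect_error(params_from_taylor(c(0.1, 0), A = 1, zeta = 2), "positive|> 0")
  expect_error(params_from_taylor(0.1, A = 1, zeta = 1.5), "zeta")
})

test_that("sigma_from_A inverts the constant-shape relation", {
  expect_equal(sigma_from_A(1), 1)
  expect_equal(sigma_from_A(1 / 3), 0.5)
  expect_lt(2 - sigma_from_A(1e8), 1e-7)  # A -> Inf gives sigma -> 2
  expect_error(sigma_from_A(0), "A")
  # strict monotonicity and round trip with A_from_sigma
  As <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(sigma_from_A(As)) > 0))
  expect_equal(A_from_sigma(sigma_from_A(As)), As)
})

test_that("scaled Dirichlet density reduces, normalizes and rescales correctly", {
  # equal rates: termwise equal to the ordinary Dirichlet density
  alpha <- c(0.5, 2, 3.5)
  vs <- rbind(c(0.2, 0.3, 0.5), c(0.01, 0.9, 0.09), c(1, 1, 1) / 3)
  gp <- gamma_params(alpha, beta = rep(2.7, 3))
  for (i in 1:3) {
    expect_equal(scaled_dirichlet_logpdf(vs[i, ], gp),
                 dirichlet_logpdf(vs[i, ], alpha), tolerance = 1e-10)
  }

  # S = 2: density integrates to 1 (quadrature oracle)
  gp2 <- gamma_params(c(2, 3), c(1, 4))
  f <- function(v1) exp(scaled_dirichlet_logpdf(cbind(v1, 1 - v1), gp2))
  expect_equal(integrate(f, 0, 1)$value, 1, tolerance = 1e-6)

  # invariance under rescaling of the rates
  gp_a <- gamma_params(c(1.2, 0.4, 5), c(0.3, 2, 11))
  gp_b <- gamma_params(c(1.2, 0.4, 5), 7 * c(0.3, 2, 11))
  v <- c(0.6, 0.1, 0.3)
  expect_equal(scaled_dirichlet_logpdf(v, gp_a),
               scaled_dirichlet_logpdf(v, gp_b), tolerance = 1e-12)

  expect_error(scaled_dirichlet_logpdf(c(0.5, 0.6), gp2), "sum to 1")
  expect_error(scaled_dirichlet_logpdf(c(0, 1), gp2), "open simplex")
})

test_that("scaled Dirichlet sampler matches its density", {
  gp <- gamma_params(c(2, 3), c(1, 4))
  v <- sample_scaled_dirichlet(gp, 1e5, seed = 3)
  expect_equal(rowSums(v), rep(1, 1e5), tolerance = 1e-12)

  # S = 2 histogram vs quadrature CDF of the package density
  expect_lt(ks_distance(v[, 1], sd2_cdf(gp)), 0.01)

  # equal rates, alpha = (1,1,1): uniform on the 2-simplex, so the first
  # component is Beta(1, 2); chi-square GOF against equal-probability bins
  gpu <- gamma_params(c(1, 1, 1), c(5, 5, 5))
  u <- sample_scaled_dirichlet(gpu, 2e4, seed = 4)[, 1]
  brk <- qbeta(seq(0, 1, by = 0.1), 1, 2)
  obs <- table(cut(u, brk))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("MD and MSSD tables are strictly compositional with the right scaling", {
  depths <- c(2e4, 5e4, 1e5)
  spec <- model_spec("mssd", lam = 1.2, A = 0.4, S = 50, R = 3,
                     depths = depths)
  tab <- sample_mssd(spec, seed = 10)
  expect_identical(unname(colSums(tab$counts)), depths)

  specmd <- model_spec("md", lam = 1.2, A = 0.01, mu = -7, S = 50, R = 3,
                       depths = depths)
  tabmd <- sample_md(specmd, seed = 10)
  expect_identical(unname(colSums(tabmd$counts)), depths)
  expect_error(sample_md(spec, seed = 1))  # model tag mismatch

  # Taylor exponents: ~2 for MSSD, ~1 for MD (coarse; the acceptance
  # suite probes the calibrated settings)
  tab2 <- mssd_test_table(seed = 21)
  expect_equal(fit_taylor(taylor_points(tab2))$zeta, 2, tolerance = 0.2)
  specmd2 <- model_spec("md", lam = 1.4, A = 0.01, mu = -9, S = 300, R = 80,
                        depths = 1e5)
  tabmd2 <- sample_md(specmd2, seed = 22)
  expect_equal(fit_taylor(taylor_points(tabmd2), zeta_fix = 1)$zeta, 1,
               tolerance = 0.2)
})

test_that("MD at vanishing A approaches pure multinomial resampling noise", {
  # A -> 0 makes the Dirichlet concentrate at the mean composition, so the
  # across-sample variance of relative abundances approaches the
  # multinomial-only variance vbar (1 - vbar) / N
  xbar <- gutmacro:::with_seed(5, rmad(100, "log_laplace", -7, 1))
  vbar <- xbar / sum(xbar)
  N <- 5e4
  spec <- model_spec("md", lam = 1, A = 1e-7, mu = -7, S = 100, R = 400,
                     depths = N)
  tab <- sample_model(spec, seed = 6, xbar = xbar)
  v <- rel_abundance(tab)
  s2 <- apply(v, 1, var)
  expected <- vbar * (1 - vbar) / N
  big <- vbar > 1e-3  # species with enough counts for a stable ratio
  expect_equal(mean(s2[big] / expected[big]), 1, tolerance = 0.15)
})

test_that("PSLG is compositional on average with near-Poisson column sums", {
  # mean column sum matches the target depth
  spec <- model_spec("pslg", lam = 1, A = 0.5, mu = -7, S = 100, R = 4000,
                     depths = 2e3)
  tab <- sample_pslg(spec, seed = 30)
  expect_false(all(tab$depths == 2e3))  # not exact per sample...
  expect_equal(mean(tab$depths) / 2e3, 1, tolerance = 0.02)  # ...but on average

  # with weak environmental noise the total-count dispersion is
  # Poisson-like: variance/mean of column sums near 1
  spec2 <- model_spec("pslg", lam = 0.3, A = 0.01, mu = -7, S = 300,
                      R = 3000, depths = 1e3, mad_family = "log_normal")
  tab2 <- sample_pslg(spec2, seed = 31)
  fano <- var(tab2$depths) / mean(tab2$depths)
  expect_equal(fano, 1, tolerance = 0.15)
})

test_that("SLM trajectories relax to the analytic stationary Gamma", {
  p <- slm_params(K = 1, sigma = 0.5, tau = 1)
  g <- gamma_from_slm(p)
  expect_equal(c(g$alpha, g$beta), c(3, 4))
  xs <- slm_stationary_sample(p, n = 4000, dt = 0.01, burn = 30, seed = 5)
  expect_gt(ks.test(xs, pgamma, shape = 3, rate = 4)$p.value, 0.01)
  # time-average matches the stationary mean K(1 - sigma/2)
  expect_equal(mean(xs), 0.75, tolerance = 0.03)

  # sigma -> 0: deterministic logistic convergence to K
  p0 <- slm_params(K = 2, sigma = 1e-8, tau = 1)
  traj <- simulate_slm(p0, dt = 0.05, t_max = 40, seed = 1, x0 = 0.1)
  expect_equal(tail(traj$x[, 1], 1), 2, tolerance = 1e-3)

  expect_error(simulate_slm(p, dt = 0.5, t_max = 1), "dt")
})
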