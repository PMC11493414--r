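test_that("cutoffs zero sub-threshold entries without renormalizing", {
  tab <- random_table(seed = 3)
  expect_identical(apply_cutoff(tab, 0), tab)

  # a toy column mimicking rare false positives at the low cutoff
  cts <- matrix(round(c(0.6, 0.3999, 1e-7, 0.0399999) * 1e7), ncol = 1)
  toy <- abundance_table(cts)
  cut <- apply_cutoff(toy, 4.5e-7)
  expect_equal(unname(cut$counts[, 1] == 0), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(cut$depths, toy$depths)  # denominator preserved
  v <- rel_abundance(cut)
  expect_lt(sum(v), 1)  # removed mass not redistributed

  # kappa = 1 zeroes everything (no relative abundance reaches 1 here)
  expect_true(all(apply_cutoff(toy, 1)$counts == 0))

  # renormalize flag recomputes the denominator
  cut2 <- apply_cutoff(toy, 4.5e-7, renormalize = TRUE)
  expect_equal(sum(rel_abundance(cut2)), 1)
})

test_that("successive cutoffs compose as their maximum", {
  tab <- mssd_test_table(S = 150, R = 30, seed = 8)
  k1 <- 9e-6; k2 <- 1.8e-4
  a <- apply_cutoff(apply_cutoff(tab, k1), k2)
  b <- apply_cutoff(apply_cutoff(tab, k2), k1)
  c_ <- apply_cutoff(tab, max(k1, k2))
  expect_identical(a$counts, c_$counts)
  expect_identical(b$counts, c_$counts)
  expect_equal(a$kappa, max(k1, k2))
})

test_that("increasing cutoffs weakly decrease diversity and occupancy", {
  tab <- mssd_test_table(S = 200, R = 40, seed = 9)
  kappas <- c(0, kappa_defaults())
  prev_gamma <- Inf; prev_alpha <- rep(Inf, 40); prev_occ <- rep(Inf, 200)
  for (k in kappas) {
    ck <- apply_cutoff(tab, k)
    d <- diversity(ck)
    expect_true(d$gamma <= prev_gamma)
    expect_true(all(d$alpha <= prev_alpha))
    occ <- occupancy(ck)
    expect_true(all(occ <= prev_occ))
    expect_true(d$gamma >= max(d$alpha))
    prev_gamma <- d$gamma; prev_alpha <- d$alpha; prev_occ <- occ
  }
})

test_that("mean abundance and occupancy match brute-force loops", {
  tab <- abundance_table(matrix(c(10, 30, 0, 0), nrow = 1) * 1e3 +
                           matrix(c(0, 0, 5, 5), nrow = 1))
  # single species, v = (0.1, 0.3) style check on a 2-species table
  cts <- matrix(c(1, 9, 3, 7), nrow = 2)  # columns sum to 10
  t2 <- abundance_table(cts)
  expect_equal(unname(mean_abundance(t2)), c(mean(c(0.1, 0.3)), mean(c(0.9, 0.7))))

  rt <- random_table(S = 5, R = 4, seed = 11)
  v <- rel_abundance(rt)
  manual_mean <- manual_occ <- numeric(5)
  for (i in 1:5) {
    acc <- 0; pres <- 0
    for (j in 1:4) {
      acc <- acc + v[i, j]
      pres <- pres + (rt$counts[i, j] > 0)
    }
    manual_mean[i] <- acc / 4
    manual_occ[i] <- pres / 4
  }
  expect_equal(unname(mean_abundance(rt)), manual_mean)
  expect_equal(unname(occupancy(rt)), manual_occ)

  # all-zero species
  expect_equal(unname(mean_abundance(toy_table()))[3], 0)
  expect_equal(unname(occupancy(toy_table()))[3], 0)
  expect_equal(unname(occupancy(toy_table()))[1], 0.5)
})

test_that("taylor_points uses the unbiased two-pass variance and filters", {
  rt <- random_table(S = 6, R = 5, seed = 13)
  tp <- taylor_points(rt, min_occupancy = 0)
  v <- rel_abundance(rt)
  for (k in seq_len(nrow(tp))) {
    i <- match(tp$species[k], rownames(rt$counts))
    m <- sum(v[i, ]) / 5
    s2 <- sum((v[i, ] - m)^2) / 4
    expect_equal(tp$mean[k], m)
    expect_equal(tp$variance[k], s2)
  }
  # occupancy filter removes rare species
  cts <- rbind(c(5, 5, 5, 5), c(1, 0, 0, 0), c(4, 5, 5, 5))
  t3 <- abundance_table(cts)
  tp3 <- taylor_points(t3, min_occupancy = 0.5)
  expect_false("sp002" %in% tp3$species)
  # identical values across samples give exactly zero variance
  expect_equal(tp3$variance[tp3$species == "sp001"], 0)
  expect_error(taylor_points(abundance_table(matrix(1:3, ncol = 1))), "2 samples")
})

test_that("diversity counts presences per sample and pooled", {
  d <- diversity(toy_table())
  expect_equal(unname(d$alpha), c(2, 1))
  expect_equal(d$gamma, 2)
  expect_true(d$gamma >= max(d$alpha))
})

test_that("AO curve is a non-decreasing saturating relation on MSSD data", {
  tab <- mssd_test_table(seed = 15)
  ao <- ao_curve(tab)
  expect_true(all(diff(ao$x) > 0))
  expect_true(all(ao$y >= 0 & ao$y <= 1))
  expect_gt(cor(ao$x, ao$y, method = "spearman"), 0.95)
  # the most abundant, everywhere-present species sits at occupancy 1
  expect_equal(tail(ao$y, 1), 1)
  # explicit edges are honored (shared binning with another table)
  ao2 <- ao_curve(tab, edges = ao$edges)
  expect_equal(ao2$x, ao$x)
})

test_that("SAD masses are a normalized distribution in both scopes", {
  tab <- mssd_test_table(S = 200, R = 40, seed = 16)
  for (scope in c("metacommunity", "sample")) {
    sd_ <- sad(tab, scope = scope)
    expect_equal(sum(sd_$y), 1, tolerance = 1e-12)
    expect_true(all(sd_$y > 0))
  }
  # single species, single sample: point mass at relative abundance 1
  one <- abundance_table(matrix(7, 1, 1))
  s1 <- sad(one)
  expect_equal(sum(s1$y), 1)
  expect_equal(length(s1$x), 1L)
  expect_equal(s1$x, 1, tolerance = 0.1)
})

test_that("SAR accumulates to exactly 1 and is monotone", {
  tab <- mssd_test_table(S = 150, R = 25, seed = 17)
  sar <- sar_curve(tab, n_permutations = 10, seed = 2)
  expect_equal(length(sar$x), 25L)
  expect_equal(tail(sar$y, 1), 1)
  expect_true(all(diff(sar$y) >= 0))
  expect_true(all(diff(sar$x) > 0))
  # single sample: one point at (N1, alpha1 / gamma)
  one <- abundance_table(matrix(c(3, 0, 2), ncol = 1))
  s1 <- sar_curve(one, n_permutations = 1, seed = 1)
  expect_equal(s1$x, 5)
  expect_equal(s1$y, 1)  # alpha1 = gamma for a single sample
  # deterministic under seed
  expect_equal(sar_curve(tab, 5, seed = 4)$y, sar_curve(tab, 5, seed = 4)$y)
})

test_that("patterns are invariant under joint row/column permutations", {
  tab <- mssd_test_table(S = 120, R = 30, seed = 18)
  perm <- gutmacro:::with_seed(19, {
    list(rows = sample(120), cols = sample(30))
  })
  ptab <- tab
  ptab$counts <- tab$counts[perm$rows, perm$cols]
  ptab$depths <- tab$depths[perm$cols]

  expect_equal(sort(unname(mean_abundance(ptab))), sort(unname(mean_abundance(tab))))
  expect_equal(sort(unname(occupancy(ptab))), sort(unname(occupancy(tab))))
  d1 <- diversity(tab); d2 <- diversity(ptab)
  expect_equal(sort(unname(d1$alpha)), sort(unname(d2$alpha)))
  expect_equal(d1$gamma, d2$gamma)
  ao1 <- ao_curve(tab); ao2 <- ao_curve(ptab, edges = ao1$edges)
  expect_equal(ao1$x, ao2$x); expect_equal(ao1$y, ao2$y)
  s1 <- sad(tab); s2 <- sad(ptab, edges = s1$edges)
  expect_equal(s1$y, s2$y)
})
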