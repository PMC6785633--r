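times6 <- seq(0, 30, by = 6)
grid2 <- toy_grid()

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.5), 0.5)  # k = 1 identity
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)
  # chi-square survival oracle for {0.05, 0.05}
  X <- -2 * (log(0.05) + log(0.05))
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(X, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gte(p0, 0)
})

test_that("Fisher combination is monotone in every input", {
  set.seed(81)
  for (i in 1:50) {
    p <- runif(3)
    j <- sample(3, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(p2), fisher_combine(p) + 1e-12)
  }
})

test_that("meta_fit period bookkeeping follows the mean-of-methods rule", {
  set.seed(82)
  m <- rbind(cosine_series(24, noise_sd = 0.02, times = times6),
             cosine_series(24, noise_sd = 0.02, times = times6))
  f <- meta_fit(m, grid2)
  expect_equal(f$period_mean, mean(c(f$period_jtk, f$period_ls)))
  expect_equal(f$period_group, 24)
  # two concordant replicates beat each single replicate (Fisher monotonicity
  # under equal evidence)
  f1 <- meta_fit(m[1, , drop = FALSE], grid2)
  f2 <- meta_fit(m[2, , drop = FALSE], grid2)
  expect_lt(f$p_combined, f1$p_combined)
  expect_lt(f$p_combined, f2$p_combined)
})

test_that("all-constant replicates yield p = 1 and no period group", {
  f <- meta_fit(rbind(rep(3, 6), rep(3, 6)), grid2)
  expect_equal(f$p_combined, 1)
  expect_true(is.na(f$period_group))
  expect_equal(f$phase_group, "none")
})

test_that("replicate grids must match the series", {
  expect_error(meta_fit(matrix(rnorm(10), 2, 5), grid2), "match grid times")
})

test_that("the methods (stacked) strategy is available and consistent", {
  set.seed(83)
  m <- rbind(cosine_series(24, noise_sd = 0.03, times = times6),
             cosine_series(24, noise_sd = 0.03, times = times6))
  f <- meta_fit(m, grid2, rhythm_config(replicate_strategy = "methods"))
  expect_lt(f$p_combined, 0.05)
  expect_equal(f$period_group, 24)
  expect_equal(f$p_combined, fisher_combine(c(f$p_jtk, f$p_ls)),
               tolerance = 1e-12)
})

test_that("period groups are 12/18/24/30 each +/- 3 h with lower-center midpoints", {
  expect_equal(assign_period_group(13.4), 12)
  expect_equal(assign_period_group(16.2), 18)
  expect_true(is.na(assign_period_group(33.5)))
  expect_equal(assign_period_group(15), 12)   # exact midpoint -> lower center
  expect_equal(assign_period_group(21), 18)
  expect_equal(assign_period_group(33), 30)   # boundary included
  expect_true(is.na(assign_period_group(8.9)))
  expect_true(is.na(assign_period_group(NA_real_)))
})

test_that("phase quadrants snap correctly and the 12 h group drops quadratures", {
  expect_equal(assign_phase_group(0, 24), "0")
  expect_equal(assign_phase_group(12, 24), "pi")
  expect_equal(assign_phase_group(6, 24), "pi/2")
  expect_equal(assign_phase_group(18, 24), "-pi/2")
  expect_equal(assign_phase_group(23.5, 24), "0")  # circular wrap
  expect_equal(assign_phase_group(4, 12, period_group = 12), "pi")
  expect_equal(assign_phase_group(1, 12, period_group = 12), "0")
  # the exact quadrature midpoint ties to the lower center
  expect_equal(assign_phase_group(3, 12, period_group = 12), "0")
  expect_equal(assign_phase_group(NA, 24), "none")
})

test_that("z-score normalization is exact and safe on constants", {
  expect_equal(zscore_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_normalize(rep(4, 5)), rep(0, 5))
  set.seed(84)
  x <- rnorm(10, 5, 2)
  z <- zscore_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("cosine fit recovers amplitude and phase of a pure cosine", {
  for (ph in c(0, 6, 12, 18)) {
    x <- 2 + 0.7 * cos(2 * pi * (times6 - ph) / 24)
    cf <- ladcycle:::cosine_fit(x, times6, 24)
    expect_equal(cf$amplitude, 0.7, tolerance = 1e-8)
    expect_equal(cf$phase_h %% 24, ph, tolerance = 1e-6)
    expect_equal(cf$base, 2, tolerance = 1e-8)
  }
})

test_that("type-I calibration: pure-noise combined p < 0.005 at rate <= 0.05", {
  # the min-over-configurations JTK convention and JTK/LS dependence make the
  # combination anticonservative; the stated bound is on the stringent tail
  set.seed(85)
  n_sim <- 300
  hits <- 0
  for (i in seq_len(n_sim)) {
    m <- rbind(0.5 + rnorm(6, 0, 0.05), 0.5 + rnorm(6, 0, 0.05))
    if (meta_fit(m, grid2)$p_combined < 0.005) hits <- hits + 1
  }
  expect_lte(hits, qbinom(0.995, n_sim, 0.05))
})

test_that("parameter recovery: injected 24 h borders are found with the right group", {
  set.seed(86)
  n_sim <- 60
  ok <- 0
  for (i in seq_len(n_sim)) {
    ph <- sample(c(0, 6, 12, 18), 1)
    m <- rbind(cosine_series(24, phase = ph, noise_sd = 0.1, times = times6),
               cosine_series(24, phase = ph, noise_sd = 0.1, times = times6))
    f <- meta_fit(m, grid2)
    if (f$p_combined < 0.05 && !is.na(f$period_group) && f$period_group == 24) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, qbinom(0.005, n_sim, 0.90))
})
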