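test_that("VBGF evaluation matches the closed form", {
  expect_equal(vbgf_length(1.5, 100, 0.5, 1.5), 0)
  expect_equal(vbgf_length(2, 100, 0.5, 0), 100 * (1 - exp(-1)))
  expect_equal(round(vbgf_length(2, 100, 0.5, 0), 4), 63.2121)
  # asymptote: far beyond t0 the curve reaches Linf
  expect_equal(vbgf_length(0.2 + 50 / 0.3, 850, 0.3, 0.2), 850,
               tolerance = 1e-8)
  # spreadsheet-style recomputation on a grid
  tt <- seq(0.5, 9, by = 0.5)
  manual <- 420 * (1 - exp(-0.27 * (tt - (-0.3))))
  expect_equal(vbgf_length(tt, 420, 0.27, -0.3), manual, tolerance = 1e-9)
})

test_that("growth performance index is log10 k + 2 log10 Linf", {
  expect_equal(growth_performance_index(1, 1), 0)
  expect_equal(growth_performance_index(100, 0.1), 3)
  # doubling Linf adds 2*log10(2) whatever k is
  for (k in c(0.05, 0.3, 1.2)) {
    expect_equal(growth_performance_index(880, k) -
                   growth_performance_index(440, k),
                 2 * log10(2), tolerance = 1e-12)
  }
  expect_error(growth_performance_index(-1, 0.5), "positive")
})

test_that("biological-intercept back-calculation matches hand computation", {
  expect_equal(back_calculate_length(500, 2, 2), 500)   # Oa = Oc identity
  expect_equal(back_calculate_length(500, 2.0, 1.0),
               500 + (1 - 2) * (500 - 4.3) / (2 - 0.01), tolerance = 1e-12)
  expect_equal(round(back_calculate_length(500, 2.0, 1.0), 3), 250.905)
  # increasing in Oa
  la <- back_calculate_length(500, 2, c(0.5, 1, 1.5, 2))
  expect_false(is.unsorted(la, strictly = TRUE))
  expect_error(back_calculate_length(500, 2, 2.5), "Oa")
})

test_that("relative condition is centred at 1 and scale invariant", {
  set.seed(2)
  L <- runif(40, 200, 800)
  W <- 2e-6 * L^3
  rc <- relative_condition(L, W)
  expect_equal(rc$b, 3, tolerance = 1e-10)
  expect_equal(unname(rc$Kn), rep(1, 40), tolerance = 1e-10)

  W2 <- W
  W2[1] <- W[1] * 1.1
  rc2 <- relative_condition(L, W2)
  expect_equal(rc2$Kn[1], 1.1, tolerance = 0.01)

  rc3 <- relative_condition(L, W * 7)
  expect_equal(unname(rc3$Kn), unname(rc$Kn), tolerance = 1e-10)
  expect_error(relative_condition(rep(100, 5), rep(10, 5)), "variance")
})

test_that("Bartlett variance test detects heteroscedastic first-annulus radii", {
  set.seed(7)
  g1 <- rnorm(50, 0, 1)
  g2 <- rnorm(50, 0, 5)
  out <- variance_homogeneity_test(c(g1, g2), rep(c("a", "b"), each = 50))
  expect_lt(out$p_value, 0.001)
  expect_equal(out$df, 1)

  # identical groups duplicated: equal variances, statistic exactly 0
  out0 <- variance_homogeneity_test(c(g1, g1), rep(c("a", "b"), each = 50))
  expect_equal(out0$statistic, 0, tolerance = 1e-12)
  expect_equal(out0$p_value, 1)

  expect_error(variance_homogeneity_test(c(1, 1, 2, 3),
                                         c("a", "a", "b", "b")),
               "zero variance")
  # p-values are calibrated under the null
  rej <- mean(vapply(1:500, function(i) {
    set.seed(5000 + i)
    x <- rnorm(60)
    variance_homogeneity_test(x, rep(1:3, each = 20))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})
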