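test_that("loess smoothing reproduces constants and linears, and denoises", {
  x <- seq(10, 1000, by = 10)
  expect_equal(smooth_profile(x, rep(2.5, length(x)), span = 0.2),
               rep(2.5, length(x)), tolerance = 1e-10)
  y_lin <- 0.1 + 0.002 * x
  expect_equal(smooth_profile(x, y_lin, span = 0.2), y_lin, tolerance = 1e-8)

  set.seed(4)
  clean <- sin(2 * pi * x / 300)
  noisy <- clean + rnorm(length(x), 0, 0.1)
  sm <- smooth_profile(x, noisy, span = 0.1)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))

  expect_error(smooth_profile(x[1:5], y_lin[1:5]), "at least 10")
  expect_error(smooth_profile(x, y_lin, span = 0), "span")
})

test_that("minima detection honours prominence, separation and translation", {
  x <- 1:100
  expect_length(detect_minima(x, x * 0.5), 0)           # monotone
  # two equal-depth minima far apart are both kept
  y <- cos(2 * pi * x / 50)
  m <- detect_minima(x, y, min_separation = 10, min_prominence = 0.5)
  expect_length(m, 2)
  # when closer than min_separation only the deepest survives
  y2 <- rep(1, 100)
  y2[c(40, 48)] <- c(-1, -2)
  m2 <- detect_minima(x, y2, min_separation = 20, min_prominence = 0.1)
  expect_equal(m2, 48)
  # translation equivariance
  m_shift <- detect_minima(x + 500, y, min_separation = 10,
                           min_prominence = 0.5)
  expect_equal(m_shift, m + 500)
  # endpoints are never minima
  y3 <- seq(1, 0, length.out = 50)
  expect_length(detect_minima(1:50, y3), 0)
})

# hand-built profile pair: P has `age` clean minima, Mg the same plus an
# optional extra trough near the otolith edge (within the edge margin)
built_profile <- function(age, extra_mg_edge = FALSE, quarter = 1) {
  x <- seq(5, 1000, by = 5)
  phase <- x / (1000 / (age + 0.35))
  p <- 2 + cos(2 * pi * phase)
  mg <- 1 + 0.5 * cos(2 * pi * phase)
  if (extra_mg_edge) {
    mg <- mg - 1.0 * exp(-((x - 960) / 30)^2)
  }
  list(fish_id = "built", distances = x, mg_ca = mg, p_ca = p,
       edge_radius = 1000, catch_quarter = quarter)
}

test_that("age estimation agrees, resolves first-quarter edge minima, or flags", {
  pr <- built_profile(3)
  est <- estimate_age(pr)
  expect_equal(est$age, 3L)
  expect_equal(est$consensus_flag, "agreed")
  expect_equal(unname(est$element_counts), c(3L, 3L))

  # Mg picks up an extra minimum at 98% of the edge radius; Q1 catch -> drop
  pr1 <- built_profile(3, extra_mg_edge = TRUE, quarter = 1)
  est1 <- estimate_age(pr1)
  expect_equal(est1$age, 3L)
  expect_equal(est1$consensus_flag, "resolved")

  # same disagreement outside the first quarter is not auto-resolved
  pr2 <- built_profile(3, extra_mg_edge = TRUE, quarter = 3)
  est2 <- estimate_age(pr2)
  expect_equal(est2$consensus_flag, "needs_review")
  expect_true(is.na(est2$age))

  expect_error(estimate_age(list(distances = 1:10, mg_ca = 1:10)), "missing")
})

test_that("annulus radii extraction appends the edge radius and demands monotonicity", {
  pr <- simulate_otolith_profile(3, edge_radius = 800, step = 4,
                                 noise_sd = 0.02, seed = 13)
  est <- estimate_age(pr)
  out <- extract_annulus_radii(est, pr$edge_radius)
  expect_length(out$annulus_radii, 3)
  expect_equal(out$radius_at_catch, 800)
  expect_lt(max(abs(out$annulus_radii - pr$truth$minima_radii)), 25)

  age0 <- structure(list(age = 0L, minima_radii = numeric(0),
                         consensus_flag = "agreed"), class = "age_result")
  expect_equal(extract_annulus_radii(age0, 500)$annulus_radii, numeric(0))
  bad <- structure(list(age = 2L, minima_radii = c(300, 200),
                        consensus_flag = "agreed"), class = "age_result")
  expect_error(extract_annulus_radii(bad, 500), "monotone")
})
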