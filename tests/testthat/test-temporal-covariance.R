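test_that("allele frequencies match a brute-force loop", {
  gt <- make_gt(rbind(c(0, 0), c(1, 2), c(2, NA)), time_index = c(1, 1, 1))
  fr <- allele_frequencies(gt)
  expect_equal(unname(fr$p[1, 1]), 0.5)       # dosages 0,1,2
  expect_equal(unname(fr$p[1, 2]), 0.5)       # 0,2,NA -> 2/4
  expect_equal(unname(fr$n[1, 2]), 2)

  d <- random_dosage(30, 50, miss = 0.15, seed = 44)
  tix <- rep(1:3, each = 10)
  fr2 <- allele_frequencies(make_gt(d, time_index = tix))
  for (t in 1:3) {
    for (l in c(1, 17, 50)) {
      x <- d[tix == t, l]
      x <- x[!is.na(x)]
      manual <- if (length(x)) sum(x) / (2 * length(x)) else NA_real_
      expect_equal(unname(fr2$p[t, l]), manual, tolerance = 1e-15)
    }
  }
})

test_that("temporal covariance equals hand and loop computations", {
  p <- rbind(c(0.5, 0.5), c(0.6, 0.4), c(0.5, 0.5), c(0.8, 0.2))
  fr <- make_freqs(p)
  # dA = (0.1, -0.1) over 1->2; dB = (0.2, -0.2) over 2->4
  expect_equal(temporal_cov(fr, c(1, 2), c(2, 4)), 0.04)
  # constant change across loci has zero covariance
  pc <- rbind(rep(0.4, 5), rep(0.5, 5), rep(0.45, 5), rep(0.6, 5))
  expect_equal(temporal_cov(make_freqs(pc), c(1, 2), c(3, 4)), 0)
  # variance form is non-negative
  set.seed(3)
  pr <- matrix(runif(4 * 200), 4, 200)
  frr <- make_freqs(pr)
  expect_gte(temporal_cov(frr, c(1, 3), c(1, 3)), 0)
  # two-pass loop oracle on a random table with missingness
  pr[sample(length(pr), 40)] <- NA
  frm <- make_freqs(pr)
  dA <- pr[3, ] - pr[1, ]; dB <- pr[4, ] - pr[2, ]
  expect_equal(temporal_cov(frm, c(1, 3), c(2, 4)), cov_oracle(dA, dB),
               tolerance = 1e-12)
  expect_error(temporal_cov(make_freqs(matrix(NA_real_, 4, 3)), c(1, 2), c(3, 4)),
               "loci")
})

test_that("lag autocovariances enumerate disjoint-endpoint interval pairs", {
  set.seed(5)
  fr <- make_freqs(matrix(runif(5 * 100), 5, 100))
  l2 <- lag_autocovariances(fr, 2)
  expect_equal(nrow(l2), 2)          # T1->T3 x T2->T4 and T2->T4 x T3->T5
  l3 <- lag_autocovariances(fr, 3)
  expect_equal(nrow(l3), 1)          # T1->T4 x T2->T5
  expect_equal(l2$value[1],
               cov(fr$p[3, ] - fr$p[1, ], fr$p[4, ] - fr$p[2, ]))
  expect_error(lag_autocovariances(fr, 1), "lag")
  constant <- make_freqs(matrix(0.4, 5, 10))
  expect_equal(lag_autocovariances(constant, 2)$value, c(0, 0))
})

test_that("block bootstrap covers the point estimate and is reproducible", {
  set.seed(11)
  fr <- make_freqs(matrix(runif(5 * 600), 5, 600))
  ci <- block_bootstrap_ci(fr, c(1, 3), c(2, 4), block_size = 20, B = 400,
                           seed = 2)
  truth <- cov_oracle(fr$p[3, ] - fr$p[1, ], fr$p[4, ] - fr$p[2, ])
  expect_equal(ci$value, truth, tolerance = 1e-12)
  expect_lte(ci$ci_low, ci$value)
  expect_gte(ci$ci_high, ci$value)
  ci2 <- block_bootstrap_ci(fr, c(1, 3), c(2, 4), block_size = 20, B = 400,
                            seed = 2)
  expect_identical(ci, ci2)
  # one giant block: interval degenerates to the point value
  ci3 <- block_bootstrap_ci(fr, c(1, 3), c(2, 4), block_size = 600, B = 100,
                            seed = 3)
  expect_equal(ci3$ci_low, ci3$value)
  expect_equal(ci3$ci_high, ci3$value)
})

test_that("subset permutation test is well-formed and order invariant", {
  set.seed(8)
  fr <- make_freqs(matrix(runif(5 * 300, 0.3, 0.7), 5, 300))
  pt <- subset_permutation_test(fr, focal_loci = 1:20, lag = 2, B = 250,
                                seed = 7)
  expect_length(pt$null_values, 250)
  expect_gt(pt$p_emp, 0)
  expect_lte(pt$p_emp, 1)
  expect_equal(pt$p_emp,
               (1 + sum(pt$null_values >= pt$observed)) / 251)

  # permuting locus columns leaves p_emp unchanged (same seed, ids fixed)
  perm <- sample(300)
  fr_perm <- make_freqs(fr$p[, perm], fr$n[, perm])
  focal_names <- colnames(fr$p)[1:20]
  a <- subset_permutation_test(fr, focal_names, lag = 2, B = 250, seed = 7)
  b <- subset_permutation_test(fr_perm, focal_names, lag = 2, B = 250,
                               seed = 7)
  expect_equal(a$p_emp, b$p_emp)
  expect_equal(a$observed, b$observed)

  expect_error(subset_permutation_test(fr, c("L0001", "nope"), 2, 10, 1),
               "absent")
})
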