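test_that("kinship matrix is a symmetric standardized cross-product", {
  d <- random_dosage(15, 200, maf = 0.4, seed = 51)
  d[3, ] <- d[2, ]              # duplicated individuals
  gt <- make_gt(d)
  K <- kinship_matrix(gt, maf_min = 0.01)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(K[2, 3], K[2, 2], tolerance = 1e-12)
  # column standardisation uses the n-1 sample variance, so the expected
  # diagonal is exactly (n-1)/n
  expect_equal(mean(diag(K)), 14 / 15, tolerance = 1e-10)
  expect_error(kinship_matrix(make_gt(matrix(2, 4, 5))), "polymorphic")
})

test_that("mixed-model scan reduces to OLS without a random effect", {
  set.seed(61)
  n <- 80
  d <- random_dosage(n, 60, maf = 0.3, seed = 61)
  gt <- make_gt(d)
  y <- rnorm(n) + 0.5 * d[, 7]
  sex <- rep_len(c("F", "M"), n)
  sc <- lmm_assoc_scan(gt, y, covariates = data.frame(sex = sex),
                       K = matrix(0, n, n), maf_min = 0.05)
  for (j in c(3, 7, 20)) {
    loc <- colnames(gt$dosage)[j]
    row <- sc[sc$locus == loc, ]
    if (!nrow(row)) next
    ols <- summary(lm(y ~ sex + d[, j]))$coefficients
    expect_equal(row$beta, ols[3, 1], tolerance = 1e-8)
    expect_equal(row$se, ols[3, 2], tolerance = 1e-8)
  }
})

test_that("the scan recovers a known additive effect under structure", {
  set.seed(62)
  n <- 200
  d <- random_dosage(n, 150, maf = 0.35, seed = 62)
  gt <- make_gt(d)
  g <- d[, 42]
  y <- 2 * g + rnorm(n, 0, 1)
  K <- kinship_matrix(gt, maf_min = 0.01)
  sc <- lmm_assoc_scan(gt, y, K = K, maf_min = 0.05)
  row <- sc[sc$locus == colnames(gt$dosage)[42], ]
  expect_lt(abs(row$beta - 2), 3 * row$se)
  expect_lt(row$wald_p, 1e-10)
  # per-SNP variance-ratio mode agrees closely at the causal SNP
  sc2 <- lmm_assoc_scan(gt, y, K = K, maf_min = 0.05, per_snp_ratio = TRUE)
  row2 <- sc2[sc2$locus == colnames(gt$dosage)[42], ]
  expect_equal(row2$beta, row$beta, tolerance = 0.1)
})

test_that("genomic inflation is near 1 for uniform p and above 1 when inflated", {
  set.seed(63)
  p <- runif(5000)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.06)
  expect_gt(genomic_inflation(p / 2), genomic_inflation(p))
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("outlier selection keeps the tail with ties included", {
  set.seed(64)
  assoc <- data.frame(locus = sprintf("L%05d", 1:10000), chrom = "c",
                      pos = 1:10000, wald_p = runif(10000))
  out <- select_gwa_outliers(assoc, tail = 0.0005)
  expect_gte(nrow(out$loci), 5)
  expect_setequal(out$loci$locus,
                  assoc$locus[order(assoc$wald_p)][seq_len(nrow(out$loci))])
  # ties at the threshold are all included
  assoc2 <- assoc
  assoc2$wald_p[1:20] <- 1e-6
  out2 <- select_gwa_outliers(assoc2, tail = 0.0005)
  expect_equal(nrow(out2$loci), 20)
  expect_equal(nrow(select_gwa_outliers(assoc, tail = 1)$loci), 10000)
  expect_error(select_gwa_outliers(assoc, tail = 0), "tail")

  win <- data.frame(chrom = "c", start = seq(1, by = 100, length.out = 100),
                    end = seq(101, by = 100, length.out = 100),
                    fst = seq(0.001, 0.1, length.out = 100))
  top <- select_fst_outlier_windows(win, top = 0.05)
  expect_equal(nrow(top), 5)
  expect_equal(sort(top$fst), sort(win$fst, decreasing = TRUE)[5:1])
  win$fst[1:10] <- 0.2
  expect_equal(nrow(select_fst_outlier_windows(win, top = 0.05)), 10)
  win$fst[1:10] <- NA
  expect_equal(nrow(select_fst_outlier_windows(win, top = 1)), 90)
})

test_that("overlap counting uses half-open windows and distinct windows", {
  win <- data.frame(chrom = "c", start = c(1, 101, 201), end = c(101, 201, 301))
  snps <- data.frame(chrom = "c", pos = c(5, 50, 99))
  expect_equal(count_overlaps(snps, win), 1)        # 3 SNPs in one window
  expect_equal(count_overlaps(data.frame(chrom = "c", pos = 101), win), 1)
  expect_equal(count_overlaps(data.frame(chrom = "c", pos = 301), win), 0)
  expect_equal(count_overlaps(snps[0, ], win), 0)
  expect_equal(count_overlaps(data.frame(chrom = "other", pos = 5), win), 0)
})

test_that("overlap randomization null matches the hypergeometric expectation", {
  set.seed(65)
  L <- 4000
  all_loci <- data.frame(chrom = "c", pos = sort(sample.int(4e6, L)))
  win <- data.frame(chrom = "c", start = seq(1, 4e6, by = 2e4),
                    end = seq(1, 4e6, by = 2e4) + 2e4)
  win <- win[sample(nrow(win), 10), ]               # 10 outlier windows
  n_draw <- 120
  obs <- all_loci[sample(L, n_draw), ]
  ov <- overlap_randomization_test(all_loci, win, obs, B = 2000, seed = 3)
  expect_length(ov$null_values, 2000)
  # closed-form: E[count] = sum_w 1 - choose(L - m_w, n) / choose(L, n)
  m_w <- vapply(seq_len(nrow(win)), function(i) {
    sum(all_loci$pos >= win$start[i] & all_loci$pos < win$end[i])
  }, numeric(1))
  e_count <- sum(1 - exp(lchoose(L - m_w, n_draw) - lchoose(L, n_draw)))
  se <- sd(ov$null_values) / sqrt(ov$B)
  expect_lt(abs(mean(ov$null_values) - e_count), 2 * se + 0.02)

  # maximal enrichment: an observed set built to hit every outlier window
  wid <- fiescan:::.window_of(all_loci$chrom, all_loci$pos, win)
  pick <- unlist(lapply(unique(wid[wid > 0]),
                        function(w) head(which(wid == w), 5)))
  ov2 <- overlap_randomization_test(all_loci, win, all_loci[pick, ],
                                    B = 300, seed = 4)
  expect_equal(ov2$observed, nrow(win))
  expect_equal(ov2$p_emp, 1 / 301)
  # windows covering everything: p near 1
  full <- data.frame(chrom = "c", start = 1, end = 4e6 + 1)
  ov3 <- overlap_randomization_test(all_loci, full, obs, B = 200, seed = 5)
  expect_equal(ov3$observed, 1)
  expect_equal(ov3$p_emp, 1)
  expect_warning(overlap_randomization_test(all_loci, win, obs, B = 50,
                                            seed = 6), "coarse")
})
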