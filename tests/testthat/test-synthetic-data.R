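test_that("otolith profiles carry exactly `age` seasonal minima and are reproducible", {
  for (age in c(1, 3, 6)) {
    pr <- simulate_otolith_profile(age, edge_radius = 900, step = 5,
                                   noise_sd = 0, seed = 42)
    raw <- detect_minima(pr$distances, pr$p_ca, min_separation = 0,
                         min_prominence = 0)
    expect_length(raw, age)
    expect_equal(length(pr$truth$minima_radii), age)
    expect_false(is.unsorted(pr$truth$minima_radii, strictly = TRUE))
    # detected positions sit within one step of the true annulus radii
    expect_lt(max(abs(raw - pr$truth$minima_radii)), 5 + 1e-9)
  }
  pr0 <- simulate_otolith_profile(0, edge_radius = 400, noise_sd = 0, seed = 1)
  expect_length(detect_minima(pr0$distances, pr0$mg_ca, 0, 0), 0)
  expect_length(pr0$truth$minima_radii, 0)

  a <- simulate_otolith_profile(4, noise_sd = 0.1, seed = 9)
  b <- simulate_otolith_profile(4, noise_sd = 0.1, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_otolith_profile(10, edge_radius = 40, step = 5),
               "edge_radius")
})

test_that("growth cohorts follow the VBGF exactly at zero noise", {
  gp <- data.frame(Linf = 3.0, k = 0.4, t0 = 0)
  coh <- simulate_growth_cohort(gp, n_per_group = 4, indiv_sd = 0, obs_sd = 0,
                                age_range = c(2, 2), seed = 3)
  r2 <- coh$observations$La[coh$observations$ta == 2]
  expect_equal(r2, rep(3.0 * (1 - exp(-0.8)), 4), tolerance = 1e-12)
  expect_equal(unique(round(r2, 4)), 1.6521, tolerance = 1e-4)

  gp2 <- data.frame(Linf = c(1000, 600), k = 0.3, t0 = 0)
  coh2 <- simulate_growth_cohort(gp2, n_per_group = 15, indiv_sd = 0.05,
                                 obs_sd = 1, age_range = c(5, 5), seed = 8)
  m <- tapply(coh2$observations$La[coh2$observations$ta == 5],
              coh2$observations$group_id[coh2$observations$ta == 5], mean)
  expect_gt(m[["g1"]], m[["g2"]])
  expect_error(simulate_growth_cohort(gp, 3, indiv_sd = -1), "indiv_sd")
})

test_that("Wright-Fisher drift respects absorption, drift magnitude and determinism", {
  cfg <- sim_config(n_diploid = 2500, burn_in = 0, n_sample_times = 1,
                    sample_size = 20)
  w <- simulate_wright_fisher(cfg, n_loci = 1000, seed = 5)
  p0 <- w$freq_true[1, ]
  p1 <- w$freq_true[2, ]
  # one-generation binomial drift: E|dp| = sqrt(p(1-p)/2N) * sqrt(2/pi)
  expected <- mean(sqrt(p0 * (1 - p0) / 5000) * sqrt(2 / pi))
  expect_equal(mean(abs(p1 - p0)), expected, tolerance = 0.1)

  w2 <- simulate_wright_fisher(cfg, n_loci = 1000, seed = 5)
  expect_identical(w$genotypes$dosage, w2$genotypes$dosage)
  expect_identical(w$freq_true, w2$freq_true)

  # loci fixed or lost stay fixed or lost
  cfg2 <- sim_config(n_diploid = 20, burn_in = 60, n_sample_times = 3,
                     sample_size = 5)
  w3 <- simulate_wright_fisher(cfg2, n_loci = 300, seed = 6)
  f <- w3$freq_true
  hit1 <- apply(f == 1, 2, function(z) any(z))
  for (l in which(hit1)) {
    first <- min(which(f[, l] == 1))
    expect_true(all(f[first:nrow(f), l] == 1))
  }
  expect_error(simulate_wright_fisher(sim_config(n_diploid = 10,
                                                 sample_size = 20), 10),
               "sample_size")
})

test_that("neutral heterozygosity decays as (1 - 1/(2N))^t", {
  N <- 100; t <- 50; reps <- 500
  h_ratio <- vapply(seq_len(reps), function(r) {
    w <- simulate_wright_fisher(sim_config(n_diploid = N, burn_in = t - 1,
                                           n_sample_times = 1,
                                           sample_size = 5),
                                n_loci = 60, seed = 9000 + r)
    h0 <- mean(2 * w$freq_true[1, ] * (1 - w$freq_true[1, ]))
    ht <- mean(2 * w$freq_true[t + 1, ] * (1 - w$freq_true[t + 1, ]))
    ht / h0
  }, numeric(1))
  expect_equal(mean(h_ratio), (1 - 1 / (2 * N))^t, tolerance = 0.02)
})

test_that("polygenic harvest drives causal alleles in the selected direction", {
  cfg <- sim_config(n_diploid = 200, burn_in = 0, n_sample_times = 20,
                    sample_size = 10)
  sel <- selection_config(n_causal_loci = 1, effect_sizes = 2, env_sd = 0.5,
                          harvest_fraction = 0.5, harvest_steepness = 3)
  signs <- vapply(1:100, function(r) {
    s <- simulate_polygenic_selection(cfg, sel, n_loci = 40, seed = 100 + r)
    f <- s$truth$freq_sampled[, s$truth$causal_loci]
    sign(f[length(f)] - f[1])
  }, numeric(1))
  # trait-increasing allele is harvested against, so it declines
  expect_gte(mean(signs <= 0), 0.95)

  # neutral loci show no mean change across replicates
  neut <- vapply(1:30, function(r) {
    s <- simulate_polygenic_selection(cfg, sel, n_loci = 40, seed = 300 + r)
    idx <- setdiff(seq_len(40), s$truth$causal_loci)
    mean(s$truth$freq_sampled[nrow(s$truth$freq_sampled), idx] -
           s$truth$freq_sampled[1, idx])
  }, numeric(1))
  expect_lt(abs(mean(neut)), 0.02)

  # harvest_fraction = 0 is a neutral model and bit-reproducible
  sel0 <- selection_config(n_causal_loci = 5, harvest_fraction = 0)
  a <- simulate_polygenic_selection(cfg, sel0, n_loci = 30, seed = 77)
  b <- simulate_polygenic_selection(cfg, sel0, n_loci = 30, seed = 77)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_error(
    simulate_polygenic_selection(cfg, selection_config(n_causal_loci = 99),
                                 n_loci = 50, seed = 1),
    "causal")
})

test_that("generated VCF round-trips through the package reader without loss", {
  d <- random_dosage(12, 40, miss = 0.1, seed = 21)
  gt <- make_gt(d, time_index = rep(1:3, each = 4))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gt, path)
  back <- read_genotypes_vcf(path, metadata = gt$samples)
  expect_equal(unname(back$dosage), unname(gt$dosage))
  expect_equal(back$loci$pos, gt$loci$pos)
  expect_equal(back$samples$time_index, gt$samples$time_index)
  unlink(path)
})
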