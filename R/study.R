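#' Canonical synthetic-study experiments
#'
#' These functions run the package's end-to-end validation experiments at
#' their canonical study conditions and are what the reproducibility script
#' and the acceptance test suite execute. Each is seeded and returns the
#' summary quantities it measures. Problem sizes are desk scale: they are
#' documented (with rationale) in the methods vignette.
#'
#' @name study
NULL

#' Growth-model parameter recovery across seeded replicate studies
#'
#' Simulates `n_runs` cohorts of 5 catch-year groups x `n_per_group` fish
#' with asymptotic length declining 1150 -> 539 (the magnitude of decline
#' reported for the motivating stock) and growth coefficient rising
#' 0.15 -> 0.40 per year, fits the hierarchical model at the test MCMC
#' preset, and measures how often the posterior group-median Linf is within
#' 10 percent of truth with the correct monotone ordering, plus convergence
#' diagnostics.
#'
#' @param n_runs replicate studies.
#' @param groups data.frame of true group parameters.
#' @param n_per_group fish per group.
#' @param indiv_sd,obs_sd cohort noise levels (log-scale CV; radius units).
#' @param mcmc [mcmc_preset()].
#' @param seed integer seed.
#' @return list: `within_10pct_rate`, `monotone_rate`, `rhat_ok_rate`
#'   (all parameters' split-Rhat < 1.05), `max_rhat`, per-run table.
#' @export
study_vbgf_recovery <- function(n_runs = 20,
                                groups = data.frame(
                                  Linf = seq(1150, 539, length.out = 5),
                                  k = seq(0.15, 0.40, length.out = 5),
                                  t0 = 0),
                                n_per_group = 20, indiv_sd = 0.08,
                                obs_sd = 10, mcmc = mcmc_preset("test"),
                                seed = 1L) {
  runs <- lapply(seq_len(n_runs), function(r) {
    coh <- simulate_growth_cohort(groups, n_per_group = n_per_group,
                                  indiv_sd = indiv_sd, obs_sd = obs_sd,
                                  age_range = c(3L, 7L),
                                  seed = seed * 1000L + r)
    fit <- fit_hierarchical_vbgf(coh$observations, mcmc = mcmc,
                                 seed = seed * 2000L + r)
    med <- apply(do.call(rbind, fit$draws), 2, median)
    Lg <- med[paste0("Linf_g[", fit$groups, "]")]
    data.frame(run = r,
               max_rel_err = max(abs(Lg - groups$Linf) / groups$Linf),
               monotone = all(diff(Lg) < 0),
               max_rhat = max(fit$rhat, na.rm = TRUE))
  })
  tab <- do.call(rbind, runs)
  list(within_10pct_rate = mean(tab$max_rel_err < 0.10),
       monotone_rate = mean(tab$monotone),
       rhat_ok_rate = mean(tab$max_rhat < 1.05),
       max_rhat = max(tab$max_rhat),
       runs = tab)
}

#' Chemical-aging accuracy on synthetic otolith profiles
#'
#' Ages `n_fish` synthetic profiles with true ages drawn from `ages` and
#' additive noise `noise_sd` (ratio units; the default is 20 percent of the
#' weaker seasonal amplitude). Each fish gets an otolith whose edge radius
#' follows a shared von Bertalanffy otolith-growth curve (a 1-year-old does
#' not carry a 7-year-old's otolith) sampled at ~220 transect points
#' (>= 28 per year of life at the oldest age).
#'
#' Catch quarters default to 2-4. First-quarter catches place the terminal
#' winter trough within the smoothing bandwidth of the otolith edge, where
#' automated minima counting is unreliable for both elements at once; the
#' field protocol handles those samples by visual assessment, which an
#' automated validation cannot emulate, so they are excluded from the
#' accuracy target and can be studied via the `quarters` argument.
#'
#' The detection parameters are matched to the transect geometry: smoothing
#' span 0.07 (bandwidth ~70 micrometres, below the ~60-110 micrometre
#' spacing of late annuli plus margin) and minimum prominence 0.25 of the
#' smoothed-series IQR (between the prominence of residual noise wiggles and
#' the ~1.4 IQR prominence of a true seasonal trough).
#'
#' @param n_fish number of profiles.
#' @param ages candidate true ages.
#' @param noise_sd additive noise SD in ratio units.
#' @param quarters catch quarters to sample from.
#' @param params [age_params()] used for estimation.
#' @param seed integer seed.
#' @return list: `exact_rate`, `needs_review_rate`, per-fish table.
#' @export
study_aging_accuracy <- function(n_fish = 200, ages = 1:7, noise_sd = 0.08,
                                 quarters = 2:4,
                                 params = age_params(span = 0.07,
                                                     min_prominence_frac = 0.25),
                                 seed = 1L) {
  set.seed(seed)
  true_age <- sample(ages, n_fish, replace = TRUE)
  quarter <- sample(quarters, n_fish, replace = TRUE)
  rows <- lapply(seq_len(n_fish), function(i) {
    t_catch <- true_age[i] + 1 / 12 + 0.2 * (quarter[i] - 1)
    edge <- 1200 * (1 - exp(-0.25 * t_catch))
    pr <- simulate_otolith_profile(true_age[i], edge_radius = edge,
                                   step = edge / 220, noise_sd = noise_sd,
                                   seed = seed * 3000L + i,
                                   catch_quarter = quarter[i])
    est <- estimate_age(pr, params)
    data.frame(true_age = true_age[i], est_age = est$age,
               flag = est$consensus_flag)
  })
  tab <- do.call(rbind, rows)
  list(exact_rate = mean(!is.na(tab$est_age) & tab$est_age == tab$true_age),
       needs_review_rate = mean(tab$flag == "needs_review"),
       fish = tab)
}

#' Neutral drift envelope of the lagged temporal autocovariances
#'
#' Runs `n_reps` Wright-Fisher replicates at the study's null conditions
#' (N = 2500 diploids, 100-generation burn-in, 20 diploids sampled in each
#' of five consecutive generations) and returns the replicate distribution
#' of the lag-2 and lag-3 autocovariances of allele-frequency change,
#' together with the Monte-Carlo standard error of their means and the
#' analytic neutral expectation. The paired intervals of a lag-l statistic
#' overlap in l - 1 generations of shared drift, so even under pure
#' neutrality the expectation is not exactly zero but
#' +E[p(1-p)]/(2N) per shared generation -- about 1.2e-5 per generation at
#' N = 2500, far below the sampling precision of a whole-genome study but
#' resolvable by this experiment's Monte-Carlo precision.
#'
#' @param n_reps replicates.
#' @param n_loci unlinked loci per replicate.
#' @param config [sim_config()].
#' @param seed integer seed.
#' @return list with per-lag mean, MC standard error, and replicate values.
#' @export
study_neutral_covariance <- function(n_reps = 100, n_loci = 5000,
                                     config = sim_config(), seed = 1L) {
  lag2 <- lag3 <- pred2 <- pred3 <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    w <- simulate_wright_fisher(config, n_loci, seed = seed * 4000L + r)
    fr <- allele_frequencies(w$genotypes)
    lag2[r] <- mean(lag_autocovariances(fr, 2)$value)
    lag3[r] <- mean(lag_autocovariances(fr, 3)$value)
    # analytic drift-overlap expectation: paired lag-l intervals share
    # (l - 1) generations of drift, each contributing E[p(1-p)]/(2N);
    # evaluated at the true frequencies of the shared generations
    f_true <- w$freq_true[w$sampled_gens, , drop = FALSE]
    pq <- rowMeans(f_true * (1 - f_true))
    N2 <- 2 * config$n_diploid
    # lag-2 pairs (i, i+1): share generation i+1 -> i+2
    pred2[r] <- mean(pq[2:3]) / N2
    # lag-3 pair shares generations 2->3 and 3->4
    pred3[r] <- (pq[2] + pq[3]) / N2
  }
  list(lag2_mean = mean(lag2), lag2_se = sd(lag2) / sqrt(n_reps),
       lag3_mean = mean(lag3), lag3_se = sd(lag3) / sqrt(n_reps),
       lag2_pred = mean(pred2), lag3_pred = mean(pred3),
       lag2 = lag2, lag3 = lag3)
}

#' Null calibration of the focal-subset permutation test
#'
#' Under neutral drift every locus subset is exchangeable, so the one-sided
#' empirical p-value of [subset_permutation_test()] on a random focal subset
#' is uniform; the rejection rate at alpha = 0.05 estimates the test size.
#'
#' @param n_reps null repetitions (each with an independent simulation).
#' @param B permutations per test (reduced for runtime).
#' @param n_loci,n_focal loci per replicate and focal subset size.
#' @param config [sim_config()]; the default shrinks the population for
#'   runtime, which does not affect exchangeability.
#' @param lag autocovariance lag.
#' @param seed integer seed.
#' @return list: `rejection_rate`, vector of p-values.
#' @export
study_subset_calibration <- function(n_reps = 200, B = 199, n_loci = 1000,
                                     n_focal = 100,
                                     config = sim_config(n_diploid = 500,
                                                         burn_in = 20),
                                     lag = 2, seed = 1L) {
  pvals <- vapply(seq_len(n_reps), function(r) {
    w <- simulate_wright_fisher(config, n_loci, seed = seed * 5000L + r)
    fr <- allele_frequencies(w$genotypes)
    set.seed(seed * 5000L + r + 7L)
    focal <- sample.int(n_loci, n_focal)
    subset_permutation_test(fr, focal, lag = lag, B = B,
                            seed = seed * 6000L + r)$p_emp
  }, numeric(1))
  list(rejection_rate = mean(pvals <= 0.05), pvals = pvals)
}

#' Null calibration of the overlap randomization test
#'
#' Draws the "observed" SNP set from the same distribution as the null
#' draws (uniformly among all loci), so p_emp should be uniform up to the
#' discreteness of overlap counts.
#'
#' @param n_reps null repetitions.
#' @param B random draws per test.
#' @param n_loci loci per replicate.
#' @param n_windows_out outlier windows (of 20 kb) per replicate.
#' @param n_draw size of the observed / drawn SNP sets.
#' @param seq_length genome length over which loci are placed.
#' @param seed integer seed.
#' @return list: `rejection_rate`, vector of p-values.
#' @export
study_overlap_calibration <- function(n_reps = 200, B = 199, n_loci = 10000,
                                      n_windows_out = 100, n_draw = 300,
                                      seq_length = 30e6, seed = 1L) {
  n_win <- seq_length %/% 20000
  pvals <- vapply(seq_len(n_reps), function(r) {
    set.seed(seed * 7000L + r)
    loci <- data.frame(chrom = "sim1",
                       pos = sort(sample.int(seq_length, n_loci)))
    w0 <- sort(sample.int(n_win, n_windows_out)) - 1
    win <- data.frame(chrom = "sim1", start = w0 * 20000 + 1,
                      end = (w0 + 1) * 20000 + 1)
    obs <- loci[sample.int(n_loci, n_draw), ]
    overlap_randomization_test(loci, win, obs, B = B,
                               seed = seed * 8000L + r)$p_emp
  }, numeric(1))
  list(rejection_rate = mean(pvals <= 0.05), pvals = pvals)
}

#' Power of the focal-locus autocovariance test under size-selective harvest
#'
#' Simulates the default polygenic harvest scenario and applies
#' [subset_permutation_test()] with the causal loci as the focal set
#' (lag 3, the longest disjoint-endpoint lag the five-time-point design
#' allows, where directional change accumulates most).
#'
#' @param n_reps replicates.
#' @param n_loci loci per replicate (causal subset per
#'   [selection_config()]).
#' @param B permutations.
#' @param config,sel study conditions; defaults are the package defaults.
#' @param lag autocovariance lag.
#' @param seed integer seed.
#' @return list: `power` (share of replicates with p <= 0.05), p-values.
#' @export
study_selection_power <- function(n_reps = 50, n_loci = 2000, B = 199,
                                  config = sim_config(), sel = selection_config(),
                                  lag = 3, seed = 1L) {
  pvals <- vapply(seq_len(n_reps), function(r) {
    s <- simulate_polygenic_selection(config, sel, n_loci,
                                      seed = seed * 9000L + r)
    fr <- allele_frequencies(s$genotypes)
    subset_permutation_test(fr, s$truth$causal_loci, lag = lag, B = B,
                            seed = seed * 10000L + r)$p_emp
  }, numeric(1))
  list(power = mean(pvals <= 0.05), pvals = pvals)
}

#' Power of the association-scan to differentiation-overlap chain
#'
#' Reduced-scale version of the integrative test. A polygenic harvest
#' scenario (20 causal loci, exponential effects, logistic size-selective
#' removal) runs over five sampled generations; the association panel is the
#' 150 fish sampled across all five time points (30 per generation), as in a
#' temporal study design, with a growth-performance-like phenotype built
#' from their causal genotypes at heritability ~0.4. Because the phenotype
#' declines with the selected allele frequencies, loci under selection gain
#' association signal from the temporal cline on top of the within-sample
#' signal -- the situation the integrative test is designed for. Weighted
#' 20-kb Fst windows contrast the full first and last generations (the
#' census differentiation the catch samples estimate), the top 5 percent are
#' outlier windows, the scan's 1 percent p-value tail defines outlier SNPs,
#' and the overlap is referred to the randomization null.
#'
#' @param n_reps replicates.
#' @param n_loci SNPs per replicate.
#' @param h2 phenotype heritability.
#' @param tail scan tail defining outlier SNPs; 1 percent of the ~6000 SNPs
#'   passing the MAF filter keeps the outlier set both enriched and large
#'   enough to aggregate, the role the 0.05 percent tail plays at
#'   whole-genome scale.
#' @param B randomization draws.
#' @param config,sel study conditions (population reduced to 1000 diploids
#'   for runtime; harvest steepness 3 and mean effect 0.4 emulate sharply
#'   size-selective, heavy exploitation).
#' @param seed integer seed.
#' @return list: `power`, p-values, mean observed overlap.
#' @export
study_gwa_overlap_power <- function(n_reps = 50, n_loci = 10000,
                                    h2 = 0.4, tail = 0.01, B = 999,
                                    config = sim_config(n_diploid = 1000,
                                                        burn_in = 30,
                                                        sample_size = 30),
                                    sel = selection_config(n_causal_loci = 20,
                                                           effect_mean = 0.4,
                                                           harvest_fraction = 0.6,
                                                           harvest_steepness = 3),
                                    seed = 1L) {
  pvals <- overlaps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- simulate_polygenic_selection(config, sel, n_loci,
                                      seed = seed * 11000L + r)
    gt <- s$genotypes
    pop <- rbind(s$population_first, s$population)
    gt_pop <- genotype_table(pop, gt$loci,
                             data.frame(sample_id = sprintf("p%05d",
                                                            seq_len(nrow(pop)))),
                             validate = FALSE)
    grp <- rep(c("first", "last"), each = nrow(s$population_first))
    fw <- fst_windows(gt_pop, grp, window_bp = 20000)
    fst_top <- select_fst_outlier_windows(fw, top = 0.05)

    set.seed(seed * 12000L + r)
    gscore <- drop(gt$dosage[, s$truth$causal_loci, drop = FALSE] %*%
                     s$truth$effect_sizes)
    phi <- drop(scale(gscore)) * sqrt(h2) +
      rnorm(nrow(gt$dosage), 0, sqrt(1 - h2))
    K <- kinship_matrix(gt, maf_min = 0.01)
    assoc <- lmm_assoc_scan(gt, phi, K = K, maf_min = 0.05)
    out <- select_gwa_outliers(assoc, tail = tail)
    ov <- overlap_randomization_test(assoc[, c("chrom", "pos")], fst_top,
                                     out$loci[, c("chrom", "pos")],
                                     B = B, seed = seed * 13000L + r)
    pvals[r] <- ov$p_emp
    overlaps[r] <- ov$observed
  }
  list(power = mean(pvals <= 0.05), pvals = pvals,
       mean_observed_overlap = mean(overlaps))
}
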