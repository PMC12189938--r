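#' Simulation configuration for temporal genotype data
#'
#' Holds the demographic and sampling parameters of the forward simulations.
#' Defaults reproduce the study conditions of the neutral null this package
#' tests against: 2500 diploids (5000 genomes), a 30-Mb sequence with
#' mutation rate 3.5e-9 and recombination rate 3.11e-8 per bp per generation,
#' a 100-generation burn-in, then 20 diploids sampled in each of five
#' consecutive generations, replicated 100 times. The mutation and
#' recombination rates are carried for coalescent cross-checks; loci in the
#' forward simulators are unlinked, so they do not enter the dynamics.
#'
#' @param n_diploid diploid population size N.
#' @param seq_length sequence length in bp over which loci are placed.
#' @param mu per-bp per-generation mutation rate (metadata only).
#' @param rec per-bp per-generation recombination rate (metadata only).
#' @param burn_in neutral generations discarded before sampling starts.
#' @param n_sample_times number of sampled generations (one per generation).
#' @param sample_size diploids sampled without replacement per time point.
#' @param n_replicates default replicate count for null distributions.
#' @param seed optional integer seed stored with the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_diploid = 2500, seq_length = 30e6, mu = 3.5e-9,
                       rec = 3.11e-8, burn_in = 100, n_sample_times = 5,
                       sample_size = 20, n_replicates = 100, seed = NULL) {
  stopifnot(n_diploid >= 1, seq_length >= 1, mu >= 0, rec >= 0,
            burn_in >= 0, n_sample_times >= 1, sample_size >= 1,
            n_replicates >= 1)
  if (sample_size > n_diploid) stop("sample_size must not exceed n_diploid")
  structure(list(n_diploid = n_diploid, seq_length = seq_length, mu = mu,
                 rec = rec, burn_in = burn_in, n_sample_times = n_sample_times,
                 sample_size = sample_size, n_replicates = n_replicates,
                 seed = seed),
            class = "sim_config")
}

#' Size-selective harvest configuration
#'
#' Parameters of the polygenic viability-selection emulation of fishing
#' pressure. Each generation an individual's trait is the additive score over
#' the causal loci plus Normal(0, env_sd) noise, and its survival probability
#' declines logistically with the trait so that on average `harvest_fraction`
#' of the population is removed. Defaults describe a stock at peak
#' exploitation: 65 percent annual removal (fishing mortality near 1, two to
#' three times sustainable levels), a sharply size-selective removal curve
#' (logistic steepness 3, as for trawl gear), and a highly polygenic trait
#' of 100 loci with unit environmental standard deviation.
#'
#' Per-locus effects default to exponential draws with mean `effect_mean`
#' (made at simulation time from the simulation seed), the usual polygenic
#' architecture of few large and many small effects. The heterogeneity
#' matters: the temporal autocovariance statistics respond to the variance
#' of the selection response across loci, so equal effects at equal
#' frequencies would produce a uniform shift that cross-locus covariance
#' cannot see.
#'
#' @param n_causal_loci number of causal loci.
#' @param effect_mean mean of the exponential effect-size distribution
#'   (trait units per allele; positive effects increase the harvested
#'   trait).
#' @param effect_sizes optional explicit per-locus effects (recycled to
#'   length `n_causal_loci`), overriding the exponential draws.
#' @param env_sd environmental (residual) trait standard deviation.
#' @param harvest_fraction mean proportion removed each generation, in [0, 1).
#' @param harvest_steepness logistic slope of removal probability vs trait.
#' @param min_causal_maf causal loci are drawn among loci whose initial minor
#'   allele frequency is at least this value, so effects act on segregating
#'   variation.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(n_causal_loci = 100, effect_mean = 0.2,
                             effect_sizes = NULL,
                             env_sd = 1, harvest_fraction = 0.65,
                             harvest_steepness = 3, min_causal_maf = 0.1) {
  stopifnot(n_causal_loci >= 1, env_sd >= 0, harvest_steepness > 0,
            min_causal_maf >= 0, min_causal_maf < 0.5, effect_mean > 0)
  if (harvest_fraction < 0 || harvest_fraction >= 1) {
    stop("harvest_fraction must be in [0, 1)")
  }
  structure(list(n_causal_loci = n_causal_loci, effect_mean = effect_mean,
                 effect_sizes = if (is.null(effect_sizes)) NULL else
                   rep_len(effect_sizes, n_causal_loci),
                 env_sd = env_sd, harvest_fraction = harvest_fraction,
                 harvest_steepness = harvest_steepness,
                 min_causal_maf = min_causal_maf),
            class = "selection_config")
}

#' Draw initial allele frequencies from the neutral site-frequency spectrum
#'
#' Frequencies follow density proportional to 1/p truncated to
#' [1/(2N), 1 - 1/(2N)], the stationary neutral SFS shape, sampled by
#' inverse-CDF transform.
#'
#' @param n_loci number of loci.
#' @param n_diploid diploid population size (sets the truncation).
#' @return numeric vector of frequencies.
#' @export
rsfs <- function(n_loci, n_diploid) {
  stopifnot(n_loci >= 1, n_diploid >= 1)
  p0 <- 1 / (2 * n_diploid)
  p1 <- 1 - p0
  p0 * (p1 / p0)^runif(n_loci)
}

# Place n_loci sorted, distinct positions on [1, seq_length].
.sim_positions <- function(n_loci, seq_length) {
  sort(sample.int(seq_length, n_loci))
}

# Distribute `alt` alternate-allele copies (per locus) at random among the
# 2 * n_s allele slots of n_s diploids; returns an n_s x n_loci dosage matrix.
.alleles_to_dosages <- function(alt, n_s) {
  L <- length(alt)
  u <- matrix(runif(2 * n_s * L), nrow = 2 * n_s, ncol = L)
  thr <- vapply(seq_len(L), function(j) {
    a <- alt[j]
    if (a == 0) return(-Inf)
    sort(u[, j], partial = a)[a]
  }, numeric(1))
  slot <- sweep(u, 2, thr, "<=")
  slot[seq_len(n_s), , drop = FALSE] +
    slot[n_s + seq_len(n_s), , drop = FALSE]
}

# Build a genotype_table from a list of per-time dosage matrices.
.sim_genotype_table <- function(dosage_by_time, pos, seq_length,
                                year_labels = NULL) {
  nt <- length(dosage_by_time)
  ns <- vapply(dosage_by_time, nrow, integer(1))
  dosage <- do.call(rbind, dosage_by_time)
  time_index <- rep(seq_len(nt), ns)
  ids <- sprintf("t%d_s%03d", time_index, unlist(lapply(ns, seq_len)))
  if (is.null(year_labels)) year_labels <- seq_len(nt)
  samples <- data.frame(sample_id = ids, time_index = time_index,
                        year_label = year_labels[time_index],
                        sex = rep_len(c("F", "M"), length(ids)),
                        stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "sim1", pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  genotype_table(dosage, loci, samples)
}

#' Simulate neutral Wright-Fisher drift with temporal sampling
#'
#' Unlinked biallelic loci evolve by multinomial resampling of 2N allele
#' copies per generation. Initial frequencies are drawn from the neutral SFS
#' (see [rsfs()]). After `burn_in` generations, `sample_size` diploids are
#' drawn without replacement in each of `n_sample_times` consecutive
#' generations, emulating the catch-sample scheme of a temporal population
#' study. Fixed or lost loci stay fixed or lost.
#'
#' @param config [sim_config()].
#' @param n_loci number of unlinked loci.
#' @param seed integer seed; the run is bit-reproducible given it.
#' @return list of class `wf_sim` with elements `genotypes` (genotype_table
#'   over all time points), `freq_true` (generations+1 x loci matrix of true
#'   frequencies, row 1 = initial state), `sampled_gens` (row indices of
#'   `freq_true` at which samples were taken), and `config`.
#' @export
simulate_wright_fisher <- function(config = sim_config(), n_loci, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_loci >= 1)
  set.seed(seed)
  N2 <- 2L * config$n_diploid
  n_gen <- config$burn_in + config$n_sample_times
  cnt <- round(rsfs(n_loci, config$n_diploid) * N2)
  cnt <- pmin(pmax(cnt, 1L), N2 - 1L)
  freq <- matrix(NA_real_, n_gen + 1L, n_loci)
  freq[1L, ] <- cnt / N2
  dosage_by_time <- vector("list", config$n_sample_times)
  sampled <- integer(0)
  for (g in seq_len(n_gen)) {
    cnt <- rbinom(n_loci, N2, cnt / N2)
    freq[g + 1L, ] <- cnt / N2
    t_idx <- g - config$burn_in
    if (t_idx >= 1L) {
      alt <- rhyper(n_loci, cnt, N2 - cnt, 2L * config$sample_size)
      dosage_by_time[[t_idx]] <- .alleles_to_dosages(alt, config$sample_size)
      sampled <- c(sampled, g + 1L)
    }
  }
  gt <- .sim_genotype_table(dosage_by_time,
                            .sim_positions(n_loci, config$seq_length),
                            config$seq_length)
  structure(list(genotypes = gt, freq_true = freq, sampled_gens = sampled,
                 config = config, seed = seed),
            class = "wf_sim")
}

#' Simulate polygenic size-selective mortality (fisheries harvest)
#'
#' Individual-based forward simulation. A neutral frequency-only burn-in
#' (exchangeable individuals) precedes the sampled window; individuals are
#' then instantiated at Hardy-Weinberg proportions and, in each sampled
#' generation, (i) `sample_size` individuals are drawn without replacement as
#' the "catch" sample, (ii) survival is Bernoulli with probability declining
#' logistically in the additive trait, centred each generation so the
#' expected removal equals `harvest_fraction`, and (iii) survivors mate at
#' random (two parents per offspring, Mendelian transmission at unlinked
#' loci) to produce the next generation of N diploids. With
#' `harvest_fraction = 0` the model reduces to neutral individual-based
#' Wright-Fisher reproduction.
#'
#' Because harvest removes large-trait individuals, trait-increasing alleles
#' at causal loci are expected to decline -- the directional signal the
#' temporal covariance statistics are designed to detect.
#'
#' @param config [sim_config()].
#' @param sel [selection_config()].
#' @param n_loci total number of loci (causal loci are a random subset with
#'   initial minor allele frequency >= `sel$min_causal_maf`).
#' @param seed integer seed.
#' @return list of class `polysel_sim` with `genotypes`, `freq_true`
#'   (rows: initial state, end of burn-in instantiation, then each sampled
#'   generation), `sampled_gens`, `traits` (list per time point, traits of
#'   the sampled individuals), `truth` (causal indices, effects, per-sampled-
#'   generation true frequencies), `population` / `population_first` (full
#'   dosage matrices at the last and first sampled generations, for
#'   census-scale contrasts), and `config`/`sel`.
#' @export
simulate_polygenic_selection <- function(config = sim_config(), sel = selection_config(),
                                         n_loci, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(sel, "selection_config"),
            n_loci >= 1)
  if (sel$n_causal_loci > n_loci) stop("n_causal_loci exceeds total loci")
  set.seed(seed)
  N <- config$n_diploid
  N2 <- 2L * N
  cnt <- round(rsfs(n_loci, N) * N2)
  cnt <- pmin(pmax(cnt, 1L), N2 - 1L)
  p_init <- cnt / N2
  # neutral burn-in on frequencies only
  for (g in seq_len(config$burn_in)) cnt <- rbinom(n_loci, N2, cnt / N2)
  p <- cnt / N2
  eligible <- which(pmin(p_init, 1 - p_init) >= sel$min_causal_maf)
  if (length(eligible) < sel$n_causal_loci) {
    stop("not enough loci with initial MAF >= min_causal_maf for causal set")
  }
  causal <- sort(sample(eligible, sel$n_causal_loci))
  eff <- if (is.null(sel$effect_sizes)) {
    stats::rexp(sel$n_causal_loci, rate = 1 / sel$effect_mean)
  } else {
    sel$effect_sizes
  }
  # instantiate diploids at HWE given post-burn-in frequencies
  geno <- .hwe_genotypes(p, N)
  n_t <- config$n_sample_times
  freq <- matrix(NA_real_, n_t + 2L, n_loci)
  freq[1L, ] <- p_init
  freq[2L, ] <- colMeans(geno) / 2
  dosage_by_time <- vector("list", n_t)
  traits_by_time <- vector("list", n_t)
  geno_first <- geno
  for (t in seq_len(n_t)) {
    freq[t + 2L, ] <- colMeans(geno) / 2
    idx <- sample.int(N, config$sample_size)
    z <- drop(geno[, causal, drop = FALSE] %*% eff) +
      rnorm(N, 0, sel$env_sd)
    dosage_by_time[[t]] <- geno[idx, , drop = FALSE]
    traits_by_time[[t]] <- z[idx]
    if (t == n_t) break
    if (sel$harvest_fraction > 0) {
      b <- sel$harvest_steepness
      # centre the logistic so mean survival = 1 - harvest_fraction
      f <- function(cc) mean(plogis(-b * (z - cc))) - (1 - sel$harvest_fraction)
      cc <- uniroot(f, lower = min(z) - 50 / b, upper = max(z) + 50 / b)$root
      alive <- which(runif(N) < plogis(-b * (z - cc)))
      if (length(alive) == 0L) {
        stop("all individuals removed by harvest in generation ", t,
             " (harvest_fraction = ", sel$harvest_fraction,
             ", steepness = ", sel$harvest_steepness, ")")
      }
    } else {
      alive <- seq_len(N)
    }
    mothers <- alive[sample.int(length(alive), N, replace = TRUE)]
    fathers <- alive[sample.int(length(alive), N, replace = TRUE)]
    geno <- .mendelian_offspring(geno, mothers, fathers)
  }
  gt <- .sim_genotype_table(dosage_by_time,
                            .sim_positions(n_loci, config$seq_length),
                            config$seq_length)
  truth <- list(causal_loci = causal, effect_sizes = eff,
                freq_sampled = freq[2L + seq_len(n_t), , drop = FALSE])
  structure(list(genotypes = gt, freq_true = freq,
                 sampled_gens = 2L + seq_len(n_t), traits = traits_by_time,
                 truth = truth, population = geno,
                 population_first = geno_first,
                 config = config, sel = sel, seed = seed),
            class = "polysel_sim")
}
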