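#' Default configuration for the end-to-end synthetic study
#'
#' Builds the nested parameter blocks consumed by [run_pipeline()]. Every
#' stage can be toggled; sizes default to a desk-scale synthetic study that
#' exercises all modules in a few minutes. The global seed fans out to
#' per-stage substreams (`seed + fixed offset` per stage), so disabling one
#' stage leaves the randomness of the others unchanged.
#'
#' @param seed global seed.
#' @param stages character vector of stages to run, in dependency order.
#' @param n_loci loci in the genotype simulation.
#' @param sim [sim_config()] for the genotype stage.
#' @param sel `NULL` for neutral drift or a [selection_config()].
#' @param growth_groups data.frame of true group VBGF parameters.
#' @param n_per_group fish per growth group.
#' @param out_dir optional directory; when set, stage outputs are written
#'   (VCF, CSVs) and hashed into the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "aging", "growth",
                                       "covariance", "scan", "gwa"),
                            n_loci = 2000,
                            sim = sim_config(n_diploid = 500, burn_in = 20,
                                             sample_size = 50),
                            sel = selection_config(),
                            growth_groups = data.frame(
                              Linf = seq(1150, 539, length.out = 5),
                              k = seq(0.15, 0.40, length.out = 5),
                              t0 = 0),
                            n_per_group = 10,
                            out_dir = NULL) {
  known <- c("simulate", "aging", "growth", "covariance", "scan", "gwa")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages, n_loci = n_loci,
                 sim = sim, sel = sel, growth_groups = growth_groups,
                 n_per_group = n_per_group, out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Diagnostic checks without mutation: dosage sanity and biallelic coding of
#' the genotype table, metadata join completeness, and monotonicity of
#' otolith profile distances.
#'
#' @param gt genotype_table or `NULL`.
#' @param metadata data.frame with `sample_id` or `NULL`.
#' @param profiles list of otolith_profile or `NULL`.
#' @return character vector of findings (empty when clean).
#' @export
validate_inputs <- function(gt = NULL, metadata = NULL, profiles = NULL) {
  findings <- character(0)
  if (!is.null(gt)) {
    bad <- which(!(gt$dosage %in% c(0, 1, 2) | is.na(gt$dosage)))
    if (length(bad)) findings <- c(findings, "non-diploid dosage values present")
    if (!is.null(metadata)) {
      miss <- setdiff(gt$samples$sample_id, metadata$sample_id)
      if (length(miss)) {
        findings <- c(findings, paste("samples absent from metadata:",
                                      paste(miss, collapse = ", ")))
      }
    }
    multi <- grepl(",", gt$loci$alt)
    if (any(multi)) {
      findings <- c(findings,
                    paste("multiallelic records at:",
                          paste(paste(gt$loci$chrom[multi], gt$loci$pos[multi],
                                      sep = ":"), collapse = ", ")))
    }
  }
  if (!is.null(profiles)) {
    for (pr in profiles) {
      if (is.unsorted(pr$distances, strictly = TRUE)) {
        findings <- c(findings,
                      paste("profile", pr$fish_id, "has non-increasing distances"))
      }
    }
  }
  findings
}

#' Run the end-to-end synthetic study
#'
#' Executes the enabled stages in dependency order: genotype simulation
#' (drift or size-selective harvest), otolith simulation + chemical aging,
#' hierarchical growth fit + growth performance index, temporal covariance
#' with focal-subset permutation, windowed Fst scan, and the association ->
#' overlap chain. Identical config and seed give identical reports (wall
#' time aside).
#'
#' @param config [pipeline_config()].
#' @return list of class `run_report`: per-stage key outputs, parameter
#'   echo, seed, wall times, and file hashes when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  report <- list(seed = config$seed, stages = st, params = config,
                 outputs = list(), timing = list(), hashes = list())
  tic <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    report$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  need <- function(dep, stage) {
    if (is.null(report$outputs[[dep]])) {
      stop("stage '", stage, "' requires output of stage '", dep, "'")
    }
  }
  sim <- NULL
  if ("simulate" %in% st) {
    sim <- tic({
      if (is.null(config$sel)) {
        simulate_wright_fisher(config$sim, config$n_loci,
                               seed = config$seed + 101L)
      } else {
        simulate_polygenic_selection(config$sim, config$sel, config$n_loci,
                                     seed = config$seed + 101L)
      }
    }, "simulate")
    report$outputs$simulate <- list(
      n_loci = config$n_loci,
      n_samples = nrow(sim$genotypes$dosage),
      causal = if (!is.null(sim$truth)) length(sim$truth$causal_loci) else 0)
  }
  if ("aging" %in% st || "growth" %in% st) {
    cohort <- tic(simulate_growth_cohort(config$growth_groups,
                                         n_per_group = config$n_per_group,
                                         indiv_sd = 0.08, obs_sd = 5,
                                         seed = config$seed + 202L),
                  "growth_cohort")
    report$outputs$growth_cohort <- list(
      n_fish = length(unique(cohort$observations$fish_id)))
  }
  if ("aging" %in% st) {
    ages <- tic({
      fish <- unique(cohort$observations$fish_id)
      n_show <- min(20L, length(fish))
      truth_age <- cohort$truth$fish$age[match(fish, cohort$truth$fish$fish_id)]
      res <- vapply(seq_len(n_show), function(i) {
        pr <- simulate_otolith_profile(truth_age[i], edge_radius = 1000,
                                       step = 5, noise_sd = 0.05,
                                       seed = config$seed + 300L + i)
        est <- estimate_age(pr)
        identical(est$age, as.integer(pr$truth$age))
      }, logical(1))
      mean(res)
    }, "aging")
    report$outputs$aging <- list(exact_age_rate = ages)
  }
  if ("growth" %in% st) {
    fitres <- tic({
      fit <- fit_hierarchical_vbgf(cohort$observations,
                                   mcmc = mcmc_preset("test"),
                                   seed = config$seed + 404L)
      med <- apply(do.call(rbind, fit$draws), 2, median)
      groups <- fit$groups
      Lg <- med[paste0("Linf_g[", groups, "]")]
      kg <- med[paste0("k_g[", groups, "]")]
      Li <- med[paste0("Linf_i[", fit$fish, "]")]
      ki <- med[paste0("k_i[", fit$fish, "]")]
      list(fit = fit,
           phi = data.frame(fish_id = fit$fish,
                            phi = growth_performance_index(Li, ki)),
           group_Linf = Lg, group_k = kg,
           max_rhat = max(fit$rhat, na.rm = TRUE))
    }, "growth")
    report$outputs$growth <- list(
      group_Linf = round(fitres$group_Linf, 2),
      group_k = round(fitres$group_k, 4),
      phi_summary = summary(fitres$phi$phi),
      max_rhat = fitres$max_rhat)
  }
  if ("covariance" %in% st) {
    need("simulate", "covariance")
    covres <- tic({
      fr <- allele_frequencies(sim$genotypes)
      lags <- rbind(lag_autocovariances(fr, 2), lag_autocovariances(fr, 3))
      focal <- if (!is.null(sim$truth)) sim$truth$causal_loci else
        seq_len(min(50, config$n_loci))
      pt <- subset_permutation_test(fr, focal, lag = 3, B = 500,
                                    seed = config$seed + 505L)
      list(lags = lags, perm = pt)
    }, "covariance")
    report$outputs$covariance <- list(lags = covres$lags,
                                      perm_p = covres$perm$p_emp,
                                      perm_observed = covres$perm$observed)
  }
  if ("scan" %in% st || "gwa" %in% st) {
    need("simulate", "scan")
    first_last <- sim$genotypes$samples$time_index %in%
      range(sim$genotypes$samples$time_index)
    gt_fl <- subset_genotypes(sim$genotypes, samples = first_last)
    fw <- tic(fst_windows(gt_fl, gt_fl$samples$time_index, window_bp = 20000),
              "scan")
    report$outputs$scan <- list(
      n_windows = nrow(fw),
      genomewide_fst = sum(fw$sum_a, na.rm = TRUE) /
        sum(fw$sum_a + fw$sum_b + fw$sum_c, na.rm = TRUE))
  }
  if ("gwa" %in% st) {
    need("simulate", "gwa")
    if (is.null(report$outputs$growth)) {
      stop("stage 'gwa' requires the growth performance index from stage 'growth'",
           " (or disable gwa)")
    }
    gwres <- tic({
      last_t <- max(sim$genotypes$samples$time_index)
      gt_last <- subset_genotypes(sim$genotypes,
                                  samples = sim$genotypes$samples$time_index == last_t)
      n_s <- nrow(gt_last$dosage)
      set.seed(config$seed + 606L)
      # attach Phi-like phenotype: causal-locus score plus noise, mimicking
      # a heritable growth performance index on the sampled genomes
      if (!is.null(sim$truth)) {
        gvals <- gt_last$dosage[, sim$truth$causal_loci, drop = FALSE] %*%
          sim$truth$effect_sizes
      } else {
        gvals <- rnorm(n_s)
      }
      phi <- scale(gvals) * sqrt(0.4) + rnorm(n_s, 0, sqrt(0.6))
      K <- kinship_matrix(gt_last, maf_min = 0.01)
      assoc <- lmm_assoc_scan(gt_last, phi, K = K, maf_min = 0.05)
      out <- select_gwa_outliers(assoc, tail = 0.005)
      fst_top <- select_fst_outlier_windows(fw, top = 0.05)
      ov <- overlap_randomization_test(assoc[, c("chrom", "pos")], fst_top,
                                       out$loci[, c("chrom", "pos")],
                                       B = 1000, seed = config$seed + 707L)
      list(lambda_gc = genomic_inflation(assoc), n_outliers = nrow(out$loci),
           observed_overlap = ov$observed, p_emp = ov$p_emp)
    }, "gwa")
    report$outputs$gwa <- gwres
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sim)) {
      vcf <- file.path(config$out_dir, "genotypes.vcf")
      write_vcf(sim$genotypes, vcf)
      meta <- file.path(config$out_dir, "samples.csv")
      write.csv(sim$genotypes$samples, meta, row.names = FALSE)
      report$hashes <- as.list(tools::md5sum(c(vcf, meta)))
    }
    jsonlite::write_json(report$outputs,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ")\n")
  for (s in names(x$outputs)) {
    cat("  stage", s, "done in", x$timing[[s]] %||% NA, "s\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
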