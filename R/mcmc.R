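#' MCMC preset for the hierarchical growth model
#'
#' `"paper"` mirrors the full-scale analysis settings (3 chains of 100,000
#' iterations, 10,000 burn-in, thin 10); `"test"` is the fast preset used
#' throughout the test suite (3 x 10,000 / 1,000 burn-in, thin 1).
#'
#' @param preset `"test"` or `"paper"`.
#' @param chains,iters,burn_in,thin override individual settings.
#' @return list with `chains`, `iters`, `burn_in`, `thin`.
#' @export
mcmc_preset <- function(preset = c("test", "paper"), chains = NULL,
                        iters = NULL, burn_in = NULL, thin = NULL) {
  preset <- match.arg(preset)
  out <- if (preset == "paper") {
    list(chains = 3L, iters = 100000L, burn_in = 10000L, thin = 10L)
  } else {
    list(chains = 3L, iters = 10000L, burn_in = 1000L, thin = 1L)
  }
  if (!is.null(chains)) out$chains <- as.integer(chains)
  if (!is.null(iters)) out$iters <- as.integer(iters)
  if (!is.null(burn_in)) out$burn_in <- as.integer(burn_in)
  if (!is.null(thin)) out$thin <- as.integer(thin)
  if (out$iters <= 0 || out$chains < 1 || out$thin < 1) {
    stop("iterations, chains and thin must be positive")
  }
  if (out$burn_in >= out$iters) stop("burn_in must be smaller than iters")
  out
}

#' Priors for the hierarchical von Bertalanffy model
#'
#' Group-level asymptotic radius and growth coefficient carry Gamma priors
#' with shape 2 and rates chosen so the prior means sit at data-scale
#' heuristics (1.5 x the largest observed radius for Linf; 0.3/yr for k);
#' t0 is Normal(0, 1) at group level. Individual log-parameters are Normal
#' around the log group values with half-Normal(0.5) hyper-SDs (a ~50
#' percent coefficient of variation upper scale), and the observation
#' variance has a vague inverse-gamma prior. All are overridable.
#'
#' @param obs annulus observations (data.frame with `La`).
#' @param mean_Linf,mean_k prior means of the group Gamma priors.
#' @param shape shape of both Gamma priors.
#' @param t0_mean,t0_sd Normal prior on group t0.
#' @param hyper_scale half-Normal scale of the log-scale hyper-SDs.
#' @param sig2_a,sig2_b inverse-gamma prior on the observation variance.
#' @return list of class `vbgf_priors`.
#' @export
vbgf_priors <- function(obs, mean_Linf = 1.5 * max(obs$La), mean_k = 0.3,
                        shape = 2, t0_mean = 0, t0_sd = 1,
                        hyper_scale = 0.5, sig2_a = 0.01, sig2_b = 0.01) {
  structure(list(shape_L = shape, rate_L = shape / mean_Linf,
                 shape_k = shape, rate_k = shape / mean_k,
                 t0_mean = t0_mean, t0_sd = t0_sd,
                 hyper_scale = hyper_scale,
                 sig2_a = sig2_a, sig2_b = sig2_b),
            class = "vbgf_priors")
}

# log density kernel of a Gamma prior expressed on the log scale (with
# Jacobian); normalising constants drop out of Metropolis ratios
.lp_gamma_log <- function(lx, shape, rate) {
  shape * lx - rate * exp(lx)
}

# half-normal log density for sd > 0, parameter on log(sd) (with Jacobian)
.lp_halfnorm_logsd <- function(lsd, scale) {
  dnorm(exp(lsd), 0, scale, log = TRUE) + lsd
}

# autocovariance (denominator n, as in acf) up to max_lag via FFT
.autocov_fft <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  np <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, np - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / np
  ac[seq_len(max_lag + 1)] / n
}

# univariate slice sampler (Neal 2003), step-out then shrink
.slice1 <- function(x0, logpost, w = 1, max_steps = 50) {
  y <- logpost(x0) - stats::rexp(1)
  lo <- x0 - w * runif(1)
  hi <- lo + w
  s <- 0
  while (logpost(lo) > y && s < max_steps) { lo <- lo - w; s <- s + 1 }
  s <- 0
  while (logpost(hi) > y && s < max_steps) { hi <- hi + w; s <- s + 1 }
  repeat {
    x1 <- runif(1, lo, hi)
    if (logpost(x1) >= y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

#' Fit the three-level hierarchical von Bertalanffy growth model
#'
#' Annulus radii at age, nested in fish, nested in groups (catch years).
#' Observation model: La ~ Normal(Linf_i * (1 - exp(-k_i * (ta - t0_g))),
#' sigma). Individual log(Linf_i) and log(k_i) are Normal around the log of
#' the group values with estimated hyper-SDs (log-scale sampling enforces
#' positivity); group Linf_g and k_g carry Gamma priors and t0_g a Normal
#' prior (see [vbgf_priors()]).
#'
#' Sampling is adaptive Metropolis-within-Gibbs: individual-level updates
#' are vectorised random-walk proposals accepted fish-wise (fish are
#' conditionally independent), group-level and hyper-SD updates are
#' random-walk Metropolis, and the observation variance is conjugate
#' inverse-gamma. Proposal scales adapt toward ~35 percent acceptance during
#' burn-in only, so the retained chain is a valid fixed-kernel Markov chain.
#'
#' @param obs data.frame of annulus observations: `fish_id`, `group_id`,
#'   `ta` (age at annulus, years), `La` (radius at annulus).
#' @param mcmc [mcmc_preset()].
#' @param priors [vbgf_priors()]; defaults derived from `obs`.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `growth_posterior`: `draws` (list of per-chain
#'   matrices, kept iterations x parameters), `params`, `rhat`, `ess`,
#'   `acceptance` (per update block), `residuals_by_age` (SD of posterior-
#'   median residuals per age), plus the inputs echoed.
#' @export
fit_hierarchical_vbgf <- function(obs, mcmc = mcmc_preset("test"),
                                  priors = NULL, seed = 1L) {
  stopifnot(all(c("fish_id", "group_id", "ta", "La") %in% names(obs)))
  if (is.null(priors)) priors <- vbgf_priors(obs)
  # order observations by group then fish so per-fish / per-group sums are
  # contiguous-block cumulative sums
  obs <- obs[order(match(obs$group_id, unique(obs$group_id)),
                   match(obs$fish_id, unique(obs$fish_id))), , drop = FALSE]
  fish <- factor(obs$fish_id, levels = unique(obs$fish_id))
  nf <- nlevels(fish)
  fidx <- as.integer(fish)
  grp_of_fish <- factor(tapply(as.character(obs$group_id), fidx, `[`, 1),
                        levels = unique(as.character(obs$group_id)))
  ng <- nlevels(grp_of_fish)
  gf <- as.integer(grp_of_fish)          # group of each fish
  gidx <- gf[fidx]                       # group of each observation
  if (any(table(gf) < 2)) stop("every group needs at least 2 fish")
  ta <- obs$ta
  La <- obs$La
  n_obs <- length(La)

  n_keep <- (mcmc$iters - mcmc$burn_in) %/% mcmc$thin
  pnames <- c(paste0("Linf_g[", levels(grp_of_fish), "]"),
              paste0("k_g[", levels(grp_of_fish), "]"),
              paste0("t0_g[", levels(grp_of_fish), "]"),
              "sd_log_Linf", "sd_log_k", "sigma_obs",
              paste0("Linf_i[", levels(fish), "]"),
              paste0("k_i[", levels(fish), "]"))
  run_chain <- function(chain) {
    set.seed(seed + chain - 1L)
    # data-driven initial values, jittered per chain: a crude per-fish k from
    # the ratio of the first two annuli (La2/La1 = 1 + exp(-k) at t0 = 0),
    # then Linf from the largest annulus given that k
    k_guess <- vapply(seq_len(nf), function(f) {
      i <- which(fidx == f)
      if (length(i) < 2) return(0.3)
      r <- La[i][order(ta[i])]
      ratio <- r[2] / r[1] - 1
      if (is.na(ratio) || ratio <= 0.01 || ratio >= 0.99) return(0.3)
      min(max(-log(ratio), 0.05), 1.5)
    }, numeric(1))
    Lmax_f <- as.numeric(tapply(La, fidx, max))
    age_f <- as.numeric(tapply(ta, fidx, max))
    L_guess <- pmax(Lmax_f / (1 - exp(-k_guess * age_f)), Lmax_f * 1.01)
    thL <- log(L_guess) + rnorm(nf, 0, 0.05)
    thK <- log(k_guess) + rnorm(nf, 0, 0.1)
    lgL <- as.numeric(tapply(thL, gf, mean)) + rnorm(ng, 0, 0.05)
    lgK <- as.numeric(tapply(thK, gf, mean)) + rnorm(ng, 0, 0.05)
    t0 <- rnorm(ng, 0, 0.1)
    lsdL <- log(0.2) + rnorm(1, 0, 0.1)
    lsdK <- log(0.2) + rnorm(1, 0, 0.1)
    sig2 <- var(La) / 10
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- (0.05 * mean(abs(La)))^2 + 1e-8

    # natural-scale per-fish parameter caches keep exp() off the long
    # observation vectors
    mu_of <- function(Lf, Kf, t0) {
      Lf[fidx] * (1 - exp(-Kf[fidx] * (ta - t0[gidx])))
    }
    Lf <- exp(thL); Kf <- exp(thK)
    obs_of_group <- split(seq_len(n_obs), gidx)
    # contiguous-block sums (observations are sorted by group then fish)
    ends_f <- c(which(diff(fidx) != 0L), n_obs)
    ends_g <- c(which(diff(gidx) != 0L), n_obs)
    ends_fg <- c(which(diff(gf) != 0L), nf)   # fish sorted by group
    blocksum <- function(x, ends) {
      s <- cumsum(x)[ends]
      s - c(0, s[-length(s)])
    }
    ssr_fish <- function(mu) blocksum((La - mu)^2, ends_f)
    nf_g <- as.numeric(table(gf))
    t0_prior_m <- priors$t0_mean; t0_prior_s <- priors$t0_sd
    shape_L <- priors$shape_L; rate_L <- priors$rate_L
    shape_k <- priors$shape_k; rate_k <- priors$rate_k
    mu <- mu_of(Lf, Kf, t0)
    ssrf <- ssr_fish(mu)

    scales <- c(thL = 0.05, thK = 0.1, ridge = 0.2, gshift = 0.1,
                t0k = 0.1, lgL = 0.05, lgK = 0.05, gridge = 0.1, t0 = 0.1,
                lsdL = 0.3, lsdK = 0.3)
    tbar_g <- as.numeric(tapply(ta, gidx, mean))
    acc <- n_try <- setNames(numeric(length(scales)), names(scales))
    draws <- matrix(NA_real_, n_keep, length(pnames))
    colnames(draws) <- pnames
    kept <- 0L

    for (it in seq_len(mcmc$iters)) {
      vL <- exp(2 * lsdL); vK <- exp(2 * lsdK)
      mL <- lgL[gf]; mK <- lgK[gf]

      # --- individual log(Linf): fish-wise vectorised MH
      prop <- thL + rnorm(nf, 0, scales["thL"])
      Lp <- exp(prop)
      mu_p <- mu_of(Lp, Kf, t0)
      ssrf_p <- ssr_fish(mu_p)
      lr <- (ssrf - ssrf_p) / (2 * sig2) +
        ((thL - mL)^2 - (prop - mL)^2) / (2 * vL)
      ok <- log(runif(nf)) < lr
      if (any(ok)) {
        thL[ok] <- prop[ok]; Lf[ok] <- Lp[ok]
        keep_obs <- ok[fidx]
        mu[keep_obs] <- mu_p[keep_obs]
        ssrf[ok] <- ssrf_p[ok]
      }
      acc["thL"] <- acc["thL"] + mean(ok); n_try["thL"] <- n_try["thL"] + 1

      # --- individual log(k)
      prop <- thK + rnorm(nf, 0, scales["thK"])
      Kp <- exp(prop)
      mu_p <- mu_of(Lf, Kp, t0)
      ssrf_p <- ssr_fish(mu_p)
      lr <- (ssrf - ssrf_p) / (2 * sig2) +
        ((thK - mK)^2 - (prop - mK)^2) / (2 * vK)
      ok <- log(runif(nf)) < lr
      if (any(ok)) {
        thK[ok] <- prop[ok]; Kf[ok] <- Kp[ok]
        keep_obs <- ok[fidx]
        mu[keep_obs] <- mu_p[keep_obs]
        ssrf[ok] <- ssrf_p[ok]
      }
      acc["thK"] <- acc["thK"] + mean(ok); n_try["thK"] <- n_try["thK"] + 1

      # --- anti-correlated ridge move: early-age radii constrain Linf * k,
      # so the individual posterior is a ridge along thL + thK = const;
      # moving both at once mixes along it (two sweeps: it is the slowest
      # direction)
      for (rep_ridge in 1:2) {
      e <- rnorm(nf, 0, scales["ridge"])
      propL <- thL + e; propK <- thK - e
      ee <- exp(e)
      Lp <- Lf * ee; Kp <- Kf / ee
      mu_p <- mu_of(Lp, Kp, t0)
      ssrf_p <- ssr_fish(mu_p)
      lr <- (ssrf - ssrf_p) / (2 * sig2) +
        ((thL - mL)^2 - (propL - mL)^2) / (2 * vL) +
        ((thK - mK)^2 - (propK - mK)^2) / (2 * vK)
      ok <- log(runif(nf)) < lr
      if (any(ok)) {
        thL[ok] <- propL[ok]; thK[ok] <- propK[ok]
        Lf[ok] <- Lp[ok]; Kf[ok] <- Kp[ok]
        keep_obs <- ok[fidx]
        mu[keep_obs] <- mu_p[keep_obs]
        ssrf[ok] <- ssrf_p[ok]
      }
      acc["ridge"] <- acc["ridge"] + mean(ok); n_try["ridge"] <- n_try["ridge"] + 1

      # --- whole-group ridge translation: move every fish of a group and
      # its group mean together along thL + thK = const; individual prior
      # terms are invariant, so this transports the slowest posterior mode
      # (the group's joint position on the Linf/k ridge) in one step
      e <- rnorm(ng, 0, scales["gshift"])
      propL <- thL + e[gf]; propK <- thK - e[gf]
      eg <- exp(e)[gf]
      Lp <- Lf * eg; Kp <- Kf / eg
      mu_p <- mu_of(Lp, Kp, t0)
      ssr_g <- blocksum((La - mu)^2, ends_g)
      ssr_gp <- blocksum((La - mu_p)^2, ends_g)
      pLg <- lgL + e; pKg <- lgK - e
      lr <- (ssr_g - ssr_gp) / (2 * sig2) +
        .lp_gamma_log(pLg, shape_L, rate_L) - .lp_gamma_log(lgL, shape_L, rate_L) +
        .lp_gamma_log(pKg, shape_k, rate_k) - .lp_gamma_log(lgK, shape_k, rate_k)
      ok <- log(runif(ng)) < lr
      if (any(ok)) {
        okf <- ok[gf]
        thL[okf] <- propL[okf]; thK[okf] <- propK[okf]
        Lf[okf] <- Lp[okf]; Kf[okf] <- Kp[okf]
        lgL[ok] <- pLg[ok]; lgK[ok] <- pKg[ok]
        keep_obs <- ok[gidx]
        mu[keep_obs] <- mu_p[keep_obs]
        ssrf <- ssr_fish(mu)
      }
      acc["gshift"] <- acc["gshift"] + mean(ok)
      n_try["gshift"] <- n_try["gshift"] + 1
      }

      # --- joint t0/k ridge: shifting a group's t0 trades off against its
      # growth coefficient (only k * (t - t0) is well constrained), so move
      # t0 and the group's k values together along that ridge; the shift in
      # (lgK, thK) is a translation (unit Jacobian) and individual prior
      # terms cancel
      e <- rnorm(ng, 0, scales["t0k"])
      feasible <- (tbar_g - t0 - e) > 0.05 & (tbar_g - t0) > 0.05
      e[!feasible] <- 0
      dlt <- numeric(ng)
      dlt[feasible] <- log(tbar_g[feasible] - t0[feasible]) -
        log(tbar_g[feasible] - t0[feasible] - e[feasible])
      propT <- t0 + e
      propK <- thK + dlt[gf]
      Kp <- Kf * exp(dlt[gf])
      pKg <- lgK + dlt
      mu_p <- mu_of(Lf, Kp, propT)
      ssr_g <- blocksum((La - mu)^2, ends_g)
      ssr_gp <- blocksum((La - mu_p)^2, ends_g)
      lr <- (ssr_g - ssr_gp) / (2 * sig2) +
        .lp_gamma_log(pKg, shape_k, rate_k) - .lp_gamma_log(lgK, shape_k, rate_k) +
        ((t0 - t0_prior_m)^2 - (propT - t0_prior_m)^2) / (2 * t0_prior_s^2)
      ok <- feasible & (log(runif(ng)) < lr)
      if (any(ok)) {
        okf <- ok[gf]
        thK[okf] <- propK[okf]; Kf[okf] <- Kp[okf]
        lgK[ok] <- pKg[ok]; t0[ok] <- propT[ok]
        keep_obs <- ok[gidx]
        mu[keep_obs] <- mu_p[keep_obs]
        ssrf <- ssr_fish(mu)
      }
      acc["t0k"] <- acc["t0k"] + mean(ok)
      n_try["t0k"] <- n_try["t0k"] + 1

      # --- group-level updates (two sweeps: cheap, improves mixing)
      sumL <- blocksum(thL, ends_fg)
      sumK <- blocksum(thK, ends_fg)
      for (sweep in 1:2) {
        prop <- lgL + rnorm(ng, 0, scales["lgL"])
        lr <- (-(nf_g * prop^2 - 2 * prop * sumL) +
                 (nf_g * lgL^2 - 2 * lgL * sumL)) / (2 * exp(2 * lsdL)) +
          .lp_gamma_log(prop, shape_L, rate_L) -
          .lp_gamma_log(lgL, shape_L, rate_L)
        ok <- log(runif(ng)) < lr
        lgL[ok] <- prop[ok]
        acc["lgL"] <- acc["lgL"] + mean(ok); n_try["lgL"] <- n_try["lgL"] + 1

        prop <- lgK + rnorm(ng, 0, scales["lgK"])
        lr <- (-(nf_g * prop^2 - 2 * prop * sumK) +
                 (nf_g * lgK^2 - 2 * lgK * sumK)) / (2 * exp(2 * lsdK)) +
          .lp_gamma_log(prop, shape_k, rate_k) -
          .lp_gamma_log(lgK, shape_k, rate_k)
        ok <- log(runif(ng)) < lr
        lgK[ok] <- prop[ok]
        acc["lgK"] <- acc["lgK"] + mean(ok); n_try["lgK"] <- n_try["lgK"] + 1

        # group-level ridge move mirroring the individual one
        e <- rnorm(ng, 0, scales["gridge"])
        pL <- lgL + e; pK <- lgK - e
        lr <- (-(nf_g * pL^2 - 2 * pL * sumL) +
                 (nf_g * lgL^2 - 2 * lgL * sumL)) / (2 * exp(2 * lsdL)) +
          (-(nf_g * pK^2 - 2 * pK * sumK) +
             (nf_g * lgK^2 - 2 * lgK * sumK)) / (2 * exp(2 * lsdK)) +
          .lp_gamma_log(pL, shape_L, rate_L) - .lp_gamma_log(lgL, shape_L, rate_L) +
          .lp_gamma_log(pK, shape_k, rate_k) - .lp_gamma_log(lgK, shape_k, rate_k)
        ok <- log(runif(ng)) < lr
        lgL[ok] <- pL[ok]; lgK[ok] <- pK[ok]
        acc["gridge"] <- acc["gridge"] + mean(ok); n_try["gridge"] <- n_try["gridge"] + 1
      }

      # --- t0 re-enters the observation likelihood; a univariate slice
      # sampler (step-out + shrink) sidesteps the t0/k ridge that slows
      # random-walk moves
      for (g in seq_len(ng)) {
        io <- obs_of_group[[g]]
        eL <- Lf[fidx[io]]; eK <- Kf[fidx[io]]
        La_g <- La[io]; ta_g <- ta[io]
        lp <- function(v) {
          -sum((La_g - eL * (1 - exp(-eK * (ta_g - v))))^2) / (2 * sig2) -
            (v - t0_prior_m)^2 / (2 * t0_prior_s^2)
        }
        t0[g] <- .slice1(t0[g], lp, w = scales["t0"])
      }
      mu <- mu_of(Lf, Kf, t0)
      ssrf <- ssr_fish(mu)

      # --- hyper-SDs (Gaussian kernels written out; constants cancel)
      ssqL <- sum((thL - lgL[gf])^2)
      prop <- lsdL + rnorm(1, 0, scales["lsdL"])
      lr <- (-nf * prop - ssqL / (2 * exp(2 * prop))) -
        (-nf * lsdL - ssqL / (2 * exp(2 * lsdL))) +
        .lp_halfnorm_logsd(prop, priors$hyper_scale) -
        .lp_halfnorm_logsd(lsdL, priors$hyper_scale)
      if (log(runif(1)) < lr) { lsdL <- prop; acc["lsdL"] <- acc["lsdL"] + 1 }
      n_try["lsdL"] <- n_try["lsdL"] + 1

      ssqK <- sum((thK - lgK[gf])^2)
      prop <- lsdK + rnorm(1, 0, scales["lsdK"])
      lr <- (-nf * prop - ssqK / (2 * exp(2 * prop))) -
        (-nf * lsdK - ssqK / (2 * exp(2 * lsdK))) +
        .lp_halfnorm_logsd(prop, priors$hyper_scale) -
        .lp_halfnorm_logsd(lsdK, priors$hyper_scale)
      if (log(runif(1)) < lr) { lsdK <- prop; acc["lsdK"] <- acc["lsdK"] + 1 }
      n_try["lsdK"] <- n_try["lsdK"] + 1

      # --- observation variance: conjugate inverse-gamma
      sig2 <- 1 / rgamma(1, priors$sig2_a + n_obs / 2,
                         priors$sig2_b + sum(ssrf) / 2)

      # --- proposal adaptation during burn-in only (t0 is slice-sampled,
      # its width needs no tuning)
      if (it <= mcmc$burn_in && it %% 25 == 0) {
        rate <- acc / pmax(n_try, 1)
        adj <- names(scales) != "t0"
        scales[adj] <- scales[adj] * exp(0.5 * (rate[adj] - 0.35))
        acc[] <- 0; n_try[] <- 0
      }
      if (it == mcmc$burn_in) { acc[] <- 0; n_try[] <- 0 }

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- c(exp(lgL), exp(lgK), t0, exp(lsdL), exp(lsdK),
                           sqrt(sig2), Lf, Kf)
      }
    }
    rate <- (acc / pmax(n_try, 1))[names(scales) != "t0"]
    list(draws = draws, acceptance = rate)
  }

  chains <- lapply(seq_len(mcmc$chains), run_chain)
  draw_list <- lapply(chains, `[[`, "draws")
  accept <- Reduce(`+`, lapply(chains, `[[`, "acceptance")) / mcmc$chains
  if (any(accept < 0.01)) {
    warning("near-zero acceptance in blocks: ",
            paste(names(accept)[accept < 0.01], collapse = ", "),
            " (rates: ", paste(round(accept[accept < 0.01], 4), collapse = ", "), ")")
  }
  rh <- es <- setNames(rep(NA_real_, length(pnames)), pnames)
  if (mcmc$chains >= 2 && n_keep >= 4) {
    for (j in seq_along(pnames)) {
      m <- vapply(draw_list, function(d) d[, j], numeric(n_keep))
      rh[j] <- tryCatch(rhat(m), error = function(e) NA_real_)
      es[j] <- tryCatch(ess_bulk(m), error = function(e) NA_real_)
    }
  }
  # posterior-median residual spread per age (model-adequacy report)
  med <- apply(do.call(rbind, draw_list), 2, median)
  Linf_i <- med[paste0("Linf_i[", levels(fish), "]")]
  k_i <- med[paste0("k_i[", levels(fish), "]")]
  t0_g <- med[paste0("t0_g[", levels(grp_of_fish), "]")]
  fitted <- Linf_i[fidx] * (1 - exp(-k_i[fidx] * (ta - t0_g[gidx])))
  res_by_age <- tapply(La - fitted, ta, sd)

  structure(list(draws = draw_list, params = pnames, rhat = rh, ess = es,
                 acceptance = accept, residuals_by_age = res_by_age,
                 groups = levels(grp_of_fish), fish = levels(fish),
                 mcmc = mcmc, priors = priors, seed = seed),
            class = "growth_posterior")
}

#' Posterior summary of a fitted growth model
#'
#' @param fit [fit_hierarchical_vbgf()] output.
#' @param prob central credible-interval mass.
#' @return data.frame: `parameter`, `median`, `ci_low`, `ci_high`, `rhat`,
#'   `ess`.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "growth_posterior"))
  all_d <- do.call(rbind, fit$draws)
  a <- (1 - prob) / 2
  data.frame(parameter = fit$params,
             median = apply(all_d, 2, median),
             ci_low = apply(all_d, 2, quantile, a),
             ci_high = apply(all_d, 2, quantile, 1 - a),
             rhat = unname(fit$rhat), ess = unname(fit$ess),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-normalized split potential scale reduction factor
#'
#' Chains are split in half, all draws are rank-normalized jointly, and the
#' classic between/within-chain variance ratio is computed on the normal
#' scores -- the convergence diagnostic reported for every monitored
#' parameter.
#'
#' @param x matrix of draws (iterations x chains) or list of equal-length
#'   numeric vectors.
#' @return scalar R-hat (>= ~1).
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 4) stop("need >= 2 chains of >= 4 draws")
  if (var(as.numeric(x)) == 0) stop("degenerate chains: zero total variance")
  n_half <- nrow(x) %/% 2
  split <- cbind(x[seq_len(n_half), , drop = FALSE],
                 x[nrow(x) - n_half + seq_len(n_half), , drop = FALSE])
  r <- matrix(rank(split, ties.method = "average"), nrow = n_half)
  z <- qnorm((r - 3 / 8) / (length(split) + 1 / 4))
  m <- ncol(z); n <- nrow(z)
  W <- mean(apply(z, 2, var))
  B <- n * var(colMeans(z))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Rank-normalized draws, per-chain autocovariances combined across chains,
#' with Geyer's initial-monotone-positive-sequence truncation.
#'
#' @param x matrix of draws (iterations x chains) or list of vectors.
#' @return scalar effective sample size.
#' @export
ess_bulk <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) stop("need >= 4 draws")
  if (var(as.numeric(x)) == 0) stop("degenerate chains: zero total variance")
  r <- matrix(rank(x, ties.method = "average"), nrow = n)
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  W <- mean(apply(z, 2, var))
  var_plus <- (n - 1) / n * W + (if (m > 1) n * var(colMeans(z)) / n else 0)
  max_lag <- min(n - 2, 1000)
  acov <- vapply(seq_len(m), function(c) .autocov_fft(z[, c], max_lag),
                 numeric(max_lag + 1))
  mean_acov <- rowMeans(as.matrix(acov))
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0; prev <- Inf; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2
  }
  tau <- max(tau * 2 - 1, 1 / log10(n * m))  # 2*sum(pairs) - rho0
  min(n * m / tau, n * m)
}
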