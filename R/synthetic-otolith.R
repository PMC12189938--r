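#' Simulate an otolith element-ratio profile with known seasonal minima
#'
#' Generates Mg/Ca and P/Ca series along the dorsal otolith radius from core
#' to edge. Otolith growth follows a von Bertalanffy radius-at-age curve, and
#' each element carries an annual sinusoid whose troughs mark the coldest
#' part of the year (late winter): a fish that has lived through `age`
#' winters has exactly `age` seasonal minima in the noise-free signal of each
#' element. White noise of standard deviation `noise_sd` (in ratio units) is
#' added on top.
#'
#' Time conventions: hatch in spring at t = 0; winter troughs at
#' t = m - 1/12 years (m = 1, 2, ...); catch time is
#' `age + 1/12 + 0.2 * (catch_quarter - 1)` years, so first-quarter catches
#' sit just past the last winter minimum -- the situation in which minima
#' counting is hardest near the otolith edge.
#'
#' @param age completed years of life (number of winters), >= 0.
#' @param edge_radius total otolith radius at catch, micrometres.
#' @param step sampling step of the laser transect, micrometres.
#' @param noise_sd additive white-noise SD in element-ratio units.
#' @param seed integer seed.
#' @param catch_quarter calendar quarter of catch, 1-4.
#' @param k_oto shape of the radius-at-age curve (1/year).
#' @param mg_base,mg_amp,p_base,p_amp offset and seasonal amplitude of the
#'   Mg/Ca and P/Ca signals (ratio units).
#' @param fish_id identifier stored on the profile.
#' @return list of class `otolith_profile` with fields `fish_id`,
#'   `distances`, `mg_ca`, `p_ca`, `edge_radius`, `catch_quarter`, and a
#'   `truth` element holding the true age and the radii/times of the annual
#'   minima.
#' @export
simulate_otolith_profile <- function(age, edge_radius = 1000, step = 5,
                                     noise_sd = 0, seed = 1L,
                                     catch_quarter = 2L, k_oto = 0.25,
                                     mg_base = 1, mg_amp = 0.4,
                                     p_base = 2, p_amp = 0.8,
                                     fish_id = "fish1") {
  stopifnot(age >= 0, step > 0, edge_radius > 0, noise_sd >= 0,
            catch_quarter %in% 1:4)
  if (age * step >= edge_radius) {
    stop("edge_radius too small for ", age, " annuli at step ", step)
  }
  set.seed(seed)
  t_catch <- age + 1 / 12 + 0.2 * (catch_quarter - 1)
  dist <- seq(step, edge_radius, by = step)
  # radius-at-age: r(t) = edge_radius * (1 - exp(-k t)) / (1 - exp(-k T))
  scale <- 1 - exp(-k_oto * t_catch)
  t_at <- -log(1 - dist / edge_radius * scale) / k_oto
  season <- cos(2 * pi * (t_at - 5 / 12))  # trough at t = m - 1/12
  mg <- mg_base + mg_amp * season + rnorm(length(dist), 0, noise_sd)
  p <- p_base + p_amp * season + rnorm(length(dist), 0, noise_sd)
  t_min <- if (age >= 1) seq_len(age) - 1 / 12 else numeric(0)
  r_min <- edge_radius * (1 - exp(-k_oto * t_min)) / scale
  structure(list(fish_id = fish_id, distances = dist, mg_ca = mg, p_ca = p,
                 edge_radius = edge_radius, catch_quarter = catch_quarter,
                 truth = list(age = age, minima_radii = r_min,
                              minima_times = t_min, t_catch = t_catch,
                              k_oto = k_oto)),
            class = "otolith_profile")
}

#' Simulate a hierarchical growth cohort with known VBGF parameters
#'
#' Draws fish nested in groups (catch years). Individual log asymptotic
#' radius and log growth coefficient are Normal around the log of the group
#' values with standard deviation `indiv_sd` (so `indiv_sd` acts as a
#' coefficient of variation); t0 is shared within a group. Each fish
#' contributes annulus radii at ages 1..age following its own von Bertalanffy
#' curve plus Gaussian observation noise.
#'
#' @param group_params data.frame (or list coercible to one) with columns
#'   `Linf`, `k`, `t0`, one row per group; an optional `group_id` column
#'   names the groups.
#' @param n_per_group fish per group (recycled).
#' @param indiv_sd between-individual SD on the log scale (fractional).
#' @param obs_sd additive observation noise SD on radii.
#' @param age_range integer range of fish ages, drawn uniformly.
#' @param seed integer seed.
#' @return list of class `growth_cohort`: `observations` data.frame
#'   (fish_id, group_id, ta, La) and `truth` (per-fish and per-group
#'   parameters, true radii).
#' @export
simulate_growth_cohort <- function(group_params, n_per_group = 20,
                                   indiv_sd = 0.1, obs_sd = 0,
                                   age_range = c(3L, 7L), seed = 1L) {
  gp <- as.data.frame(group_params)
  stopifnot(all(c("Linf", "k", "t0") %in% names(gp)),
            all(gp$Linf > 0), all(gp$k > 0))
  if (indiv_sd < 0 || obs_sd < 0) stop("indiv_sd and obs_sd must be >= 0")
  n_per_group <- rep_len(n_per_group, nrow(gp))
  stopifnot(all(n_per_group >= 1))
  if (is.null(gp$group_id)) gp$group_id <- paste0("g", seq_len(nrow(gp)))
  set.seed(seed)
  obs <- list()
  fish <- list()
  fid <- 0L
  for (g in seq_len(nrow(gp))) {
    for (i in seq_len(n_per_group[g])) {
      fid <- fid + 1L
      id <- sprintf("%s_f%03d", gp$group_id[g], i)
      Linf_i <- gp$Linf[g] * exp(rnorm(1, 0, indiv_sd))
      k_i <- gp$k[g] * exp(rnorm(1, 0, indiv_sd))
      age <- if (age_range[1] == age_range[2]) age_range[1] else
        sample(seq(age_range[1], age_range[2]), 1)
      ta <- seq_len(age)
      La_true <- vbgf_length(ta, Linf_i, k_i, gp$t0[g])
      La <- La_true + rnorm(age, 0, obs_sd)
      obs[[fid]] <- data.frame(fish_id = id, group_id = gp$group_id[g],
                               ta = ta, La = La, stringsAsFactors = FALSE)
      fish[[fid]] <- data.frame(fish_id = id, group_id = gp$group_id[g],
                                Linf = Linf_i, k = k_i, t0 = gp$t0[g],
                                age = age, stringsAsFactors = FALSE)
    }
  }
  structure(list(observations = do.call(rbind, obs),
                 truth = list(fish = do.call(rbind, fish), groups = gp),
                 indiv_sd = indiv_sd, obs_sd = obs_sd, seed = seed),
            class = "growth_cohort")
}
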