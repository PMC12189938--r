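#' von Bertalanffy growth function
#'
#' L(t) = Linf * (1 - exp(-k * (t - t0))). Negative values are returned as
#' computed for t < t0; interpretation is the caller's.
#'
#' @param t age in years (vectorised).
#' @param Linf asymptotic length (otolith or body scale).
#' @param k Brody growth coefficient (1/year).
#' @param t0 hypothetical age at length zero (years).
#' @return length at age t.
#' @export
vbgf_length <- function(t, Linf, k, t0 = 0) {
  Linf * (1 - exp(-k * (t - t0)))
}

#' Growth performance index
#'
#' Phi = log10(k) + 2 * log10(Linf), the scalar summary of growth capacity
#' used as the association phenotype. Base 10 by convention of the growth-
#' performance literature.
#'
#' @param Linf asymptotic length, > 0.
#' @param k growth coefficient, > 0.
#' @param base logarithm base.
#' @return Phi (vectorised).
#' @export
growth_performance_index <- function(Linf, k, base = 10) {
  if (any(Linf <= 0) || any(k <= 0)) stop("Linf and k must be positive")
  log(k, base) + 2 * log(Linf, base)
}

#' Biological-intercept back-calculation of body length
#'
#' La = Lc + (Oa - Oc) * (Lc - L0) / (Oc - O0): body length at the age of an
#' annulus from the otolith radius at that annulus, anchored at the
#' length/otolith-radius pair at age 0. Defaults are the biological
#' intercepts for Baltic cod: L0 = 4.3 (body length units) and O0 = 0.01
#' (otolith units).
#'
#' @param Lc body length at capture.
#' @param Oc otolith radius at capture.
#' @param Oa otolith radius at the annulus, 0 < Oa <= Oc.
#' @param L0,O0 body length and otolith radius at age 0.
#' @return back-calculated body length at the annulus age.
#' @export
back_calculate_length <- function(Lc, Oc, Oa, L0 = 4.3, O0 = 0.01) {
  if (any(Oc <= O0)) stop("Oc must exceed O0")
  if (any(Oa <= 0) || any(Oa > Oc)) stop("need 0 < Oa <= Oc")
  Lc + (Oa - Oc) * (Lc - L0) / (Oc - O0)
}

#' Relative condition factor
#'
#' Fits the length-weight allometry log10(W) = log10(a) + b * log10(L) by
#' least squares on the pooled sample and returns Le Cren's relative
#' condition Kn_i = W_i / (a * L_i^b), which averages ~1 in the fitting
#' sample and is robust to the allometric exponent differing from 3.
#'
#' @param lengths,weights positive vectors, same length, n >= 3.
#' @return list of class `condition_result`: `Kn`, `a`, `b`.
#' @export
relative_condition <- function(lengths, weights) {
  stopifnot(length(lengths) == length(weights))
  if (length(lengths) < 3) stop("need at least 3 fish")
  if (any(lengths <= 0) || any(weights <= 0)) stop("lengths and weights must be positive")
  if (var(log10(lengths)) == 0) stop("zero length variance; allometry undefined")
  fit <- lm(log10(weights) ~ log10(lengths))
  a <- 10^coef(fit)[[1]]
  b <- coef(fit)[[2]]
  structure(list(Kn = weights / (a * lengths^b), a = a, b = b),
            class = "condition_result")
}

#' Bartlett's test of variance homogeneity across groups
#'
#' Used on first-annulus radii per catch year to ask whether juvenile growth
#' variability changed through time. Thin wrapper around
#' [stats::bartlett.test()] with explicit degenerate-input handling.
#'
#' @param values numeric vector.
#' @param groups grouping factor, >= 2 groups with >= 2 observations each.
#' @return list with `statistic` (Bartlett chi-square), `df`, `p_value`.
#' @export
variance_homogeneity_test <- function(values, groups) {
  groups <- as.factor(groups)
  n <- table(groups)
  if (nlevels(groups) < 2 || any(n < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  v <- tapply(values, groups, var)
  if (any(v == 0)) stop("zero variance within a group; Bartlett statistic undefined")
  bt <- bartlett.test(values, groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = bt$p.value)
}
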