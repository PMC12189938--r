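#' Smooth an element profile with local polynomial regression
#'
#' Degree-2 loess fit evaluated at the input distances, the standard
#' pre-processing step before seasonal minima are counted.
#'
#' @param distances strictly increasing positions (micrometres).
#' @param values element-ratio series, same length.
#' @param span loess span as a fraction of points, in (0, 1].
#' @return numeric vector of fitted values, same length as the input.
#' @export
smooth_profile <- function(distances, values, span = 0.1) {
  stopifnot(length(distances) == length(values))
  if (length(values) < 10) stop("need at least 10 points to smooth")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(values) < 4) {
    stop("span covers fewer points than a local quadratic supports")
  }
  fit <- loess(values ~ distances, span = span, degree = 2,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  as.numeric(predict(fit, data.frame(distances = distances)))
}

#' Detect local minima in a smoothed series
#'
#' Interior local minima are screened by topographic prominence (depth below
#' the lower of the two enclosing barriers) and then thinned greedily,
#' keeping the deepest minimum whenever two candidates lie closer than
#' `min_separation`. Endpoints are never minima.
#'
#' @param distances positions of the series (micrometres).
#' @param values smoothed series.
#' @param min_separation minimum distance between reported minima.
#' @param min_prominence minimum prominence in series units.
#' @return sorted numeric vector of minima positions (possibly empty).
#' @export
detect_minima <- function(distances, values, min_separation = 0,
                          min_prominence = 0) {
  stopifnot(length(distances) == length(values), min_separation >= 0)
  n <- length(values)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  cand <- i[values[i] < values[i - 1] & values[i] <= values[i + 1]]
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(j) {
    v <- values[j]
    left <- if (j > 1) values[seq_len(j - 1)] else numeric(0)
    below_l <- which(left < v)
    lbar <- if (length(below_l)) max(left[(max(below_l) + 1):(j - 1)]) else max(left)
    right <- if (j < n) values[(j + 1):n] else numeric(0)
    below_r <- which(right < v)
    rbar <- if (length(below_r)) max(right[seq_len(min(below_r) - 1)]) else max(right)
    min(lbar, rbar) - v
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))
  # greedy thinning, deepest first
  ord <- cand[order(values[cand])]
  accepted <- numeric(0)
  for (j in ord) {
    if (!length(accepted) ||
        all(abs(distances[j] - distances[accepted]) >= min_separation)) {
      accepted <- c(accepted, j)
    }
  }
  sort(distances[accepted])
}

#' Parameters for chemical age estimation
#'
#' @param span loess span passed to [smooth_profile()].
#' @param min_prominence_frac minimum prominence as a fraction of the
#'   interquartile range of the smoothed series.
#' @param min_separation minimum distance between annual minima; if `NULL`
#'   it defaults to half the median inter-annulus spacing implied by the
#'   edge radius and `prior_max_age`.
#' @param prior_max_age prior upper bound on age used for the default
#'   separation.
#' @param edge_margin fraction of the edge radius beyond which a terminal
#'   minimum may be dropped under the first-quarter rule.
#' @return list of class `age_params`.
#' @export
age_params <- function(span = 0.1, min_prominence_frac = 0.05,
                       min_separation = NULL, prior_max_age = 10,
                       edge_margin = 0.95) {
  structure(list(span = span, min_prominence_frac = min_prominence_frac,
                 min_separation = min_separation,
                 prior_max_age = prior_max_age, edge_margin = edge_margin),
            class = "age_params")
}

#' Estimate fish age from otolith Mg/Ca and P/Ca profiles
#'
#' Each element series is smoothed and its seasonal minima counted; the
#' counts are the candidate ages. If the two elements agree, that is the age
#' (`flag = "agreed"`). If they differ by one and the fish was caught in the
#' first quarter of the year, the extra terminal minimum of the longer list
#' is dropped when it lies beyond `edge_margin` of the edge radius
#' (`flag = "resolved"`): early-year catches sit just past the winter trough,
#' so one element often picks up a minimum right at the otolith edge. Any
#' other disagreement is flagged `needs_review` and the age left NA rather
#' than guessed. Consensus annulus radii are taken from the P/Ca series
#' (configurable by convention, not biology).
#'
#' @param profile [simulate_otolith_profile()] output or any list with
#'   `distances`, `mg_ca`, `p_ca`, `edge_radius`, `catch_quarter`.
#' @param params [age_params()].
#' @param consensus_element `"p"` or `"mg"`.
#' @return list of class `age_result`: `age`, `minima_radii` (consensus),
#'   `consensus_flag`, `element_counts`, `minima_by_element`.
#' @export
estimate_age <- function(profile, params = age_params(),
                         consensus_element = c("p", "mg")) {
  consensus_element <- match.arg(consensus_element)
  need <- c("distances", "mg_ca", "p_ca", "edge_radius", "catch_quarter")
  miss <- need[!vapply(need, function(f) !is.null(profile[[f]]), logical(1))]
  if (length(miss)) stop("profile missing: ", paste(miss, collapse = ", "))
  sep <- params$min_separation
  if (is.null(sep)) sep <- 0.5 * profile$edge_radius / params$prior_max_age
  one <- function(y) {
    s <- smooth_profile(profile$distances, y, span = params$span)
    detect_minima(profile$distances, s, min_separation = sep,
                  min_prominence = params$min_prominence_frac *
                    stats::IQR(s))
  }
  minima <- list(mg = one(profile$mg_ca), p = one(profile$p_ca))
  counts <- vapply(minima, length, integer(1))
  drop_edge <- function(m) {
    if (length(m) && m[length(m)] >= params$edge_margin * profile$edge_radius)
      m[-length(m)] else m
  }
  flag <- NULL
  if (counts["mg"] == counts["p"]) {
    flag <- "agreed"
  } else if (abs(counts["mg"] - counts["p"]) == 1 && profile$catch_quarter == 1) {
    longer <- names(which.max(counts))
    trimmed <- drop_edge(minima[[longer]])
    if (length(trimmed) == min(counts)) {
      minima[[longer]] <- trimmed
      flag <- "resolved"
    }
  }
  if (is.null(flag)) {
    return(structure(list(age = NA_integer_, minima_radii = NULL,
                          consensus_flag = "needs_review",
                          element_counts = counts, minima_by_element = minima),
                     class = "age_result"))
  }
  cons <- minima[[consensus_element]]
  structure(list(age = length(cons), minima_radii = cons,
                 consensus_flag = flag, element_counts = counts,
                 minima_by_element = minima),
            class = "age_result")
}

#' Extract annulus radii from an age result
#'
#' Returns the consensus minima radii (one per completed year) with the edge
#' radius appended as the radius at catch.
#'
#' @param age_result [estimate_age()] output with a consensus.
#' @param edge_radius total otolith radius at catch.
#' @return list with `annulus_radii` (length = age) and `radius_at_catch`.
#' @export
extract_annulus_radii <- function(age_result, edge_radius) {
  if (is.na(age_result$age)) stop("no consensus age; profile needs review")
  r <- age_result$minima_radii
  if (length(r) && (is.unsorted(r, strictly = TRUE) || r[length(r)] > edge_radius)) {
    stop("non-monotone annulus radii; check detector configuration")
  }
  list(annulus_radii = r, radius_at_catch = edge_radius)
}
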