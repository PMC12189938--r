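#' Mann-Kendall test for monotonic trend
#'
#' S = sum over i < j of sign(x_j - x_i). The null distribution (random
#' ordering of the observed values) is evaluated exactly for small series:
#' with distinct values the inversion-number convolution gives the full
#' enumeration distribution for n <= 10, and with ties the n! orderings are
#' enumerated directly for n <= 8 (conditioning on the observed tie
#' pattern). Larger series use the normal approximation with the
#' tie-corrected variance and a continuity correction.
#'
#' @param x numeric series in time order, n >= 3.
#' @return list of class `trend_test`: `S`, `n`, `p_one_sided` (in the
#'   direction of the observed S), `p_two_sided`, `direction`
#'   (increasing/decreasing/none), `method` (exact/normal).
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  S <- .mk_s(x)
  ties <- anyDuplicated(x) > 0
  direction <- if (S > 0) "increasing" else if (S < 0) "decreasing" else "none"
  if (all(x == x[1])) {
    return(structure(list(S = 0L, n = n, p_one_sided = 1, p_two_sided = 1,
                          direction = "none", method = "degenerate"),
                     class = "trend_test"))
  }
  if (!ties && n <= 10) {
    tab <- .mk_exact_distinct(n)         # P(S = s) over s
    p1 <- .mk_tail(tab, S)
    method <- "exact"
  } else if (ties && n <= 8) {
    tab <- .mk_exact_ties(x)
    p1 <- .mk_tail(tab, S)
    method <- "exact"
  } else {
    tt <- table(x)
    varS <- (n * (n - 1) * (2 * n + 5) -
               sum(tt * (tt - 1) * (2 * tt + 5))) / 18
    z <- (S - sign(S)) / sqrt(varS)      # continuity correction
    p1 <- pnorm(-abs(z))
    if (S == 0) p1 <- 0.5
    method <- "normal"
  }
  structure(list(S = S, n = n, p_one_sided = p1,
                 p_two_sided = min(1, 2 * p1),
                 direction = direction, method = method),
            class = "trend_test")
}

.mk_s <- function(x) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sum(sign(x[ij[, 2]] - x[ij[, 1]]))
}

# exact distribution of S for n distinct values: S = n(n-1)/2 - 2 * inversions,
# inversions distributed as the convolution of Uniform{0..i-1}, i = 1..n
.mk_exact_distinct <- function(n) {
  counts <- 1
  for (i in 2:n) counts <- convolve_uniform(counts, i)
  inv <- seq_along(counts) - 1
  s <- n * (n - 1) / 2 - 2 * inv
  prob <- counts / sum(counts)
  tapply(prob, s, sum)
}

convolve_uniform <- function(counts, i) {
  out <- numeric(length(counts) + i - 1)
  for (shift in 0:(i - 1)) {
    out[seq_along(counts) + shift] <- out[seq_along(counts) + shift] + counts
  }
  out
}

# exact distribution of S under random orderings of a (possibly tied)
# multiset, by full enumeration
.mk_exact_ties <- function(x) {
  perms <- .permutations(length(x))
  s_vals <- apply(perms, 1, function(p) .mk_s(x[p]))
  tab <- table(s_vals) / nrow(perms)
  setNames(as.numeric(tab), names(tab))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    remap <- seq_len(n)[-i]
    out[rows, -1] <- matrix(remap[sub], nrow(sub))
  }
  out
}

# one-sided tail probability in the direction of the observed S
.mk_tail <- function(tab, S) {
  s <- as.numeric(names(tab))
  if (S > 0) sum(tab[s >= S]) else if (S < 0) sum(tab[s <= S]) else
    min(1, sum(tab[s >= 0]))
}
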