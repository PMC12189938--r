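#' Per-time-point allele frequencies
#'
#' Alternate-allele frequency and non-missing diploid count per time point
#' and locus: p = sum(dosage) / (2 * n_nonmissing). Loci with no genotyped
#' sample in a time group get NA there.
#'
#' @param gt genotype_table whose samples carry `time_index` (or supply
#'   `time` explicitly).
#' @param time optional vector of time labels per sample, overriding
#'   `gt$samples$time_index`.
#' @return object of class `freq_matrix`: `p` and `n` (time points x loci)
#'   and `times` (sorted unique labels).
#' @export
allele_frequencies <- function(gt, time = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(time)) time <- gt$samples$time_index
  if (is.null(time)) stop("no time grouping available")
  if (anyNA(time)) stop("time labels contain NA")
  tl <- sort(unique(time))
  d <- gt$dosage
  p <- n <- matrix(NA_real_, length(tl), ncol(d),
                   dimnames = list(tl, colnames(d)))
  for (i in seq_along(tl)) {
    rows <- which(time == tl[i])
    if (!length(rows)) stop("empty time group: ", tl[i])
    sub <- d[rows, , drop = FALSE]
    nn <- colSums(!is.na(sub))
    p[i, ] <- ifelse(nn > 0, colSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
    n[i, ] <- nn
  }
  structure(list(p = p, n = n, times = tl), class = "freq_matrix")
}

.delta <- function(freqs, from, to) freqs$p[to, ] - freqs$p[from, ]

#' Temporal covariance of allele-frequency change across loci
#'
#' Sample covariance (denominator n - 1), across loci, of the frequency
#' change over interval A = (t_i -> t_j) with the change over interval
#' B = (t_k -> t_m). Loci with any missing frequency among the four time
#' points are dropped pairwise.
#'
#' @param freqs [allele_frequencies()] output.
#' @param a,b integer pairs: row indices (into `freqs$times`) of the interval
#'   endpoints, e.g. `c(1, 3)`.
#' @return scalar covariance.
#' @export
temporal_cov <- function(freqs, a, b) {
  stopifnot(inherits(freqs, "freq_matrix"), length(a) == 2, length(b) == 2)
  nt <- nrow(freqs$p)
  if (any(c(a, b) < 1) || any(c(a, b) > nt)) stop("interval index out of range")
  dA <- .delta(freqs, a[1], a[2])
  dB <- .delta(freqs, b[1], b[2])
  ok <- !is.na(dA) & !is.na(dB)
  if (sum(ok) < 2) stop("fewer than 2 loci with both intervals defined")
  cov(dA[ok], dB[ok])
}

#' Lagged temporal autocovariances
#'
#' For ordered time points T1..Tn and lag `lag` = l, returns
#' cov(Delta(T_i -> T_{i+l}), Delta(T_{i+1} -> T_{i+1+l})) for every valid i.
#' Paired intervals share no sampled endpoint, which is why l >= 2 is
#' enforced: consecutive-interval (lag-1) pairs share a sample whose noise
#' induces spurious covariance under pure drift.
#'
#' @param freqs [allele_frequencies()] output.
#' @param lag integer >= 2.
#' @return data.frame with one row per interval pair: `pair`, `lag`,
#'   `value`, `n_loci`.
#' @export
lag_autocovariances <- function(freqs, lag) {
  stopifnot(inherits(freqs, "freq_matrix"))
  if (lag < 2) stop("lag must be >= 2: lag-1 pairs share a sampled endpoint")
  nt <- nrow(freqs$p)
  if (nt < lag + 2) stop("need at least lag + 2 time points")
  tl <- freqs$times
  out <- lapply(seq_len(nt - lag - 1), function(i) {
    a <- c(i, i + lag); b <- c(i + 1, i + 1 + lag)
    dA <- .delta(freqs, a[1], a[2]); dB <- .delta(freqs, b[1], b[2])
    ok <- !is.na(dA) & !is.na(dB)
    data.frame(
      pair = sprintf("cov(\u0394%s\u2013%s, \u0394%s\u2013%s)",
                     tl[a[1]], tl[a[2]], tl[b[1]], tl[b[2]]),
      lag = lag, value = cov(dA[ok], dB[ok]), n_loci = sum(ok),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Block bootstrap confidence interval for a temporal covariance
#'
#' Loci are partitioned into contiguous blocks in genome order; blocks are
#' resampled with replacement B times and the covariance recomputed on each
#' resample; the percentile interval at level `alpha` is returned. Blocks of
#' adjacent loci preserve any local dependence the point estimate ignores.
#'
#' @param freqs [allele_frequencies()] output (loci in genome order).
#' @param a,b interval index pairs as in [temporal_cov()].
#' @param block_size loci per block (default 1000 adjacent loci).
#' @param B bootstrap replicates (>= 100).
#' @param alpha two-sided interval level (0.05 gives 95 percent CI).
#' @param seed integer seed.
#' @return list of class `cov_stat`: `pair`, `value`, `ci_low`, `ci_high`,
#'   `n_loci`, `B`, `block_size`.
#' @export
block_bootstrap_ci <- function(freqs, a, b, block_size = 1000, B = 5000,
                               alpha = 0.05, seed = 1L) {
  stopifnot(B >= 100, block_size >= 1)
  dA <- .delta(freqs, a[1], a[2])
  dB <- .delta(freqs, b[1], b[2])
  ok <- which(!is.na(dA) & !is.na(dB))
  dA <- dA[ok]; dB <- dB[ok]
  L <- length(dA)
  blk <- ceiling(seq_along(dA) / block_size)
  nb <- max(blk)
  if (L < 2) stop("fewer than 2 complete loci")
  value <- cov(dA, dB)
  if (nb < 2) {
    # a single block can only resample itself: degenerate interval
    return(structure(list(pair = sprintf("cov(\u0394%s\u2013%s, \u0394%s\u2013%s)",
                                         freqs$times[a[1]], freqs$times[a[2]],
                                         freqs$times[b[1]], freqs$times[b[2]]),
                          value = value, ci_low = value, ci_high = value,
                          n_loci = L, B = B, block_size = block_size),
                     class = "cov_stat"))
  }
  # per-block sufficient statistics; covariance of a resample from sums
  sA <- rowsum(dA, blk); sB <- rowsum(dB, blk)
  sAB <- rowsum(dA * dB, blk); cnt <- as.numeric(table(blk))
  set.seed(seed)
  boots <- vapply(seq_len(B), function(i) {
    pick <- sample.int(nb, nb, replace = TRUE)
    n <- sum(cnt[pick])
    mA <- sum(sA[pick]) / n; mB <- sum(sB[pick]) / n
    (sum(sAB[pick]) - n * mA * mB) / (n - 1)
  }, numeric(1))
  ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  structure(list(pair = sprintf("cov(\u0394%s\u2013%s, \u0394%s\u2013%s)",
                                freqs$times[a[1]], freqs$times[a[2]],
                                freqs$times[b[1]], freqs$times[b[2]]),
                 value = value, ci_low = ci[1], ci_high = ci[2],
                 n_loci = L, B = B, block_size = block_size),
            class = "cov_stat")
}

#' Subset permutation test for focal-locus temporal autocovariance
#'
#' The observed statistic is the mean lag-`lag` autocovariance computed on
#' the focal loci (e.g. association-scan outliers). The null is the same
#' statistic on B random subsets of equal size drawn without replacement
#' from all loci; the one-sided empirical p-value uses the
#' (1 + x) / (B + 1) estimator, so it is never zero.
#'
#' @param freqs [allele_frequencies()] output.
#' @param focal_loci integer indices or locus names (columns of `freqs$p`).
#' @param lag autocovariance lag, >= 2.
#' @param B permutations.
#' @param seed integer seed.
#' @return list of class `perm_result`: `observed`, `null_values`, `p_emp`,
#'   `B`, `seed`, `lag`, `n_focal`.
#' @export
subset_permutation_test <- function(freqs, focal_loci, lag = 2, B = 1000,
                                    seed = 1L) {
  stopifnot(inherits(freqs, "freq_matrix"))
  L <- ncol(freqs$p)
  if (is.character(focal_loci)) {
    idx <- match(focal_loci, colnames(freqs$p))
    if (anyNA(idx)) {
      stop("focal loci absent from table: ",
           paste(focal_loci[is.na(idx)], collapse = ", "))
    }
    focal_loci <- idx
  }
  focal_loci <- as.integer(focal_loci)
  if (any(focal_loci < 1 | focal_loci > L)) stop("focal locus index out of range")
  nf <- length(focal_loci)
  if (nf < 2) stop("need at least 2 focal loci")
  stat <- function(idx) {
    sub <- structure(list(p = freqs$p[, idx, drop = FALSE],
                          n = freqs$n[, idx, drop = FALSE],
                          times = freqs$times), class = "freq_matrix")
    mean(lag_autocovariances(sub, lag)$value)
  }
  observed <- stat(focal_loci)
  # null subsets are drawn against the sorted-locus-id order, so the
  # seed-to-subset mapping (and hence p_emp) is invariant to column order
  ord <- if (!is.null(colnames(freqs$p))) order(colnames(freqs$p)) else seq_len(L)
  set.seed(seed)
  null_values <- vapply(seq_len(B), function(i) stat(ord[sample.int(L, nf)]),
                        numeric(1))
  structure(list(observed = observed, null_values = null_values,
                 p_emp = (1 + sum(null_values >= observed)) / (B + 1),
                 B = B, seed = seed, lag = lag, n_focal = nf),
            class = "perm_result")
}
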