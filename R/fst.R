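#' Weir-Cockerham variance components at biallelic sites
#'
#' Two-level (populations, individuals, alleles-within-individuals)
#' variance-component estimator from genotype counts. Observed heterozygosity
#' enters the within-individual component c. Sites monomorphic across all
#' groups, or with a group entirely missing, are skipped: all components are
#' set to 0 and the site flagged.
#'
#' @param dosage matrix samples x sites (0/1/2/NA), or a vector for a single
#'   site.
#' @param groups group label per sample; >= 2 groups.
#' @return data.frame with one row per site: `a`, `b`, `c`, `skipped`.
#' @export
wc_fst_components <- function(dosage, groups) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1)
  groups <- as.factor(groups)
  r <- nlevels(groups)
  if (r < 2) stop("need >= 2 groups")
  L <- ncol(dosage)
  n_i <- p_i <- h_i <- matrix(0, r, L)
  for (g in seq_len(r)) {
    sub <- dosage[groups == levels(groups)[g], , drop = FALSE]
    nn <- colSums(!is.na(sub))
    n_i[g, ] <- nn
    p_i[g, ] <- ifelse(nn > 0, colSums(sub, na.rm = TRUE) / (2 * nn), 0)
    h_i[g, ] <- ifelse(nn > 0, colSums(sub == 1, na.rm = TRUE) / nn, 0)
  }
  skipped <- colSums(n_i == 0) > 0
  nbar <- colMeans(n_i)
  nsum <- colSums(n_i)
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum
  mono <- pbar == 0 | pbar == 1
  skipped <- skipped | mono
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[skipped] <- 0; b[skipped] <- 0; cc[skipped] <- 0
  data.frame(a = a, b = b, c = cc, skipped = skipped)
}

#' Weir-Cockerham Fst at a single site
#'
#' @param dosages dosage vector over samples at one site.
#' @param groups group label per sample.
#' @return list with components `a`, `b`, `c`, the ratio `fst` =
#'   a / (a + b + c) (NA when the denominator is 0), and `skipped`.
#' @export
wc_fst_site <- function(dosages, groups) {
  comp <- wc_fst_components(dosages, groups)
  den <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (den == 0) NA_real_ else comp$a / den,
       skipped = comp$skipped)
}

#' Windowed weighted Fst scan
#'
#' Weir-Cockerham components are summed over the sites of nonoverlapping
#' windows tiled from position 1 ([start, start + window) half-open) and the
#' weighted ("ratio of sums") estimator sum(a) / sum(a + b + c) is reported
#' per window. Windows without usable sites are reported with `fst = NA`.
#' Negative window values are reported as computed, not clamped.
#'
#' @param gt genotype_table.
#' @param groups group label per sample (e.g. catch year).
#' @param window_bp window size in bp (default 20 kb).
#' @return data.frame of class `window_stat`: `chrom`, `start`, `end`
#'   (1-based inclusive start, exclusive end), `n_sites`, `sum_a`, `sum_b`,
#'   `sum_c`, `fst`.
#' @export
fst_windows <- function(gt, groups, window_bp = 20000) {
  stopifnot(inherits(gt, "genotype_table"), window_bp > 0)
  comp <- wc_fst_components(gt$dosage, groups)
  out <- list()
  for (ch in unique(gt$loci$chrom)) {
    on_ch <- gt$loci$chrom == ch
    pos <- gt$loci$pos[on_ch]
    win <- (pos - 1) %/% window_bp
    full <- seq(0, max(win))
    agg <- function(x) {
      z <- rowsum(x, win)
      full_z <- setNames(rep(0, length(full)), full)
      full_z[rownames(z)] <- z
      full_z
    }
    use <- !comp$skipped[on_ch]
    A <- agg(comp$a[on_ch] * use); B <- agg(comp$b[on_ch] * use)
    C <- agg(comp$c[on_ch] * use); n <- agg(as.numeric(use))
    den <- A + B + C
    out[[ch]] <- data.frame(chrom = ch, start = full * window_bp + 1,
                            end = (full + 1) * window_bp + 1,
                            n_sites = as.integer(n),
                            sum_a = unname(A), sum_b = unname(B),
                            sum_c = unname(C),
                            fst = ifelse(den == 0, NA_real_, A / den),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stat", "data.frame")
  res
}
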