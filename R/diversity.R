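#' Per-site genotyped allele counts by group
#'
#' Helper that converts a genotype table into the per-site count format used
#' by [pi_windows()] and [dxy_windows()]: for every site and group, the
#' number of genotyped alleles `n` and the alternate-allele count `alt`.
#' Invariant sites (absent from a variants-only VCF) can be appended as rows
#' with `alt = 0` so that diversity denominators include them.
#'
#' @param gt genotype_table.
#' @param groups group label per sample.
#' @return data.frame: `chrom`, `pos`, `group`, `n`, `alt`.
#' @export
allele_counts <- function(gt, groups) {
  stopifnot(inherits(gt, "genotype_table"))
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    sub <- gt$dosage[groups == g, , drop = FALSE]
    data.frame(chrom = gt$loci$chrom, pos = gt$loci$pos, group = g,
               n = 2 * colSums(!is.na(sub)),
               alt = colSums(sub, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.tile_ratio_windows <- function(chrom, pos, num, den, window_bp) {
  out <- list()
  for (ch in unique(chrom)) {
    on_ch <- chrom == ch
    win <- (pos[on_ch] - 1) %/% window_bp
    full <- seq(0, max(win))
    agg <- function(x) {
      z <- rowsum(x, win)
      fz <- setNames(rep(0, length(full)), full)
      fz[rownames(z)] <- z
      fz
    }
    NUM <- agg(num[on_ch]); DEN <- agg(den[on_ch])
    n_sites <- agg(rep(1, sum(on_ch)))
    out[[ch]] <- data.frame(chrom = ch, start = full * window_bp + 1,
                            end = (full + 1) * window_bp + 1,
                            n_sites = as.integer(n_sites),
                            numerator = unname(NUM), denominator = unname(DEN),
                            value = ifelse(DEN == 0, NA_real_, NUM / DEN),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed nucleotide diversity (pi) with missing-data awareness
#'
#' Ratio-of-sums estimator: per window,
#' pi = sum over sites of pairwise allele differences / sum over sites of
#' pairwise comparisons among genotyped alleles. Sites with missing alleles
#' contribute fewer comparisons at that site only; invariant sites contribute
#' comparisons but no differences, so they must be present in `counts` for
#' per-bp diversity to be interpretable.
#'
#' @param counts data.frame as produced by [allele_counts()] (`chrom`, `pos`,
#'   `group`, `n`, `alt`), including invariant-site rows.
#' @param window_bp window size in bp (default 50 kb).
#' @return data.frame with one row per group x window: `group`, `chrom`,
#'   `start`, `end`, `n_sites`, `diffs`, `comparisons`, `pi`.
#' @export
pi_windows <- function(counts, window_bp = 50000) {
  stopifnot(all(c("chrom", "pos", "group", "n", "alt") %in% names(counts)))
  out <- lapply(unique(counts$group), function(g) {
    cg <- counts[counts$group == g, ]
    num <- cg$alt * (cg$n - cg$alt)          # pairwise differences
    den <- cg$n * (cg$n - 1) / 2             # pairwise comparisons
    w <- .tile_ratio_windows(cg$chrom, cg$pos, num, den, window_bp)
    data.frame(group = g, chrom = w$chrom, start = w$start, end = w$end,
               n_sites = w$n_sites, diffs = w$numerator,
               comparisons = w$denominator, pi = w$value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed absolute divergence (dxy) between two groups
#'
#' dxy = sum over sites of between-group allele pair differences /
#' sum over sites of between-group comparisons, with the same ratio-of-sums
#' and missing-data conventions as [pi_windows()].
#'
#' @param counts data.frame as for [pi_windows()].
#' @param group_pair character vector of the two group labels.
#' @param window_bp window size in bp (default 50 kb).
#' @return data.frame: `group_pair`, `chrom`, `start`, `end`, `n_sites`,
#'   `diffs`, `comparisons`, `dxy`.
#' @export
dxy_windows <- function(counts, group_pair, window_bp = 50000) {
  stopifnot(length(group_pair) == 2)
  c1 <- counts[counts$group == group_pair[1], ]
  c2 <- counts[counts$group == group_pair[2], ]
  key1 <- paste(c1$chrom, c1$pos); key2 <- paste(c2$chrom, c2$pos)
  shared <- intersect(key1, key2)
  c1 <- c1[match(shared, key1), ]
  c2 <- c2[match(shared, key2), ]
  num <- c1$alt * (c2$n - c2$alt) + (c1$n - c1$alt) * c2$alt
  den <- c1$n * c2$n
  w <- .tile_ratio_windows(c1$chrom, c1$pos, num, den, window_bp)
  data.frame(group_pair = paste(group_pair, collapse = ":"),
             chrom = w$chrom, start = w$start, end = w$end,
             n_sites = w$n_sites, diffs = w$numerator,
             comparisons = w$denominator, dxy = w$value,
             stringsAsFactors = FALSE)
}

#' Genome-wide pi or dxy from window tables
#'
#' The genome-wide value is the same ratio of sums taken over all windows,
#' not the mean of per-window ratios.
#'
#' @param windows output of [pi_windows()] or [dxy_windows()].
#' @return scalar (or named vector, one value per group / group pair).
#' @export
genomewide_diversity <- function(windows) {
  key <- if ("group" %in% names(windows)) windows$group else windows$group_pair
  vapply(split(windows, key),
         function(w) sum(w$diffs) / sum(w$comparisons), numeric(1))
}
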