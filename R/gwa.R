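#' Genomic kinship matrix from standardized dosages
#'
#' K = Z Z' / m, where Z is the mean-imputed, column-standardized (mean 0,
#' variance 1) dosage matrix over the m polymorphic loci passing the MAF
#' filter. Used as the random-effect covariance capturing population
#' structure in the association scan.
#'
#' @param gt genotype_table.
#' @param maf_min minimum minor allele frequency for loci entering K.
#' @return n x n symmetric matrix with attribute `n_loci`.
#' @export
kinship_matrix <- function(gt, maf_min = 0.01) {
  stopifnot(inherits(gt, "genotype_table"))
  X <- gt$dosage
  if (nrow(X) < 2) stop("need at least 2 samples")
  cm <- colMeans(X, na.rm = TRUE)
  na_at <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_at)) X[na_at] <- cm[na_at[, 2]]
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  v <- apply(X, 2, var)
  use <- maf >= maf_min & v > 0
  if (!any(use)) stop("no polymorphic loci pass the MAF filter")
  Z <- scale(X[, use, drop = FALSE])
  K <- tcrossprod(Z) / sum(use)
  dimnames(K) <- list(gt$samples$sample_id, gt$samples$sample_id)
  attr(K, "n_loci") <- sum(use)
  K
}

# profile (restricted to fixed lambda) Gaussian log-likelihood in the
# eigenrotated model y ~ N(Xb, sigma_e^2 (lambda K + I))
.lmm_loglik <- function(loglam, yt, Xt, d) {
  lam <- exp(loglam)
  w <- 1 / (lam * d + 1)
  sw <- sqrt(w)
  A <- Xt * sw
  b <- yt * sw
  qr_a <- qr(A)
  res <- qr.resid(qr_a, b)
  n <- length(yt)
  s2 <- sum(res^2) / n
  -0.5 * (n * log(2 * pi * s2) - sum(log(w)) + n)
}

#' Mixed-model association scan of a quantitative phenotype
#'
#' Per-SNP fit of y = mu + covariates + g * beta + u + e with
#' u ~ N(0, sigma_g^2 K) and e ~ N(0, sigma_e^2 I), via a single
#' eigendecomposition of K. By default the variance ratio
#' lambda = sigma_g^2 / sigma_e^2 is estimated once on the null
#' (covariates-only) model and held fixed across SNPs; per-SNP
#' re-estimation is available with `per_snp_ratio = TRUE`. Effects and
#' standard errors come from the rotated weighted regression and
#' significance is the Wald test p = 2 * Phi(-|beta / se|).
#'
#' SNPs failing the MAF or missingness filters are excluded; missing
#' genotypes at tested SNPs are mean-imputed.
#'
#' @param gt genotype_table.
#' @param phenotype numeric phenotype per sample (e.g. growth performance
#'   index Phi), aligned with `gt$samples`.
#' @param covariates optional data.frame/matrix of fixed covariates (e.g.
#'   sex); factors are model-matrixed.
#' @param K kinship matrix from [kinship_matrix()]; `NULL` or a zero matrix
#'   reduces the fit to ordinary least squares.
#' @param maf_min,max_missing SNP filters (defaults 0.05 and 0.1).
#' @param per_snp_ratio re-estimate the variance ratio for every SNP.
#' @return data.frame of class `assoc_scan`: `locus`, `chrom`, `pos`,
#'   `beta`, `se`, `wald_p`, `p_bh` (Benjamini-Hochberg adjusted), `maf`,
#'   `n_used`; attributes `lambda` and `n_tested`.
#' @export
lmm_assoc_scan <- function(gt, phenotype, covariates = NULL, K = NULL,
                           maf_min = 0.05, max_missing = 0.1,
                           per_snp_ratio = FALSE) {
  stopifnot(inherits(gt, "genotype_table"))
  y <- as.numeric(phenotype)
  n <- nrow(gt$dosage)
  if (length(y) != n) stop("phenotype length does not match samples")
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    X <- mm
  }
  if (qr(X)$rank < ncol(X)) stop("singular covariate design")
  G <- gt$dosage
  miss <- colMeans(is.na(G))
  cm <- colMeans(G, na.rm = TRUE)
  p <- cm / 2
  maf <- pmin(p, 1 - p)
  use <- which(maf >= maf_min & miss <= max_missing)
  if (!length(use)) stop("no SNPs pass the filters")
  G <- G[, use, drop = FALSE]
  na_at <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_at)) G[na_at] <- cm[use][na_at[, 2]]
  n_used <- colSums(!is.na(gt$dosage[, use, drop = FALSE]))

  if (is.null(K)) K <- matrix(0, n, n)
  ev <- eigen(K, symmetric = TRUE)
  d <- ev$values
  if (min(d) < -1e-8 * max(abs(d), 1)) {
    warning("kinship matrix not PSD within tolerance; clamping negative eigenvalues")
  }
  d <- pmax(d, 0)
  U <- ev$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  Gt <- crossprod(U, G)

  fit_at <- function(lam) {
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    A <- Xt * sw
    b <- yt * sw
    qr_a <- qr(A)
    b_perp <- qr.resid(qr_a, b)
    G_perp <- qr.resid(qr_a, Gt * sw)
    gg <- colSums(G_perp^2)
    beta <- colSums(G_perp * b_perp) / gg
    ssr <- sum(b_perp^2) - beta^2 * gg
    df <- n - ncol(X) - 1
    se <- sqrt(pmax(ssr, 0) / df / gg)
    list(beta = beta, se = se)
  }

  if (!per_snp_ratio) {
    if (all(d == 0)) {
      lam <- 0
    } else {
      opt <- optimize(.lmm_loglik, c(-12, 12), yt = yt, Xt = Xt, d = d,
                      maximum = TRUE)
      lam <- exp(opt$maximum)
      if (.lmm_loglik(-Inf, yt, Xt, d) >= opt$objective) lam <- 0
    }
    ft <- fit_at(lam)
    beta <- ft$beta; se <- ft$se
  } else {
    lam <- numeric(length(use))
    beta <- se <- numeric(length(use))
    for (j in seq_along(use)) {
      Xj <- cbind(Xt, Gt[, j])
      if (all(d == 0)) {
        lj <- 0
      } else {
        opt <- optimize(.lmm_loglik, c(-12, 12), yt = yt, Xt = Xj, d = d,
                        maximum = TRUE)
        lj <- exp(opt$maximum)
      }
      w <- 1 / (lj * d + 1); sw <- sqrt(w)
      qr_a <- qr(Xt * sw)
      b_perp <- qr.resid(qr_a, yt * sw)
      g_perp <- qr.resid(qr_a, Gt[, j] * sw)
      gg <- sum(g_perp^2)
      beta[j] <- sum(g_perp * b_perp) / gg
      ssr <- sum(b_perp^2) - beta[j]^2 * gg
      se[j] <- sqrt(max(ssr, 0) / (n - ncol(X) - 1) / gg)
      lam[j] <- lj
    }
  }
  wald_p <- 2 * pnorm(-abs(beta / se))
  res <- data.frame(locus = colnames(gt$dosage)[use],
                    chrom = gt$loci$chrom[use], pos = gt$loci$pos[use],
                    beta = beta, se = se, wald_p = wald_p,
                    p_bh = p.adjust(wald_p, method = "BH"),
                    maf = maf[use], n_used = n_used,
                    stringsAsFactors = FALSE)
  attr(res, "lambda") <- lam
  attr(res, "n_tested") <- length(use)
  class(res) <- c("assoc_scan", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' lambda_GC = median of the chi-square(1) quantiles of the p-values divided
#' by the null median 0.4549; values near 1 indicate adequate correction of
#' structure-driven inflation.
#'
#' @param assoc [lmm_assoc_scan()] output or a numeric vector of p-values.
#' @return scalar lambda.
#' @export
genomic_inflation <- function(assoc) {
  p <- if (is.data.frame(assoc)) assoc$wald_p else as.numeric(assoc)
  if (length(p) < 100) stop("need at least 100 tests")
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

#' Select association outliers at a p-value tail
#'
#' Keeps all loci whose p-value is at most the ceiling(tail * n)-th smallest
#' p-value; ties at the threshold are all included, so the set may exceed
#' ceiling(tail * n).
#'
#' @param assoc [lmm_assoc_scan()] output.
#' @param tail tail fraction (default 0.0005, the 0.05 percent tail).
#' @return list: `loci` (data.frame subset of `assoc`), `threshold`.
#' @export
select_gwa_outliers <- function(assoc, tail = 0.0005) {
  if (!nrow(assoc)) stop("empty association table")
  if (tail <= 0 || tail > 1) stop("tail must be in (0, 1]")
  k <- min(nrow(assoc), max(1L, ceiling(tail * nrow(assoc))))
  thr <- sort(assoc$wald_p, partial = k)[k]
  list(loci = assoc[assoc$wald_p <= thr, , drop = FALSE], threshold = thr)
}

#' Select top differentiation outlier windows
#'
#' Windows with defined Fst at or above the value of the
#' ceiling(top * n)-th largest window Fst; undefined windows are excluded
#' before ranking and ties at the threshold are all included.
#'
#' @param windows [fst_windows()] output.
#' @param top fraction of windows to keep (default 0.05).
#' @return data.frame subset of `windows`.
#' @export
select_fst_outlier_windows <- function(windows, top = 0.05) {
  def <- windows[!is.na(windows$fst), , drop = FALSE]
  if (nrow(def) < 20) stop("need at least 20 defined windows")
  k <- max(1L, ceiling(top * nrow(def)))
  thr <- sort(def$fst, decreasing = TRUE)[k]
  def[def$fst >= thr, , drop = FALSE]
}

# window index (or 0) for each position, assuming non-overlapping windows
.window_of <- function(chrom, pos, windows) {
  wid <- integer(length(pos))
  for (ch in unique(chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (!nrow(w)) next
    ord <- order(w$start)
    w <- w[ord, , drop = FALSE]
    j <- findInterval(pos[i], w$start)
    inside <- j >= 1 & ifelse(j >= 1, pos[i] < w$end[pmax(j, 1)], FALSE)
    glob <- which(windows$chrom == ch)[ord]
    wid[i][inside] <- glob[j[inside]]
  }
  wid
}

#' Count outlier windows hit by a SNP set
#'
#' A window counts once if it contains at least one SNP of the set
#' (half-open [start, end) coordinates; a SNP exactly at `start` is inside).
#'
#' @param snp_set data.frame with `chrom`, `pos`.
#' @param window_set data.frame with `chrom`, `start`, `end`
#'   (non-overlapping).
#' @return integer count of distinct windows hit.
#' @export
count_overlaps <- function(snp_set, window_set) {
  if (!nrow(snp_set)) return(0L)
  wid <- .window_of(snp_set$chrom, snp_set$pos, window_set)
  length(unique(wid[wid > 0]))
}

#' Randomization test for SNP-set / outlier-window overlap
#'
#' Compares the number of outlier windows containing at least one SNP of
#' the observed set with the null distribution obtained by drawing
#' `n_draw` loci without replacement from all tested loci, B times. The
#' one-sided empirical p-value uses the (1 + x) / (B + 1) estimator.
#'
#' @param all_loci data.frame of every tested locus: `chrom`, `pos`.
#' @param window_set outlier windows (`chrom`, `start`, `end`).
#' @param snp_set observed outlier SNPs (`chrom`, `pos`).
#' @param n_draw loci per null draw; defaults to `nrow(snp_set)`.
#' @param B random draws (default 5000; a warning below 100).
#' @param seed integer seed.
#' @return list of class `overlap_result`: `observed`, `null_values`,
#'   `p_emp`, `B`, `n_snps_drawn`.
#' @export
overlap_randomization_test <- function(all_loci, window_set, snp_set,
                                       n_draw = nrow(snp_set), B = 5000,
                                       seed = 1L) {
  if (n_draw > nrow(all_loci)) stop("n_draw exceeds the number of tested loci")
  if (B < 100) warning("B < 100 gives a very coarse null")
  observed <- count_overlaps(snp_set, window_set)
  wid <- .window_of(all_loci$chrom, all_loci$pos, window_set)
  set.seed(seed)
  null_values <- vapply(seq_len(B), function(i) {
    w <- wid[sample.int(length(wid), n_draw)]
    length(unique(w[w > 0]))
  }, numeric(1))
  structure(list(observed = observed, null_values = null_values,
                 p_emp = (1 + sum(null_values >= observed)) / (B + 1),
                 B = B, n_snps_drawn = n_draw, seed = seed),
            class = "overlap_result")
}
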