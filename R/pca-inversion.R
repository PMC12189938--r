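#' Genotype PCA with optional LD pruning and region exclusion
#'
#' Dosages are mean-imputed and centred (optionally standardised by the
#' empirical SD) and decomposed by SVD. LD pruning slides a window of
#' `window` SNPs in steps of `step` and removes the later member of any pair
#' with squared correlation above `r2_max`, the usual pre-processing for
#' population-structure PCA. Known structural-variant regions (e.g.
#' inversions) can be excluded first so they do not dominate the axes.
#'
#' @param gt genotype_table.
#' @param ld_prune `NULL` or list with `window`, `step`, `r2_max`.
#' @param exclude_regions `NULL` or data.frame `chrom`, `start`, `end`
#'   (1-based inclusive start, exclusive end).
#' @param n_axes number of axes to return.
#' @param standardize divide centred dosages by their SD.
#' @return list of class `genotype_pca`: `scores` (samples x axes),
#'   `explained` (variance fractions), `kept_loci` (indices into `gt`).
#' @export
pca_genotypes <- function(gt, ld_prune = NULL, exclude_regions = NULL,
                          n_axes = 10, standardize = FALSE) {
  stopifnot(inherits(gt, "genotype_table"))
  keep <- rep(TRUE, ncol(gt$dosage))
  if (!is.null(exclude_regions)) {
    for (i in seq_len(nrow(exclude_regions))) {
      hit <- gt$loci$chrom == exclude_regions$chrom[i] &
        gt$loci$pos >= exclude_regions$start[i] &
        gt$loci$pos < exclude_regions$end[i]
      keep[hit] <- FALSE
    }
  }
  X <- gt$dosage[, keep, drop = FALSE]
  kept_idx <- which(keep)
  # mean imputation
  cm <- colMeans(X, na.rm = TRUE)
  na_at <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_at)) X[na_at] <- cm[na_at[, 2]]
  v <- apply(X, 2, var)
  poly <- v > 0
  X <- X[, poly, drop = FALSE]
  kept_idx <- kept_idx[poly]
  if (!is.null(ld_prune)) {
    stopifnot(all(c("window", "step", "r2_max") %in% names(ld_prune)))
    drop <- rep(FALSE, ncol(X))
    if (ld_prune$r2_max < 1) {
      start <- 1
      while (start <= ncol(X)) {
        idx <- seq(start, min(start + ld_prune$window - 1, ncol(X)))
        idx <- idx[!drop[idx]]
        if (length(idx) > 1) {
          r2 <- cor(X[, idx, drop = FALSE])^2
          for (jj in seq_along(idx)[-1]) {
            if (!drop[idx[jj]] &&
                any(r2[seq_len(jj - 1), jj] > ld_prune$r2_max &
                    !drop[idx[seq_len(jj - 1)]])) {
              drop[idx[jj]] <- TRUE
            }
          }
        }
        start <- start + ld_prune$step
      }
    }
    X <- X[, !drop, drop = FALSE]
    kept_idx <- kept_idx[!drop]
  }
  if (ncol(X) < 2) stop("fewer than 2 loci remain after pruning/exclusion")
  if (nrow(X) < 2) stop("need at least 2 samples")
  Xc <- scale(X, center = TRUE, scale = standardize)
  sv <- svd(Xc)
  n_axes <- min(n_axes, length(sv$d))
  expl <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- gt$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  structure(list(scores = scores, explained = expl[seq_len(n_axes)],
                 kept_loci = kept_idx),
            class = "genotype_pca")
}

#' Genotype a chromosomal inversion by local PCA
#'
#' Inversions segregate as non-recombining haplotype blocks, so a PCA of the
#' region's genotypes separates samples into three clusters along the first
#' axis: the two homozygote orientations at the extremes and heterozygotes in
#' between. One-dimensional k-means (k = 3, centres initialised at the score
#' quantiles, deterministic) assigns samples; clusters are ordered by centre
#' and labelled hom_A / het / hom_B. Which homozygote cluster is "ancestral"
#' is fixed by reference samples when supplied (via `ancestral_samples`),
#' otherwise hom_A (low end of PC1) is reported as ancestral by convention.
#'
#' @param gt genotype_table.
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (1-based, end exclusive); must contain >= 10 loci.
#' @param ancestral_samples optional sample ids of known ancestral
#'   homozygotes used to orient the calls.
#' @return list of class `inversion_calls`: `calls` data.frame (`sample_id`,
#'   `genotype` in ancestral-hom/heterozygous/derived-hom, `pc1`),
#'   `ancestral_freq` = (2 n_homAnc + n_het) / (2n), `centers`,
#'   `low_confidence` flag (fewer than 3 occupied clusters).
#' @export
genotype_inversion <- function(gt, region, ancestral_samples = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  in_reg <- gt$loci$chrom == region$chrom &
    gt$loci$pos >= region$start & gt$loci$pos < region$end
  if (sum(in_reg) < 10) stop("region contains fewer than 10 loci")
  sub <- subset_genotypes(gt, loci = which(in_reg))
  pc <- pca_genotypes(sub, n_axes = 1)
  s <- pc$scores[, 1]
  qs <- quantile(s, c(0.1, 0.5, 0.9))
  low_conf <- FALSE
  if (length(unique(qs)) < 3) {
    qs <- qs + c(-1e-8, 0, 1e-8)
    low_conf <- TRUE
  }
  km <- kmeans(s, centers = matrix(qs, ncol = 1))
  ord <- order(km$centers)
  lab3 <- c("hom_low", "heterozygous", "hom_high")
  cls <- lab3[match(km$cluster, ord)]
  if (length(unique(km$cluster)) < 3) low_conf <- TRUE
  anc_is_low <- TRUE
  if (!is.null(ancestral_samples)) {
    ref <- s[gt$samples$sample_id %in% ancestral_samples]
    if (!length(ref)) stop("no ancestral reference samples found in table")
    anc_is_low <- mean(ref) < median(km$centers)
  }
  geno <- ifelse(cls == "heterozygous", "heterozygous",
                 ifelse((cls == "hom_low") == anc_is_low,
                        "ancestral-hom", "derived-hom"))
  n_anc <- sum(geno == "ancestral-hom")
  n_het <- sum(geno == "heterozygous")
  structure(list(calls = data.frame(sample_id = gt$samples$sample_id,
                                    genotype = geno, pc1 = unname(s),
                                    stringsAsFactors = FALSE),
                 ancestral_freq = (2 * n_anc + n_het) / (2 * length(geno)),
                 centers = sort(as.numeric(km$centers)),
                 low_confidence = low_conf,
                 region = region),
            class = "inversion_calls")
}

#' Ancestry painting at diagnostic sites
#'
#' Diagnostic sites are those whose allele-frequency difference between two
#' reference groups is at least `fixity` and whose missingness does not
#' exceed `max_missing`. Every focal sample is labelled at each diagnostic
#' site as A-like, B-like, heterozygous, or missing, according to the allele
#' orientation defined by reference group A.
#'
#' @param gt genotype_table.
#' @param region `chrom`, `start`, `end` (end exclusive) to paint.
#' @param ref_group_a,ref_group_b sample ids of the two reference panels.
#' @param fixity minimum absolute reference frequency difference (default
#'   0.8).
#' @param max_missing maximum fraction of missing genotypes at a site
#'   (across all samples; default 0.2).
#' @return list of class `ancestry_painting`: `labels` (samples x diagnostic
#'   sites character matrix), `sites` (locus metadata), `n_diagnostic`.
#' @export
ancestry_paint <- function(gt, region, ref_group_a, ref_group_b,
                           fixity = 0.8, max_missing = 0.2) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!length(ref_group_a) || !length(ref_group_b)) {
    stop("both reference groups must be non-empty")
  }
  in_reg <- gt$loci$chrom == region$chrom &
    gt$loci$pos >= region$start & gt$loci$pos < region$end
  d <- gt$dosage[, in_reg, drop = FALSE]
  ia <- gt$samples$sample_id %in% ref_group_a
  ib <- gt$samples$sample_id %in% ref_group_b
  if (!any(ia) || !any(ib)) stop("reference samples not found in table")
  fr <- function(rows) {
    nn <- colSums(!is.na(d[rows, , drop = FALSE]))
    ifelse(nn > 0, colSums(d[rows, , drop = FALSE], na.rm = TRUE) / (2 * nn), NA)
  }
  pa <- fr(ia); pb <- fr(ib)
  missg <- colMeans(is.na(d))
  diag_site <- !is.na(pa) & !is.na(pb) &
    abs(pa - pb) >= fixity & missg <= max_missing
  if (!any(diag_site)) stop("no diagnostic sites at this fixity/missingness")
  dd <- d[, diag_site, drop = FALSE]
  # orient: the allele more common in reference A is the A allele
  a_is_alt <- pa[diag_site] > pb[diag_site]
  or <- dd
  or[, !a_is_alt] <- 2 - dd[, !a_is_alt, drop = FALSE]  # A-allele dosage
  lab <- matrix("missing", nrow(or), ncol(or),
                dimnames = list(gt$samples$sample_id,
                                colnames(gt$dosage)[in_reg][diag_site]))
  lab[!is.na(or) & or == 2] <- "A-like"
  lab[!is.na(or) & or == 1] <- "heterozygous"
  lab[!is.na(or) & or == 0] <- "B-like"
  structure(list(labels = lab,
                 sites = gt$loci[in_reg, ][diag_site, ],
                 n_diagnostic = sum(diag_site)),
            class = "ancestry_painting")
}
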