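# Small fixture builders shared across test files.

# genotype table from a dosage matrix, loci placed at fixed spacing
make_gt <- function(dosage, spacing = 1000, chrom = "chr1",
                    time_index = NULL, sex = NULL) {
  n <- nrow(dosage)
  L <- ncol(dosage)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(time_index)) samples$time_index <- time_index
  samples$sex <- if (is.null(sex)) rep_len(c("F", "M"), n) else sex
  loci <- data.frame(chrom = chrom, pos = seq_len(L) * spacing,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_table(dosage, loci, samples)
}

# random dosage matrix with optional missingness
random_dosage <- function(n, L, maf = 0.3, miss = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * L, 2, maf), n, L)
  if (miss > 0) d[runif(n * L) < miss] <- NA
  d
}

# freq_matrix built directly from a p matrix (time x loci)
make_freqs <- function(p, n = NULL) {
  if (is.null(n)) n <- matrix(10, nrow(p), ncol(p))
  if (is.null(colnames(p))) colnames(p) <- sprintf("L%04d", seq_len(ncol(p)))
  structure(list(p = p, n = n, times = seq_len(nrow(p))),
            class = "freq_matrix")
}

# independent naive Weir-Cockerham (1984) per-site implementation used as
# the oracle: plain loops, no shared code with the package version
wc_oracle <- function(dos, grp) {
  grp <- as.factor(grp)
  r <- nlevels(grp)
  n_i <- p_i <- h_i <- numeric(r)
  for (g in seq_len(r)) {
    x <- dos[grp == levels(grp)[g]]
    x <- x[!is.na(x)]
    n_i[g] <- length(x)
    p_i[g] <- if (length(x)) sum(x) / (2 * length(x)) else 0
    h_i[g] <- if (length(x)) mean(x == 1) else 0
  }
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# two-pass loop oracle for the cross-locus covariance of frequency changes
cov_oracle <- function(dA, dB) {
  ok <- !is.na(dA) & !is.na(dB)
  dA <- dA[ok]; dB <- dB[ok]
  mA <- sum(dA) / length(dA)
  mB <- sum(dB) / length(dB)
  s <- 0
  for (i in seq_along(dA)) s <- s + (dA[i] - mA) * (dB[i] - mB)
  unname(s / (length(dA) - 1))
}
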