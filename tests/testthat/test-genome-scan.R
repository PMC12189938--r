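test_that("Weir-Cockerham components match the independent 1984 oracle", {
  # fixed difference between two pairs of diploids
  dos <- c(0, 0, 2, 2)
  grp <- c("a", "a", "b", "b")
  s <- wc_fst_site(dos, grp)
  expect_equal(s$fst, 1)
  # identical composition gives a non-positive estimator
  s0 <- wc_fst_site(c(0, 1, 2, 0, 1, 2), rep(c("a", "b"), each = 3))
  expect_lte(s0$a / (s0$a + s0$b + s0$c), 0)
  # random tables with missingness against the loop oracle
  set.seed(19)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    dos <- rbinom(n, 2, runif(1, 0.1, 0.9))
    if (runif(1) < 0.3) dos[sample(n, 1)] <- NA
    grp <- sample(rep(c("a", "b"), length.out = n))
    got <- wc_fst_site(dos, grp)
    if (got$skipped) next
    want <- wc_oracle(dos, grp)
    expect_equal(c(got$a, got$b, got$c), unname(want), tolerance = 1e-12)
  }
  # monomorphic site is skipped with zeroed components
  sm <- wc_fst_site(rep(2, 6), rep(c("a", "b"), 3))
  expect_true(sm$skipped)
  expect_equal(c(sm$a, sm$b, sm$c), c(0, 0, 0))
})

test_that("windowed Fst is the ratio of summed components", {
  # 2 windows x 3 sites, positions straddling the 20-kb boundary
  set.seed(23)
  d <- random_dosage(12, 6, maf = 0.4, seed = 23)
  loci <- data.frame(chrom = "chr1",
                     pos = c(1, 9000, 19999, 20000, 25000, 39000),
                     ref = "A", alt = "T")
  gt <- genotype_table(d, loci, data.frame(sample_id = sprintf("s%02d", 1:12)))
  grp <- rep(c("x", "y"), each = 6)
  fw <- fst_windows(gt, grp, window_bp = 20000)
  comp <- wc_fst_components(d, grp)
  use <- !comp$skipped
  w1 <- which(loci$pos <= 20000); w2 <- which(loci$pos > 20000)
  expect_equal(fw$fst[1],
               sum(comp$a[w1][use[w1]]) /
                 sum((comp$a + comp$b + comp$c)[w1][use[w1]]))
  expect_equal(fw$fst[2],
               sum(comp$a[w2][use[w2]]) /
                 sum((comp$a + comp$b + comp$c)[w2][use[w2]]))
  expect_equal(fw$start, c(1, 20001))
  expect_equal(fw$n_sites, c(sum(use[w1]), sum(use[w2])))

  # all fixed differences -> window Fst of 1; empty window -> NA
  dfix <- rbind(matrix(0, 3, 2), matrix(2, 3, 2))
  gtf <- genotype_table(dfix,
                        data.frame(chrom = "chr1", pos = c(100, 45000),
                                   ref = "A", alt = "T"),
                        data.frame(sample_id = sprintf("f%d", 1:6)))
  fwf <- fst_windows(gtf, rep(c("x", "y"), each = 3), window_bp = 20000)
  expect_equal(fwf$fst[c(1, 3)], c(1, 1))
  expect_true(is.na(fwf$fst[2]))
  expect_equal(fwf$n_sites[2], 0)
})

test_that("pi and dxy are differences over comparisons including invariant sites", {
  # 1 segregating site (2 alt / 2 ref among 4 alleles) + 9 invariant sites
  counts <- data.frame(chrom = "c", pos = 1:10, group = "g",
                       n = 4, alt = c(2, rep(0, 9)))
  pw <- pi_windows(counts, window_bp = 50000)
  expect_equal(pw$pi, 4 / 60)
  expect_equal(pw$diffs, 4)
  expect_equal(pw$comparisons, 60)
  # all monomorphic -> 0
  counts0 <- transform(counts, alt = 0)
  expect_equal(pi_windows(counts0, 50000)$pi, 0)
  # a missing allele reduces that site's comparisons only
  counts_m <- counts
  counts_m$n[2] <- 2
  pwm <- pi_windows(counts_m, 50000)
  expect_equal(pwm$comparisons, 6 + 1 + 8 * 6)

  # dxy: fixed difference at 1 of 10 sites
  cx <- data.frame(chrom = "c", pos = 1:10, group = "x", n = 4,
                   alt = c(4, rep(0, 9)))
  cy <- data.frame(chrom = "c", pos = 1:10, group = "y", n = 4,
                   alt = 0)
  dxy <- dxy_windows(rbind(cx, cy), c("x", "y"), 50000)
  expect_equal(dxy$dxy, 0.1)
  # identical allele frequencies: dxy equals 2p(1-p) summed over sites
  cz <- transform(cx, group = "z", alt = c(2, rep(0, 9)))
  cw <- transform(cx, group = "w", alt = c(2, rep(0, 9)))
  d2 <- dxy_windows(rbind(cz, cw), c("z", "w"), 50000)
  expect_equal(d2$dxy, (2 * 0.5 * 0.5) / 10)
  # doubling every count leaves the ratio unchanged
  big <- rbind(transform(cx, n = 8, alt = alt * 2),
               transform(cy, n = 8, alt = alt * 2))
  expect_equal(dxy_windows(big, c("x", "y"), 50000)$dxy, 0.1)
  # genome-wide value is a ratio of sums over windows
  expect_equal(unname(genomewide_diversity(pw)), 4 / 60)
})

test_that("genotype PCA separates clonal groups and respects pruning options", {
  d <- rbind(matrix(0, 5, 30), matrix(2, 5, 30))
  d[1, 1] <- 1  # keep loci polymorphic within the clone pattern
  gt <- make_gt(d)
  pc <- pca_genotypes(gt, n_axes = 3)
  expect_gt(sum(pc$explained[1]), 0.95)
  expect_gt(abs(mean(pc$scores[1:5, 1]) - mean(pc$scores[6:10, 1])), 1)
  expect_lte(sum(pc$explained), 1 + 1e-8)

  set.seed(2)
  dr <- random_dosage(20, 40, seed = 31)
  dr[, 2] <- dr[, 1]            # a perfectly correlated pair must be pruned
  gtr <- make_gt(dr)
  pc_all <- pca_genotypes(gtr, ld_prune = list(window = 10, step = 5,
                                               r2_max = 1.0))
  expect_equal(length(pc_all$kept_loci), sum(apply(dr, 2, var) > 0))
  pc_pruned <- pca_genotypes(gtr, ld_prune = list(window = 10, step = 5,
                                                  r2_max = 0.2))
  expect_lt(length(pc_pruned$kept_loci), length(pc_all$kept_loci))
  # excluding a region removes its loci
  pc_ex <- pca_genotypes(gtr, exclude_regions = data.frame(
    chrom = "chr1", start = 1, end = 10001))
  expect_false(any(pc_ex$kept_loci <= 10))
})

test_that("inversion genotyping recovers three archetype clusters", {
  d <- rbind(matrix(0, 6, 15), matrix(1, 5, 15), matrix(2, 7, 15))
  set.seed(9)
  d[sample(length(d), 15)] <- NA   # some missingness
  gt <- make_gt(d, spacing = 500)
  region <- list(chrom = "chr1", start = 1, end = 10000)
  inv <- genotype_inversion(gt, region)
  expect_false(inv$low_confidence)
  truth <- rep(c("hom0", "het", "hom2"), c(6, 5, 7))
  expect_equal(inv$calls$genotype[truth == "het"],
               rep("heterozygous", 5))
  homs <- inv$calls$genotype[truth != "het"]
  expect_true(all(homs %in% c("ancestral-hom", "derived-hom")))
  expect_equal(length(unique(inv$calls$genotype[truth == "hom0"])), 1)
  # het cluster centre lies between the homozygote centres
  expect_true(inv$centers[1] < inv$centers[2] &&
                inv$centers[2] < inv$centers[3])
  # ancestral frequency is a simple count
  n_anc <- sum(inv$calls$genotype == "ancestral-hom")
  expect_equal(inv$ancestral_freq, (2 * n_anc + 5) / (2 * 18))
  # orientation by reference samples
  inv2 <- genotype_inversion(gt, region,
                             ancestral_samples = gt$samples$sample_id[13:18])
  expect_equal(inv2$calls$genotype[18], "ancestral-hom")
  expect_error(genotype_inversion(gt, list(chrom = "chr1", start = 1,
                                           end = 1000)), "10 loci")
})

test_that("ancestry painting labels diagnostic sites by reference orientation", {
  ref_a <- matrix(0, 4, 12)
  ref_b <- matrix(2, 4, 12)
  f1 <- matrix(1, 2, 12)       # F1-style heterozygote
  like_a <- matrix(0, 1, 12)
  d <- rbind(ref_a, ref_b, f1, like_a)
  d[1, 12] <- 2; d[5, 11] <- 0  # two non-diagnostic sites at fixity 1
  gt <- make_gt(d, spacing = 100)
  ids <- gt$samples$sample_id
  region <- list(chrom = "chr1", start = 1, end = 2000)
  ap <- ancestry_paint(gt, region, ids[1:4], ids[5:8], fixity = 1)
  expect_equal(ap$n_diagnostic, 10)
  expect_true(all(ap$labels[ids[11], ] == "A-like"))
  expect_true(all(ap$labels[ids[9], ] == "heterozygous"))
  ap8 <- ancestry_paint(gt, region, ids[1:4], ids[5:8], fixity = 0.7)
  expect_equal(ap8$n_diagnostic, 12)
  expect_error(ancestry_paint(gt, region, character(0), ids[5:8]),
               "non-empty")
})

test_that("Mann-Kendall exact p-values equal full enumeration", {
  mk <- mann_kendall(c(5, 4, 3, 2, 1))
  expect_equal(mk$S, -10)
  expect_equal(mk$p_one_sided, 1 / 120)
  expect_equal(mk$direction, "decreasing")
  mk2 <- mann_kendall(c(1, 2, 3))
  expect_equal(mk2$S, 3)
  expect_equal(mk2$p_one_sided, 1 / 6)
  # reversal negates S, same one-sided p
  set.seed(6)
  x <- rnorm(7)
  a <- mann_kendall(x); b <- mann_kendall(rev(x))
  expect_equal(a$S, -b$S)
  expect_equal(a$p_one_sided, b$p_one_sided)
  # all equal -> degenerate
  d <- mann_kendall(rep(2, 5))
  expect_equal(d$S, 0)
  expect_equal(d$p_one_sided, 1)
  # tied series: exact equals brute-force enumeration over orderings
  xt <- c(1, 2, 2, 3, 1)
  mk_t <- mann_kendall(xt)
  perms <- fiescan:::.permutations(5)
  s_all <- apply(perms, 1, function(p) fiescan:::.mk_s(xt[p]))
  expect_equal(mk_t$p_one_sided, mean(s_all >= mk_t$S))
  # large n falls back to the tie-corrected normal approximation
  mk_big <- mann_kendall(seq_len(20) + rep(c(0, 0.5), 10))
  expect_equal(mk_big$method, "normal")
  expect_lt(mk_big$p_one_sided, 0.001)
})
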