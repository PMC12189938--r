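#' Diploid genotype table
#'
#' Container for biallelic diploid genotypes: a samples x loci dosage matrix
#' (count of alternate alleles, 0/1/2 or NA for missing) plus locus and sample
#' metadata. This is the common currency of the genomic modules.
#'
#' @param dosage Numeric or integer matrix, samples in rows, loci in columns.
#'   Values must be 0, 1, 2 or NA.
#' @param loci data.frame with one row per locus: columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`. Positions must be sorted within chromosome.
#' @param samples data.frame with one row per sample: column `sample_id` is
#'   required; `time_index`, `year_label` and `sex` are used downstream when
#'   present.
#' @param validate check dosage values and position ordering (skippable for
#'   large programmatically built matrices whose construction guarantees
#'   both).
#' @return An object of class `genotype_table`: a list with elements `dosage`,
#'   `loci`, `samples`.
#' @export
genotype_table <- function(dosage, loci, samples, validate = TRUE) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(loci), is.data.frame(samples))
  if (nrow(samples) != nrow(dosage) || nrow(loci) != ncol(dosage)) {
    stop("dimensions of dosage do not match sample/locus metadata")
  }
  if (!all(c("chrom", "pos") %in% names(loci))) {
    stop("loci must have columns 'chrom' and 'pos'")
  }
  if (!"sample_id" %in% names(samples)) stop("samples must have 'sample_id'")
  if (validate) {
    bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
    if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
    ord_ok <- all(tapply(loci$pos, loci$chrom, function(p) !is.unsorted(p)))
    if (!ord_ok) stop("locus positions must be sorted within chromosome")
  }
  if (is.null(loci$ref)) loci$ref <- "A"
  if (is.null(loci$alt)) loci$alt <- "T"
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- paste(loci$chrom, loci$pos, sep = "_")
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosage), "samples x", ncol(x$dosage), "loci\n")
  if (!is.null(x$samples$time_index)) {
    cat("time points:", paste(sort(unique(x$samples$time_index)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Subset a genotype table
#'
#' @param x genotype_table.
#' @param samples,loci logical, integer or character index into samples/loci.
#' @return genotype_table restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosage)) else samples
  li <- if (is.null(loci)) seq_len(ncol(x$dosage)) else loci
  genotype_table(x$dosage[si, li, drop = FALSE],
                 x$loci[li, , drop = FALSE],
                 x$samples[si, , drop = FALSE])
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Emits one GT-only FORMAT column per sample; missing genotypes become `./.`.
#' Heterozygotes are always written `0/1` (dosage carries no phase).
#'
#' @param gt genotype_table.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  d <- t(gt$dosage)  # loci x samples
  code <- matrix("./.", nrow(d), ncol(d))
  code[!is.na(d) & d == 0] <- "0/0"
  code[!is.na(d) & d == 1] <- "0/1"
  code[!is.na(d) & d == 2] <- "1/1"
  body <- cbind(gt$loci$chrom, gt$loci$pos, ".", gt$loci$ref, gt$loci$alt,
                ".", "PASS", ".", "GT", code)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$samples$sample_id), collapse = "\t")),
             con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF file into a genotype table
#'
#' Uses \pkg{vcfR} for parsing. Only biallelic SNP records are kept; genotypes
#' are converted to alternate-allele dosages irrespective of phase.
#'
#' @param path VCF file (plain or gzipped).
#' @param metadata optional data.frame (or CSV path) of per-sample metadata
#'   with a `sample_id` column; joined to the VCF sample order. Every VCF
#'   sample must be present in the metadata when supplied.
#' @return genotype_table.
#' @export
read_genotypes_vcf <- function(path, metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  gtmat <- vcfR::extract.gt(v)[biallelic, , drop = FALSE]
  alleles <- gsub("\\|", "/", gtmat)
  dos <- matrix(NA_real_, nrow(alleles), ncol(alleles))
  dos[alleles == "0/0"] <- 0
  dos[alleles %in% c("0/1", "1/0")] <- 1
  dos[alleles == "1/1"] <- 2
  loci <- data.frame(chrom = fix$CHROM[biallelic],
                     pos = as.integer(fix$POS[biallelic]),
                     ref = fix$REF[biallelic], alt = fix$ALT[biallelic],
                     stringsAsFactors = FALSE)
  ids <- colnames(gtmat)
  if (is.null(metadata)) {
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  } else {
    if (is.character(metadata)) metadata <- read.csv(metadata, stringsAsFactors = FALSE)
    miss <- setdiff(ids, metadata$sample_id)
    if (length(miss)) stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    samples <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  genotype_table(t(dos), loci, samples)
}
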