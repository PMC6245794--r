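#' Filter a biallelic marker panel
#'
#' Applies the standard panel-cleaning rules for inbred cultivars, in order:
#' drop markers with any missing code; drop markers whose heterozygote
#' fraction is `>= max_het` (phenotyped and genotyped plants are different
#' individuals, so residual heterozygosity flags poorly fixed loci); drop
#' monomorphic markers; drop markers with minor allele frequency below
#' `maf_min` (heterozygotes count half an alternate allele); drop markers in
#' complete linkage with an earlier marker (exact duplicate columns,
#' including sign-flipped duplicates; the first occurrence is kept).
#'
#' @param codes cultivars x markers matrix coded -1 (homozygous reference),
#'   0 (heterozygous), 1 (homozygous alternate); dimnames are preserved.
#' @param maf_min minimum minor allele frequency (default 0.025).
#' @param max_het maximum heterozygote fraction (markers at or above are
#'   dropped; default 0.05).
#' @return the filtered matrix, with attribute `"filter_counts"` recording
#'   how many markers each rule removed.
#' @export
filter_markers <- function(codes, maf_min = 0.025, max_het = 0.05) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(-1, 0, 1) | is.na(codes)))
    stop("marker codes must be -1, 0, or 1")
  n0 <- ncol(codes)
  counts <- c(missing = 0L, het = 0L, monomorphic = 0L, maf = 0L,
              duplicate = 0L)

  keep <- colSums(is.na(codes)) == 0
  counts["missing"] <- sum(!keep)
  codes <- codes[, keep, drop = FALSE]

  het <- colMeans(codes == 0)
  keep <- het < max_het
  counts["het"] <- sum(!keep)
  codes <- codes[, keep, drop = FALSE]

  mono <- apply(codes, 2, function(z) length(unique(z)) == 1L)
  counts["monomorphic"] <- sum(mono)
  codes <- codes[, !mono, drop = FALSE]

  # alternate-allele frequency; heterozygote contributes one of two alleles
  alt <- colMeans(codes + 1) / 2
  maf <- pmin(alt, 1 - alt)
  keep <- maf >= maf_min
  counts["maf"] <- sum(!keep)
  codes <- codes[, keep, drop = FALSE]

  if (ncol(codes) > 1) {
    # complete linkage: identical or sign-flipped identical columns
    key <- apply(codes, 2, function(z) {
      if (z[which(z != 0)[1]] < 0) z <- -z
      paste(z, collapse = ",")
    })
    dup <- duplicated(key)
    counts["duplicate"] <- sum(dup)
    codes <- codes[, !dup, drop = FALSE]
  }
  if (ncol(codes) == 0)
    stop("all ", n0, " markers removed by filtering")
  attr(codes, "filter_counts") <- counts
  codes
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Column-centers the marker codes and scales the cross-product by twice the
#' summed allele-frequency variance: `K = Z Z' / (2 * sum(p_k (1 - p_k)))`
#' with `p_k` the alternate-allele frequency of marker k.  K is symmetric
#' and positive semi-definite, and its rows sum to zero.  GBLUP predictions
#' are invariant to any positive rescaling of K (the variance components
#' compensate), so the scaling is a reporting convention, not a modeling
#' choice.
#'
#' @param codes filtered cultivars x markers matrix in \{-1, 0, 1\}.
#' @return cultivars x cultivars relationship matrix.
#' @export
genomic_relationship <- function(codes) {
  codes <- as.matrix(codes)
  Z <- scale(codes, center = TRUE, scale = FALSE)
  freq <- colMeans(codes + 1) / 2
  denom <- 2 * sum(freq * (1 - freq))
  if (denom <= 0) stop("degenerate panel: no polymorphic markers")
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(codes), rownames(codes))
  K
}

#' Read a genotype matrix from CSV
#'
#' Expects a header row of marker ids and a first column of cultivar ids;
#' remaining cells are codes in \{-1, 0, 1\}.
#'
#' @param path CSV file path.
#' @return cultivars x markers numeric matrix with dimnames.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Maps diploid genotypes 0/0 to -1, 1/1 to 1, and 0/1 (or 1/0) to 0;
#' multiallelic sites and missing calls become `NA` (removed later by
#' [filter_markers()]).  Requires the `vcfR` package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return samples x markers numeric matrix.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code_one <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- -1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g == "1/1"] <- 1
    out
  }
  m <- apply(gt, 2, code_one)           # markers x samples -> coerced below
  m <- t(matrix(m, nrow = nrow(gt),
                dimnames = list(rownames(gt), colnames(gt))))
  m
}
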