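#' @importClassesFrom vcfR vcfR
#' @importFrom methods new
NULL

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into alternate-allele counts (0/1/2; `./.` becomes `NA`)
#' and optionally extracts per-genotype DP depths. Locus order is preserved.
#'
#' @param path VCF file (plain or gzipped, 4.x).
#' @param biallelic_only drop records with more than one ALT allele
#'   (default `TRUE`).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("VCF parse error in '", path,
                                           "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only) {
    alt <- fix[, "ALT"]
    keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  }
  if (!any(keep)) stop("no biallelic SNPs found in '", path, "'")
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  gt_allele_count <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(v) {
      if (any(is.na(v)) || any(v == ".")) return(NA_integer_)
      sum(as.integer(v) > 0L)
    }, integer(1))
  }
  codes <- apply(gt, 2, gt_allele_count)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = sum(keep))
  codes[is.na(gt)] <- NA_integer_
  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depth <- t(dp[keep, , drop = FALSE])
  }
  genotype_matrix(t(codes),
                  chrom = fix[keep, "CHROM"],
                  pos = as.integer(fix[keep, "POS"]),
                  individual_ids = colnames(gt),
                  depth = depth)
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 with GT fields; missing genotypes become `./.`.
#' Output is gzip-compressed (vcfR convention); `read_vcf()` round-trips it.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (a `.vcf.gz` suffix is recommended).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  if (n_individuals(g) == 0) stop("cannot write a VCF with no individuals")
  L <- n_loci(g)
  gt_str <- matrix("./.", nrow = L, ncol = n_individuals(g))
  codes <- t(g$genotypes)
  gt_str[which(codes == 0L)] <- "0/0"
  gt_str[which(codes == 1L)] <- "0/1"
  gt_str[which(codes == 2L)] <- "1/1"
  colnames(gt_str) <- g$individual_ids
  fix <- cbind(CHROM = g$chrom, POS = as.character(g$pos),
               ID = rep(".", L), REF = rep("A", L), ALT = rep("T", L),
               QUAL = rep(".", L), FILTER = rep(".", L), INFO = rep(".", L))
  gt <- cbind(FORMAT = rep("GT", L), gt_str)
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}
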