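#' Genotype QC thresholds
#'
#' Container for the genotype-level quality filters: per-locus and
#' per-individual maximum missingness, a minor-allele-frequency floor, and a
#' minimum per-genotype depth (applied only when depths are available).
#' Defaults match common practice for reduced-representation and WGS panels:
#' loci missing in more than 5% of individuals are dropped, individuals with
#' more than 40% missing data are dropped, and sites are retained only when
#' MAF is strictly greater than 0.05.
#'
#' @param max_locus_missing maximum tolerated per-locus missing fraction.
#' @param max_indiv_missing maximum tolerated per-individual missing fraction.
#' @param maf_min sites kept iff MAF strictly exceeds this value.
#' @param min_genotype_depth genotypes with depth below this are masked.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_locus_missing = 0.05, max_indiv_missing = 0.40,
                          maf_min = 0.05, min_genotype_depth = 2L) {
  for (v in c(max_locus_missing, max_indiv_missing, maf_min))
    if (v < 0 || v > 1) stop("QC fractions must lie in [0,1]")
  structure(list(max_locus_missing = max_locus_missing,
                 max_indiv_missing = max_indiv_missing,
                 maf_min = maf_min,
                 min_genotype_depth = as.integer(min_genotype_depth)),
            class = "qc_thresholds")
}

# per-locus minor allele frequency from allele counts over non-missing calls
locus_maf <- function(genotypes) {
  alt <- colSums(genotypes, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(genotypes))
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  pmin(p, 1 - p)
}

#' Apply genotype QC filters
#'
#' Filters are applied in a fixed, reported order: (1) mask genotypes below
#' the depth floor (when depths are present), (2) drop loci whose missing
#' fraction exceeds `max_locus_missing`, (3) drop individuals whose missing
#' fraction exceeds `max_indiv_missing`, (4) drop loci whose MAF (computed on
#' the retained individuals) is not strictly above `maf_min`.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `genotype_matrix`, with a `filter_report` attribute
#'   recording the counts removed at each step.
#' @export
filter_genotypes <- function(g, thresholds = qc_thresholds()) {
  if (n_loci(g) == 0 || n_individuals(g) == 0) stop("empty genotype matrix")
  t <- thresholds
  report <- list(input_loci = n_loci(g), input_individuals = n_individuals(g))

  gm <- g$genotypes
  if (!is.null(g$depth)) {
    masked <- !is.na(g$depth) & g$depth < t$min_genotype_depth
    gm[masked] <- NA_integer_
    report$genotypes_depth_masked <- sum(masked)
  } else report$genotypes_depth_masked <- 0L

  locus_miss <- colMeans(is.na(gm))
  keep_loci <- locus_miss <= t$max_locus_missing
  report$loci_removed_missingness <- sum(!keep_loci)
  gm <- gm[, keep_loci, drop = FALSE]

  indiv_miss <- rowMeans(is.na(gm))
  keep_ind <- indiv_miss <= t$max_indiv_missing
  report$individuals_removed_missingness <- sum(!keep_ind)
  if (!any(keep_ind)) stop("all individuals removed by the missingness filter")
  gm <- gm[keep_ind, , drop = FALSE]

  maf <- locus_maf(gm)
  keep_maf <- !is.na(maf) & maf > t$maf_min
  report$loci_removed_maf <- sum(!keep_maf)
  report$retained_loci <- sum(keep_maf)
  report$retained_individuals <- sum(keep_ind)

  out <- genotype_matrix(gm[, keep_maf, drop = FALSE],
                         g$chrom[keep_loci][keep_maf],
                         g$pos[keep_loci][keep_maf],
                         g$individual_ids[keep_ind],
                         pop_labels = if (!is.null(g$pop_labels)) g$pop_labels[keep_ind],
                         depth = if (!is.null(g$depth))
                           g$depth[keep_ind, keep_loci, drop = FALSE][, keep_maf, drop = FALSE])
  attr(out, "filter_report") <- report
  out
}
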