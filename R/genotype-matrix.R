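#' Genotype matrix container
#'
#' Holds biallelic-SNP genotypes as counts of the alternate allele (0, 1, 2,
#' or `NA` for missing) for a set of diploid individuals, together with locus
#' coordinates and optional per-individual population labels and per-genotype
#' sequencing depths.
#'
#' @param genotypes integer matrix, individuals x loci; entries in
#'   \{0, 1, 2, NA\}.
#' @param chrom character vector of per-locus chromosome identifiers.
#' @param pos integer vector of 1-based per-locus positions; must be strictly
#'   increasing within each chromosome.
#' @param individual_ids unique character vector, one per row.
#' @param pop_labels optional character vector of population names per
#'   individual.
#' @param depth optional numeric matrix of per-genotype depths (same shape as
#'   `genotypes`).
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, chrom, pos, individual_ids,
                            pop_labels = NULL, depth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  L <- ncol(genotypes)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  individual_ids <- as.character(individual_ids)
  if (length(chrom) != L || length(pos) != L)
    stop("chrom/pos length must equal the number of loci")
  if (length(individual_ids) != n)
    stop("individual_ids length must equal the number of individuals")
  if (anyDuplicated(individual_ids))
    stop("individual_ids must be unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing genotype codes must be in {0,1,2}")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(pop_labels)) {
    pop_labels <- as.character(pop_labels)
    if (length(pop_labels) != n)
      stop("pop_labels length must equal the number of individuals")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(genotypes)))
      stop("depth matrix must match genotypes in shape")
  }
  rownames(genotypes) <- individual_ids
  structure(list(genotypes = genotypes, chrom = chrom, pos = pos,
                 individual_ids = individual_ids, pop_labels = pop_labels,
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci\n")
  cat("  chromosomes:", length(unique(x$chrom)), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing fraction: %.4f\n", miss))
  if (!is.null(x$pop_labels)) {
    tb <- table(x$pop_labels)
    cat("  populations:", paste(sprintf("%s (%d)", names(tb), tb),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param ind individual index (logical, integer, or character ids).
#' @param loci locus index (logical or integer).
#' @param ... unused.
#' @return a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, ind, loci, ...) {
  if (missing(ind)) ind <- seq_len(nrow(x$genotypes))
  if (missing(loci)) loci <- seq_len(ncol(x$genotypes))
  if (is.character(ind)) ind <- match(ind, x$individual_ids)
  genotype_matrix(x$genotypes[ind, loci, drop = FALSE],
                  x$chrom[loci], x$pos[loci],
                  x$individual_ids[ind],
                  pop_labels = if (!is.null(x$pop_labels)) x$pop_labels[ind],
                  depth = if (!is.null(x$depth)) x$depth[ind, loci, drop = FALSE])
}

#' Number of individuals / loci
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$genotypes)

#' @rdname n_individuals
#' @export
n_loci <- function(g) ncol(g$genotypes)

# indices of individuals in a named population
pop_index <- function(g, pop) {
  if (is.null(g$pop_labels)) stop("genotype matrix carries no population labels")
  idx <- which(g$pop_labels == pop)
  if (!length(idx)) stop("unknown population label: ", pop)
  idx
}

#' Attach population labels from a delimited table
#'
#' Reads a two-column delimited file (individual_id, pop) and attaches the
#' labels to a genotype matrix, matching on individual id.
#'
#' @param g a `genotype_matrix`.
#' @param path path to a tab- or comma-delimited file with a header.
#' @return `g` with `pop_labels` set.
#' @export
read_pop_labels <- function(g, path) {
  tb <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 2) stop("label table needs columns: individual_id, pop")
  m <- match(g$individual_ids, tb[[1]])
  if (anyNA(m)) stop("label table is missing ids: ",
                     paste(g$individual_ids[is.na(m)], collapse = ", "))
  g$pop_labels <- as.character(tb[[2]][m])
  g
}
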