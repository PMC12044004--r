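#' Folded site-frequency spectra
#'
#' A folded SFS indexes sites by minor-allele count, avoiding any assumption
#' about ancestral states. The 1D spectrum for a population of n haploids has
#' classes 0..floor(n/2); the joint spectrum of two populations is a matrix
#' over allele counts (0..nA) x (0..nB) folded on the total count (entries
#' with total count above (nA+nB)/2 are reflected onto their complements;
#' classes exactly at half are merged deterministically onto the cell with
#' the smaller first index).
#'
#' @name folded_sfs_objects
NULL

fold_1d <- function(counts_by_d, n) {
  # counts_by_d: vector over alt counts 0..n
  eta <- numeric(floor(n / 2) + 1)
  for (d in 0:n) {
    m <- min(d, n - d)
    eta[m + 1] <- eta[m + 1] + counts_by_d[d + 1]
  }
  eta
}

fold_joint <- function(M) {
  # M: matrix over (0..nA) x (0..nB); fold (i,j) with (nA-i, nB-j)
  nA <- nrow(M) - 1L
  nB <- ncol(M) - 1L
  ntot <- nA + nB
  out <- matrix(0, nA + 1, nB + 1)
  for (i in 0:nA) for (j in 0:nB) {
    c <- i + j
    if (2 * c < ntot) out[i + 1, j + 1] <- out[i + 1, j + 1] + M[i + 1, j + 1]
    else if (2 * c > ntot) out[nA - i + 1, nB - j + 1] <-
        out[nA - i + 1, nB - j + 1] + M[i + 1, j + 1]
    else { # exactly half: merge onto the cell with the smaller row index
      ti <- min(i, nA - i)
      tj <- if (ti == i) j else nB - j
      out[ti + 1, tj + 1] <- out[ti + 1, tj + 1] + M[i + 1, j + 1]
    }
  }
  out
}

# subsample alt-allele counts hypergeometrically to a fixed haploid size
project_counts <- function(d, n, target) {
  ifelse(n == target, d,
         stats::rhyper(length(d), m = d, n = n - d, k = target))
}

#' Folded SFS of one population
#'
#' Sites genotyped in fewer than `min_presence` of the population's
#' individuals are excluded; sites with more genotypes than the target are
#' down-sampled hypergeometrically (seeded projection) so every site
#' contributes at the same haploid sample size.
#'
#' @param g a [genotype_matrix()] with labels.
#' @param pop population name.
#' @param min_presence minimum fraction of individuals genotyped.
#' @param seed seed for the hypergeometric projection.
#' @return object of class `folded_sfs`: counts over minor-allele classes
#'   0..floor(n/2) with attributes `n_hap` and `n_sites`.
#' @export
folded_sfs <- function(g, pop, min_presence = 0.80, seed = 1L) {
  ind <- pop_index(g, pop)
  sub <- g$genotypes[ind, , drop = FALSE]
  n_target <- 2L * as.integer(ceiling(min_presence * length(ind)))
  if (n_target < 2) stop("target sample size below 2 haploids")
  n_al <- 2L * colSums(!is.na(sub))
  d <- colSums(sub, na.rm = TRUE)
  keep <- n_al >= n_target
  if (!is.null(seed)) set.seed(seed)
  dp <- project_counts(d[keep], n_al[keep], n_target)
  eta <- fold_1d(tabulate(dp + 1L, nbins = n_target + 1L), n_target)
  structure(eta, class = "folded_sfs", n_hap = n_target, n_sites = sum(keep))
}

#' Folded joint SFS of a population pair
#'
#' @param g a [genotype_matrix()] with labels.
#' @param popA,popB population names.
#' @param min_presence minimum fraction of individuals genotyped, applied in
#'   each population (sites must satisfy both).
#' @param seed seed for the hypergeometric projection.
#' @return object of class `joint_folded_sfs`: (nA+1) x (nB+1) folded count
#'   matrix with attributes `n_hap_A`, `n_hap_B`, `n_sites`.
#' @export
joint_folded_sfs <- function(g, popA, popB, min_presence = 0.80, seed = 1L) {
  iA <- pop_index(g, popA); iB <- pop_index(g, popB)
  gA <- g$genotypes[iA, , drop = FALSE]
  gB <- g$genotypes[iB, , drop = FALSE]
  tA <- 2L * as.integer(ceiling(min_presence * length(iA)))
  tB <- 2L * as.integer(ceiling(min_presence * length(iB)))
  nA <- 2L * colSums(!is.na(gA)); dA <- colSums(gA, na.rm = TRUE)
  nB <- 2L * colSums(!is.na(gB)); dB <- colSums(gB, na.rm = TRUE)
  keep <- nA >= tA & nB >= tB
  if (!is.null(seed)) set.seed(seed)
  dAp <- project_counts(dA[keep], nA[keep], tA)
  dBp <- project_counts(dB[keep], nB[keep], tB)
  M <- matrix(0, tA + 1, tB + 1)
  for (s in seq_along(dAp)) M[dAp[s] + 1, dBp[s] + 1] <- M[dAp[s] + 1, dBp[s] + 1] + 1
  F <- fold_joint(M)
  structure(F, class = "joint_folded_sfs", n_hap_A = tA, n_hap_B = tB,
            n_sites = sum(keep))
}

#' Write / read an SFS as a small text matrix
#'
#' Header lines carry the haploid sample sizes and site count; the body is a
#' whitespace-delimited count matrix (1D spectra are a single row).
#'
#' @param sfs a `folded_sfs` or `joint_folded_sfs`.
#' @param path file path.
#' @return `path` (write) or the SFS object (read).
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(sfs, "joint_folded_sfs")) {
    writeLines(c(sprintf("# joint_folded_sfs n_hap_A=%d n_hap_B=%d n_sites=%d",
                         attr(sfs, "n_hap_A"), attr(sfs, "n_hap_B"),
                         attr(sfs, "n_sites"))), con)
    utils::write.table(unclass(sfs), con, row.names = FALSE,
                       col.names = FALSE)
  } else {
    writeLines(sprintf("# folded_sfs n_hap=%d n_sites=%d",
                       attr(sfs, "n_hap"), attr(sfs, "n_sites")), con)
    writeLines(paste(as.numeric(sfs), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# *", "", lines[1]), " +")[[1]]
  kv <- function(key) as.integer(sub(paste0(key, "="), "",
                                     grep(paste0("^", key, "="), hdr, value = TRUE)))
  body <- lines[-1]
  M <- do.call(rbind, lapply(body, function(x)
    as.numeric(strsplit(trimws(x), " +")[[1]])))
  if (hdr[1] == "joint_folded_sfs") {
    structure(M, class = "joint_folded_sfs", n_hap_A = kv("n_hap_A"),
              n_hap_B = kv("n_hap_B"), n_sites = kv("n_sites"))
  } else {
    structure(as.numeric(M), class = "folded_sfs", n_hap = kv("n_hap"),
              n_sites = kv("n_sites"))
  }
}
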