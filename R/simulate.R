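#' @useDynLib foniokit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run the compiled coalescent engine; samples is a named vector of diploid
# counts per population (zero allowed)
run_engine <- function(model, samples, n_loci, locus_len = 1, mu = model$mu,
                       want_sites = FALSE, one_snp_per_locus = FALSE,
                       want_trees = FALSE, want_sfs = FALSE,
                       focal = NULL) {
  nhap <- integer(length(model$pop_names))
  names(nhap) <- model$pop_names
  if (is.null(names(samples))) {
    if (length(samples) != length(nhap))
      stop("unnamed samples must give one count per population")
    nhap[] <- 2L * as.integer(samples)
  } else {
    if (!all(names(samples) %in% model$pop_names))
      stop("sample names must match model populations")
    nhap[names(samples)] <- 2L * as.integer(samples)
  }
  if (any(nhap < 0) || sum(nhap) < 2)
    stop("samples must be non-negative with at least one diploid in total")
  ev <- compile_model(model)
  fa <- fb <- -1L
  if (want_sfs) {
    fa <- match(focal[1], model$pop_names) - 1L
    fb <- match(focal[2], model$pop_names) - 1L
  }
  cpp_simulate(nhap, model$pop_sizes, ev$ev_time, ev$ev_type, ev$ev_p1,
               ev$ev_p2, ev$ev_size, as.integer(n_loci), locus_len, mu,
               want_sites, one_snp_per_locus, want_trees, want_sfs, fa, fb)
}

# haplotype labels in engine tip order, and their populations
hap_layout <- function(model, samples) {
  nhap <- integer(length(model$pop_names))
  names(nhap) <- model$pop_names
  if (is.null(names(samples))) nhap[] <- 2L * as.integer(samples)
  else nhap[names(samples)] <- 2L * as.integer(samples)
  pop_of_hap <- rep(model$pop_names, nhap)
  n_dip <- nhap %/% 2L
  ind_ids <- unlist(lapply(model$pop_names[n_dip > 0], function(p)
    paste0(p, "_", seq_len(n_dip[p]))), use.names = FALSE)
  list(nhap = nhap, pop_of_hap = pop_of_hap, n_dip = n_dip,
       ind_ids = ind_ids, pop_of_ind = rep(model$pop_names, n_dip))
}

# haplotype 0/1 raw matrix -> diploid genotype matrix (consecutive pairing)
pair_haplotypes <- function(H) {
  H <- matrix(as.integer(H), nrow = nrow(H))
  odd <- seq(1, nrow(H), by = 2)
  H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
}

#' Simulate unlinked SNP loci under a demographic model
#'
#' Draws one independent genealogy per locus under the standard structured
#' n-coalescent (no migration, no intra-locus recombination) and drops
#' infinite-sites mutations on branches as a Poisson process with rate
#' `mu * locus_len` per generation. With `one_snp_per_locus = TRUE` each
#' locus instead contributes exactly one segregating site, sampled on a
#' branch with probability proportional to branch length.
#'
#' @param model a [demographic_model()].
#' @param samples named vector of diploid sample counts per population.
#' @param n_loci number of independent loci.
#' @param locus_len locus length in bp.
#' @param seed integer seed (sets the R RNG).
#' @param one_snp_per_locus force exactly one SNP per locus.
#' @return a `simulated_dataset`: list with `genotypes`
#'   (a [genotype_matrix()] of the polymorphic sites, one chromosome per
#'   locus), `tmrca` per locus, and the `seed`.
#' @export
simulate_unlinked_snps <- function(model, samples, n_loci, locus_len = 1000,
                                   seed = NULL, one_snp_per_locus = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  lay <- hap_layout(model, samples)
  res <- run_engine(model, samples, n_loci, locus_len, want_sites = TRUE,
                    one_snp_per_locus = one_snp_per_locus)
  H <- res$haplotypes
  if (is.null(H) || ncol(H) == 0)
    stop("no segregating sites simulated; increase n_loci, locus_len or mu")
  g <- pair_haplotypes(H)
  loc <- res$site_locus
  # unique, sorted positions within each locus (each locus is a chromosome)
  pos <- integer(length(loc))
  for (l in unique(loc)) {
    idx <- which(loc == l)
    if (length(idx) > locus_len)
      stop("more segregating sites than base pairs in locus ", l)
    pos[idx] <- sort(sample.int(locus_len, length(idx)))
  }
  gm <- genotype_matrix(g, chrom = paste0("locus_", loc), pos = pos,
                        individual_ids = lay$ind_ids,
                        pop_labels = lay$pop_of_ind)
  structure(list(genotypes = gm, tmrca = res$tmrca, haplotypes = NULL,
                 windows = NULL, true_trees = NULL, model = model,
                 samples = samples, seed = seed),
            class = "simulated_dataset")
}

#' Simulate contiguous windows with true genealogies
#'
#' One independent genealogy per window (free recombination between windows,
#' none within). Windows tile a single chromosome; SNP positions are uniform
#' within each window, so sliding-window code runs unchanged on the output.
#' The true per-window genealogy is returned in newick (haplotype tips
#' `h1..hn` in population order).
#'
#' @param model a [demographic_model()].
#' @param samples named vector of diploid counts.
#' @param n_windows number of windows.
#' @param window_len window length in bp.
#' @param seed integer seed.
#' @return a `simulated_dataset` with `genotypes`, `windows` (data.frame of
#'   chrom/start/end), `true_trees` (newick strings), and per-window
#'   haplotype matrices in `haplotypes`.
#' @export
simulate_windows <- function(model, samples, n_windows, window_len = 50000,
                             seed = NULL) {
  if (window_len < 1) stop("window_len must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lay <- hap_layout(model, samples)
  res <- run_engine(model, samples, n_windows, window_len, want_sites = TRUE,
                    want_trees = TRUE)
  loc <- res$site_locus
  H <- res$haplotypes
  pos <- integer(length(loc))
  haps <- vector("list", n_windows)
  for (l in seq_len(n_windows)) {
    idx <- which(loc == l)
    if (length(idx) > window_len)
      stop("more segregating sites than base pairs in window ", l)
    pos[idx] <- (l - 1L) * window_len + sort(sample.int(window_len, length(idx)))
    haps[[l]] <- matrix(as.integer(H[, idx, drop = FALSE]), nrow = nrow(H))
  }
  o <- order(pos)
  g <- pair_haplotypes(H[, o, drop = FALSE])
  windows <- data.frame(chrom = "chr1",
                        start = (seq_len(n_windows) - 1L) * window_len + 1L,
                        end = seq_len(n_windows) * window_len)
  gm <- genotype_matrix(g, chrom = rep("chr1", length(pos)), pos = pos[o],
                        individual_ids = lay$ind_ids,
                        pop_labels = lay$pop_of_ind)
  structure(list(genotypes = gm, tmrca = res$tmrca, haplotypes = haps,
                 hap_pos = lapply(seq_len(n_windows), function(l)
                   sort(pos[loc == l]) - (l - 1L) * window_len),
                 windows = windows, true_trees = as.character(res$newick),
                 hap_pop = lay$pop_of_hap, model = model, samples = samples,
                 seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", n_individuals(x$genotypes), "individuals,",
      n_loci(x$genotypes), "segregating sites\n")
  if (!is.null(x$windows)) cat("  windows:", nrow(x$windows), "\n")
  invisible(x)
}

#' Write per-individual FASTA sequences from simulated windows
#'
#' Places the simulated alleles on a fixed random background sequence (drawn
#' once per window from the dataset's seed), writing each individual's two
#' haplotype sequences per window. The reference base at a segregating
#' position carries allele 0 and a fixed alternate base carries allele 1, so
#' genotypes are exactly recomputable from the sequences.
#'
#' @param dataset a `simulated_dataset` from [simulate_windows()].
#' @param dir output directory; one FASTA per individual.
#' @param seed seed for the background sequence (defaults to the dataset's).
#' @return named character vector of file paths.
#' @export
emit_sequences <- function(dataset, dir, seed = dataset$seed) {
  if (is.null(dataset$haplotypes))
    stop("dataset carries no haplotypes; use simulate_windows()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n_win <- nrow(dataset$windows)
  wl <- dataset$windows$end[1] - dataset$windows$start[1] + 1L
  bases <- c("A", "C", "G", "T")
  backgrounds <- lapply(seq_len(n_win), function(l)
    sample(bases, wl, replace = TRUE))
  alt_of <- c(A = "T", C = "G", G = "C", T = "A")
  n_hap <- length(dataset$hap_pop)
  ids <- dataset$genotypes$individual_ids
  paths <- character(length(ids))
  names(paths) <- ids
  for (i in seq_along(ids)) {
    recs <- character(0)
    for (h in 1:2) {
      hap_row <- 2L * (i - 1L) + h
      for (l in seq_len(n_win)) {
        seqv <- backgrounds[[l]]
        posl <- dataset$hap_pos[[l]]
        if (length(posl)) {
          carr <- dataset$haplotypes[[l]][hap_row, ] == 1L
          if (any(carr))
            seqv[posl[carr]] <- alt_of[seqv[posl[carr]]]
        }
        recs <- c(recs, paste0(">", ids[i], "_win", l, "_hap", h),
                  paste(seqv, collapse = ""))
      }
    }
    paths[i] <- file.path(dir, paste0(ids[i], ".fasta"))
    writeLines(recs, paths[i])
  }
  paths
}

#' Inject genotype missingness
#'
#' Sets genotype cells to missing independently at a global rate or at
#' per-individual rates (emulating, e.g., platform- or species-specific
#' missingness differences).
#'
#' @param g a [genotype_matrix()].
#' @param rate global missingness rate, or a vector of per-individual rates.
#' @param seed integer seed.
#' @return the `genotype_matrix` with injected missingness.
#' @export
inject_missingness <- function(g, rate, seed = NULL) {
  if (any(rate < 0 | rate > 1)) stop("missingness rates must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(g); L <- n_loci(g)
  r <- if (length(rate) == 1) rep(rate, n) else rate
  if (length(r) != n) stop("need one rate, or one per individual")
  gm <- g$genotypes
  for (i in seq_len(n)) {
    if (r[i] > 0) {
      miss <- stats::runif(L) < r[i]
      gm[i, miss] <- NA_integer_
    }
  }
  g$genotypes <- gm
  g
}
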