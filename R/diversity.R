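#' Sliding-window specification
#'
#' @param size window size in bp.
#' @param step step between window starts in bp (must not exceed `size`).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(size = 50000, step = 10000) {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "window_spec")
}

# 1-based closed windows tiling [1, max_pos]
make_windows <- function(max_pos, w) {
  starts <- seq(1L, max(1L, max_pos), by = w$step)
  data.frame(start = starts, end = starts + w$size - 1L)
}

# Watterson's harmonic number a_{n-1}
harmonic_a <- function(n) if (n < 2) NA_real_ else sum(1 / seq_len(n - 1))

# per-site pi contributions from alt counts d out of n alleles (unbiased)
pi_site <- function(d, n) ifelse(n > 1, 2 * d * (n - d) / (n * (n - 1)), 0)

tajima_d_stat <- function(S, pi_total, n) {
  if (is.na(n) || n < 2 || S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / a1) / sqrt(v)
}

#' Sliding-window diversity statistics
#'
#' Computes, per window and population: the number of segregating sites S,
#' nucleotide diversity pi, Watterson's theta, and Tajima's D. Within each
#' population, loci missing in more than `max_locus_missing_within_pop` of
#' that population's individuals are dropped before computing. pi uses
#' unbiased per-site heterozygosity from pairwise-complete allele counts;
#' theta_W divides S by the harmonic number at the median haploid sample
#' size across used loci; per-site values divide by the full window length.
#'
#' @param g a [genotype_matrix()] with population labels.
#' @param pops populations to compute (default: all labelled).
#' @param w a [window_spec()].
#' @param max_locus_missing_within_pop per-population locus missingness cap.
#' @return data.frame with one row per window x population: chrom, start,
#'   end, pop, S, pi, theta_w, tajima_d, n_used, sites_used. Tajima's D is
#'   `NA` when S = 0.
#' @export
window_diversity <- function(g, pops = NULL, w = window_spec(),
                             max_locus_missing_within_pop = 0.20) {
  if (is.null(g$pop_labels)) stop("population labels required")
  if (is.null(pops)) pops <- unique(g$pop_labels)
  if (!all(pops %in% g$pop_labels)) stop("unknown population label")
  out <- list()
  for (ch in unique(g$chrom)) {
    on_ch <- which(g$chrom == ch)
    wins <- make_windows(max(g$pos[on_ch]), w)
    for (k in seq_len(nrow(wins))) {
      in_win <- on_ch[g$pos[on_ch] >= wins$start[k] & g$pos[on_ch] <= wins$end[k]]
      for (pp in pops) {
        ind <- pop_index(g, pp)
        sub <- g$genotypes[ind, in_win, drop = FALSE]
        if (ncol(sub)) {
          miss <- colMeans(is.na(sub))
          sub <- sub[, miss <= max_locus_missing_within_pop, drop = FALSE]
        }
        n_al <- 2L * colSums(!is.na(sub))
        d <- colSums(sub, na.rm = TRUE)
        seg <- n_al > 0 & d > 0 & d < n_al
        S <- sum(seg)
        pi_tot <- sum(pi_site(d[seg], n_al[seg]))
        n_med <- if (ncol(sub)) stats::median(n_al[n_al > 0]) else 2L * length(ind)
        if (is.na(n_med)) n_med <- 2L * length(ind)
        theta_tot <- if (S > 0) S / harmonic_a(n_med) else 0
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = wins$start[k], end = wins$end[k], pop = pp,
          S = S, pi = pi_tot / w$size, theta_w = theta_tot / w$size,
          tajima_d = tajima_d_stat(S, pi_tot, n_med),
          n_used = length(ind), sites_used = ncol(sub))
      }
    }
  }
  do.call(rbind, out)
}

#' Between-population divergence dxy and da per window
#'
#' dxy is the mean per-site difference between one sequence from population A
#' and one from B over all cross pairs (pairwise-complete allele counts);
#' da = dxy - (pi_A + pi_B)/2 is the net divergence and may be negative.
#'
#' @param g a [genotype_matrix()] with labels.
#' @param popA,popB population names (each with at least one individual).
#' @param w a [window_spec()].
#' @return data.frame: chrom, start, end, dxy, da, pi_A, pi_B, sites_used.
#' @export
dxy_da <- function(g, popA, popB, w = window_spec()) {
  iA <- pop_index(g, popA)
  iB <- pop_index(g, popB)
  out <- list()
  for (ch in unique(g$chrom)) {
    on_ch <- which(g$chrom == ch)
    wins <- make_windows(max(g$pos[on_ch]), w)
    for (k in seq_len(nrow(wins))) {
      in_win <- on_ch[g$pos[on_ch] >= wins$start[k] & g$pos[on_ch] <= wins$end[k]]
      gA <- g$genotypes[iA, in_win, drop = FALSE]
      gB <- g$genotypes[iB, in_win, drop = FALSE]
      nA <- 2L * colSums(!is.na(gA)); dA <- colSums(gA, na.rm = TRUE)
      nB <- 2L * colSums(!is.na(gB)); dB <- colSums(gB, na.rm = TRUE)
      ok <- nA > 0 & nB > 0
      dxy_tot <- sum((dA[ok] * (nB[ok] - dB[ok]) + dB[ok] * (nA[ok] - dA[ok])) /
                       (nA[ok] * nB[ok]))
      piA <- sum(pi_site(dA[ok], nA[ok]))
      piB <- sum(pi_site(dB[ok], nB[ok]))
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = wins$start[k], end = wins$end[k],
        dxy = dxy_tot / w$size,
        da = (dxy_tot - (piA + piB) / 2) / w$size,
        pi_A = piA / w$size, pi_B = piB / w$size, sites_used = sum(ok))
    }
  }
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay
#'
#' r^2 is the squared Pearson correlation of genotype codes for every
#' intra-chromosome locus pair with distance at most `max_dist`
#' (pairwise-complete individuals), binned by distance.
#'
#' @param g a [genotype_matrix()].
#' @param pop population name (default: all individuals).
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame: bin midpoint `dist`, `mean_r2`, `n_pairs`, plus an
#'   attribute `n_undefined` counting monomorphic (undefined-r2) pairs.
#' @export
ld_decay <- function(g, pop = NULL, max_dist = 500000, bin_width = 1000) {
  ind <- if (is.null(pop)) seq_len(n_individuals(g)) else pop_index(g, pop)
  dists <- numeric(0); r2s <- numeric(0); n_undef <- 0L
  for (ch in unique(g$chrom)) {
    on_ch <- which(g$chrom == ch)
    if (length(on_ch) < 2) next
    sub <- g$genotypes[ind, on_ch, drop = FALSE]
    p <- g$pos[on_ch]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    D <- abs(outer(p, p, "-"))
    up <- upper.tri(D)
    sel <- up & D <= max_dist
    r2 <- cc[sel]^2
    n_undef <- n_undef + sum(is.na(r2))
    keep <- !is.na(r2)
    dists <- c(dists, D[sel][keep])
    r2s <- c(r2s, r2[keep])
  }
  if (!length(r2s)) {
    out <- data.frame(dist = numeric(0), mean_r2 = numeric(0),
                      n_pairs = integer(0))
  } else {
    bin <- pmin(floor(dists / bin_width), ceiling(max_dist / bin_width) - 1)
    agg <- tapply(r2s, bin, mean)
    cnt <- tapply(r2s, bin, length)
    mids <- (as.numeric(names(agg)) + 0.5) * bin_width
    out <- data.frame(dist = mids, mean_r2 = as.numeric(agg),
                      n_pairs = as.integer(cnt))
  }
  attr(out, "n_undefined") <- n_undef
  out
}
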