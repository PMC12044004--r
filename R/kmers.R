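revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mers of a nucleotide sequence
#'
#' Slides a window of width `k` along the sequence, skips windows containing
#' `N`, and replaces each k-mer by the lexicographic minimum of itself and
#' its reverse complement. `k` must be odd so no k-mer equals its own
#' reverse complement.
#'
#' @param seq a single nucleotide string over A/C/G/T/N.
#' @param k odd k-mer size (default 31).
#' @return character vector of unique canonical k-mers (empty if
#'   `k > nchar(seq)`).
#' @export
canonical_kmers <- function(seq, k = 31) {
  if (k %% 2 == 0) stop("k must be odd")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (k > L) return(character(0))
  km <- substring(seq, 1:(L - k + 1), k:L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character(0))
  rc <- revcomp_chr(km)
  unique(ifelse(km <= rc, km, rc))
}

# per-sequence occurrence table: canonical kmer, seen-as-given, seen-as-rc
kmer_orientations <- function(seqs, k) {
  fwd <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    L <- nchar(s)
    if (k > L) return(character(0))
    km <- substring(s, 1:(L - k + 1), k:L)
    km[!grepl("N", km, fixed = TRUE)]
  }), use.names = FALSE)
  if (!length(fwd))
    return(data.frame(kmer = character(0), canon = logical(0),
                      noncanon = logical(0)))
  rc <- revcomp_chr(fwd)
  canon_form <- ifelse(fwd <= rc, fwd, rc)
  is_canon <- fwd <= rc
  canon <- tapply(is_canon, canon_form, any)
  noncanon <- tapply(!is_canon, canon_form, any)
  data.frame(kmer = names(canon), canon = as.logical(canon),
             noncanon = as.logical(noncanon), row.names = NULL)
}

#' Build a k-mer presence/absence table
#'
#' Decomposes each individual's sequences into canonical k-mers and applies,
#' in order: (1) an optional canonization-support filter — a k-mer is kept
#' only if at least `min_canonized_fraction` of the individuals carrying it
#' observed it in both its canonical and non-canonical orientation — and
#' (2) a minor-allele filter treating presence/absence across individuals as
#' the two alleles (minor allele count >= `mac_min` and minor allele
#' frequency strictly > `maf_min`).
#'
#' @param fastas named character vector of per-individual FASTA paths, or a
#'   named list of character vectors of sequences.
#' @param k odd k-mer size.
#' @param min_canonized_fraction canonization-support threshold;
#'   `NA` disables the filter.
#' @param mac_min minimum minor allele count.
#' @param maf_min minor allele frequency floor (strict).
#' @param both_strands also scan the reverse complement of every sequence
#'   (emulating reads sampled from both strands).
#' @return object of class `kmer_table`: list with `k`, `kmers`, logical
#'   `presence` (k-mers x individuals), and `filter_state`.
#' @export
build_kmer_table <- function(fastas, k = 31, min_canonized_fraction = 0.20,
                             mac_min = 2, maf_min = 0.05,
                             both_strands = TRUE) {
  if (length(fastas) < 2) stop("need at least two individuals")
  if (is.null(names(fastas))) stop("fastas must be named by individual")
  get_seqs <- function(x) {
    if (file.exists(x[1]) && length(x) == 1) {
      ss <- tryCatch(Biostrings::readDNAStringSet(x),
                     error = function(e) stop("cannot read FASTA '", x, "': ",
                                              conditionMessage(e)))
      as.character(ss)
    } else as.character(x)
  }
  per_ind <- lapply(fastas, function(x) {
    seqs <- get_seqs(x)
    if (both_strands) seqs <- c(seqs, revcomp_chr(seqs))
    kmer_orientations(seqs, k)
  })
  all_kmers <- sort(unique(unlist(lapply(per_ind, `[[`, "kmer"),
                                  use.names = FALSE)))
  n_ind <- length(per_ind)
  presence <- matrix(FALSE, length(all_kmers), n_ind,
                     dimnames = list(all_kmers, names(fastas)))
  canon_m <- noncanon_m <- presence
  for (i in seq_len(n_ind)) {
    m <- match(per_ind[[i]]$kmer, all_kmers)
    presence[m, i] <- TRUE
    canon_m[m, i] <- per_ind[[i]]$canon
    noncanon_m[m, i] <- per_ind[[i]]$noncanon
  }
  state <- list(k = k, n_input_kmers = length(all_kmers))
  keep <- rep(TRUE, length(all_kmers))
  if (!is.na(min_canonized_fraction)) {
    carriers <- rowSums(presence)
    both <- rowSums(canon_m & noncanon_m)
    keep <- carriers > 0 & (both / carriers) >= min_canonized_fraction
    state$removed_canonization <- sum(!keep)
  } else state$removed_canonization <- 0L
  pres2 <- presence[keep, , drop = FALSE]
  cnt <- rowSums(pres2)
  mac <- pmin(cnt, n_ind - cnt)
  maf <- mac / n_ind
  keep2 <- mac >= mac_min & maf > maf_min
  state$removed_minor_allele <- sum(!keep2)
  state$retained <- sum(keep2)
  structure(list(k = k, kmers = rownames(pres2)[keep2],
                 presence = pres2[keep2, , drop = FALSE],
                 filter_state = state),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, ",", length(x$kmers), "k-mers x",
      ncol(x$presence), "individuals\n")
  invisible(x)
}

#' Uniform subsample of a k-mer table
#'
#' @param t a `kmer_table`.
#' @param n number of k-mers to sample without replacement (if `n` exceeds
#'   the table size the full table is returned with a warning).
#' @param seed integer seed.
#' @return a `kmer_table`.
#' @export
sample_kmer_table <- function(t, n = 1000000, seed = 1L) {
  nk <- length(t$kmers)
  if (n >= nk) {
    if (n > nk) warning("requested more k-mers than available; returning all")
    return(t)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(nk, n))
  t$kmers <- t$kmers[idx]
  t$presence <- t$presence[idx, , drop = FALSE]
  t$filter_state$sampled_to <- n
  t$filter_state$sample_seed <- seed
  t
}

#' Within-group k-mer Jaccard dissimilarities
#'
#' Splits the table into `n_tables` independent random subtables of
#' `table_size` k-mers and, within each, computes the Jaccard dissimilarity
#' `1 - |A intersect B| / |A union B|` for every within-group individual
#' pair, over the k-mers present in at least one of the pair.
#'
#' @param t a `kmer_table`.
#' @param groups named list of character vectors of individual ids (each of
#'   size >= 2), or a factor/vector of group labels per individual.
#' @param n_tables number of random subtables.
#' @param table_size k-mers per subtable.
#' @param seed integer seed.
#' @return data.frame (table, group, ind1, ind2, dissimilarity; `NA` where
#'   the pair union is empty) with a `group_means` attribute.
#' @export
jaccard_dissimilarity <- function(t, groups, n_tables = 100,
                                  table_size = 10000, seed = 1L) {
  ids <- colnames(t$presence)
  if (!is.list(groups)) {
    if (length(groups) != length(ids)) stop("one group label per individual")
    groups <- split(ids, as.character(groups))
  }
  for (gname in names(groups)) {
    if (length(groups[[gname]]) < 2)
      stop("group '", gname, "' has fewer than 2 individuals")
    if (!all(groups[[gname]] %in% ids))
      stop("group '", gname, "' names unknown individuals")
  }
  if (!is.null(seed)) set.seed(seed)
  nk <- length(t$kmers)
  sz <- min(table_size, nk)
  rows <- list()
  for (tab in seq_len(n_tables)) {
    sub <- t$presence[sample.int(nk, sz), , drop = FALSE]
    M <- matrix(as.numeric(sub), nrow = sz)
    inter <- crossprod(M)
    tot <- colSums(M)
    uni <- outer(tot, tot, "+") - inter
    diss <- 1 - inter / uni  # NaN where union empty
    for (gname in names(groups)) {
      gi <- match(groups[[gname]], ids)
      prs <- utils::combn(gi, 2)
      rows[[length(rows) + 1]] <- data.frame(
        table = tab, group = gname,
        ind1 = ids[prs[1, ]], ind2 = ids[prs[2, ]],
        dissimilarity = ifelse(is.nan(diss[cbind(prs[1, ], prs[2, ])]),
                               NA_real_, diss[cbind(prs[1, ], prs[2, ])]))
    }
  }
  out <- do.call(rbind, rows)
  gm <- tapply(out$dissimilarity, out$group, mean, na.rm = TRUE)
  attr(out, "group_means") <- gm
  out
}

#' Numeric k-mer matrix for PCA
#'
#' @param t a `kmer_table`.
#' @return individuals x k-mers 0/1 numeric matrix (stable column order).
#' @export
kmer_matrix_for_pca <- function(t) {
  if (!length(t$kmers)) stop("empty k-mer table")
  M <- t(matrix(as.numeric(t$presence), nrow = length(t$kmers)))
  rownames(M) <- colnames(t$presence)
  colnames(M) <- t$kmers
  M
}
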