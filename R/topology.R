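#' Neighbour-joining trees in sliding windows
#'
#' For each window with at least `min_snps_per_window` SNPs, computes the
#' pairwise genotype p-distance (mean absolute code difference / 2 over
#' pairwise-complete loci) between individuals and builds an NJ tree
#' (negative branch lengths clipped to zero). Windows with fewer than four
#' usable tips are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param w a [window_spec()].
#' @param min_snps_per_window minimum SNPs per window (default 20).
#' @return list of `window_tree` objects: each a list with `tree`
#'   (an `ape::phylo`) and `window` (chrom, start, end, n_snps).
#' @export
window_nj_trees <- function(g, w = window_spec(), min_snps_per_window = 20) {
  if (n_loci(g) == 0) stop("empty genotype matrix")
  trees <- list()
  for (ch in unique(g$chrom)) {
    on_ch <- which(g$chrom == ch)
    wins <- make_windows(max(g$pos[on_ch]), w)
    for (k in seq_len(nrow(wins))) {
      in_win <- on_ch[g$pos[on_ch] >= wins$start[k] & g$pos[on_ch] <= wins$end[k]]
      if (length(in_win) < min_snps_per_window) next
      sub <- g$genotypes[, in_win, drop = FALSE]
      usable <- rowSums(!is.na(sub)) > 0
      if (sum(usable) < 4) next
      sub <- sub[usable, , drop = FALSE]
      n <- nrow(sub)
      D <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        dif <- abs(sub[i, ] - sub[j, ])
        D[i, j] <- D[j, i] <- mean(dif, na.rm = TRUE) / 2
      }
      D[is.nan(D)] <- 0
      tr <- ape::nj(D)
      tr$edge.length[tr$edge.length < 0] <- 0
      trees[[length(trees) + 1]] <- structure(
        list(tree = tr,
             window = data.frame(chrom = ch, start = wins$start[k],
                                 end = wins$end[k],
                                 n_snps = length(in_win))),
        class = "window_tree")
    }
  }
  trees
}

# sum of two distance sub-matrices expanded over the 4-way combination grid:
# result[i1,i2,i3,i4] = M12[i_{dims12}] + M34[i_{dims34}]
comb_sum <- function(M12, M34, dims, dims12, dims34) {
  expand <- function(M, axes) {
    rest <- setdiff(1:4, axes)
    a <- array(M, c(dim(M), dims[rest]))
    aperm(a, order(c(axes, rest)))
  }
  expand(M12, dims12) + expand(M34, dims34)
}

#' Topology weights of window trees over four groups (Twisst)
#'
#' For each window tree and each combination of one tip per group, the
#' induced unrooted quartet topology is determined from the tree structure
#' (topological distances with unit branch lengths); the weight of a
#' topology is the fraction of combinations inducing it. Combinations are
#' enumerated exhaustively when their count does not exceed
#' `max_subsamples`, and sampled uniformly otherwise.
#'
#' The three topologies are reported in the fixed order
#' `T1 = (g1,g2 | g3,g4)`, `T2 = (g1,g3 | g2,g4)`, `T3 = (g1,g4 | g2,g3)`
#' where `g1..g4` are the groups in the order given.
#'
#' @param trees list of `window_tree` objects from [window_nj_trees()], or a
#'   list of `ape::phylo` trees.
#' @param group_map named list of four character vectors mapping group name
#'   to tip labels.
#' @param method `"auto"`, `"exact"`, or `"sample"`.
#' @param max_subsamples enumeration cutoff / number of sampled combinations.
#' @param seed seed for sampled mode.
#' @return object of class `topology_weights`: list with `weights` (windows
#'   x 3 matrix), `topologies` (newick of the three pairings), `mean_weights`
#'   (genome-wide means), `max_weight_fraction` (fraction of windows whose
#'   max-weight topology is each pairing), `method`, and `excluded` windows.
#' @export
twisst_weights <- function(trees, group_map, method = c("auto", "exact", "sample"),
                           max_subsamples = 100000, seed = 1L) {
  method <- match.arg(method)
  if (length(group_map) != 4 || is.null(names(group_map)))
    stop("group_map must be a named list of exactly 4 groups")
  if (!is.null(seed)) set.seed(seed)
  gn <- names(group_map)
  W <- matrix(NA_real_, length(trees), 3)
  excluded <- logical(length(trees))
  used_method <- character(length(trees))
  for (ti in seq_along(trees)) {
    tr <- if (inherits(trees[[ti]], "window_tree")) trees[[ti]]$tree else trees[[ti]]
    tips <- lapply(group_map, function(v) intersect(v, tr$tip.label))
    if (any(vapply(tips, length, integer(1)) == 0)) {
      excluded[ti] <- TRUE
      next
    }
    trt <- tr
    trt$edge.length <- rep(1, nrow(trt$edge))
    Dt <- ape::cophenetic.phylo(trt)
    iA <- match(tips[[1]], rownames(Dt)); iB <- match(tips[[2]], rownames(Dt))
    iC <- match(tips[[3]], rownames(Dt)); iD <- match(tips[[4]], rownames(Dt))
    nA <- length(iA); nB <- length(iB); nC <- length(iC); nD <- length(iD)
    n_comb <- as.double(nA) * nB * nC * nD
    if (method == "exact" || (method == "auto" && n_comb <= max_subsamples)) {
      dims <- c(nA, nB, nC, nD)
      s1 <- comb_sum(Dt[iA, iB, drop = FALSE], Dt[iC, iD, drop = FALSE],
                     dims, c(1, 2), c(3, 4))
      s2 <- comb_sum(Dt[iA, iC, drop = FALSE], Dt[iB, iD, drop = FALSE],
                     dims, c(1, 3), c(2, 4))
      s3 <- comb_sum(Dt[iA, iD, drop = FALSE], Dt[iB, iC, drop = FALSE],
                     dims, c(1, 4), c(2, 3))
      w1 <- sum(s1 < s2 & s1 < s3)
      w2 <- sum(s2 < s1 & s2 < s3)
      w3 <- sum(s3 < s1 & s3 < s2)
      unresolved <- n_comb - w1 - w2 - w3
      tot <- w1 + w2 + w3
      W[ti, ] <- if (tot > 0) c(w1, w2, w3) / tot else rep(1 / 3, 3)
      used_method[ti] <- "exact"
    } else {
      m <- max_subsamples
      a <- iA[sample.int(nA, m, replace = TRUE)]
      b <- iB[sample.int(nB, m, replace = TRUE)]
      cc <- iC[sample.int(nC, m, replace = TRUE)]
      d <- iD[sample.int(nD, m, replace = TRUE)]
      s1 <- Dt[cbind(a, b)] + Dt[cbind(cc, d)]
      s2 <- Dt[cbind(a, cc)] + Dt[cbind(b, d)]
      s3 <- Dt[cbind(a, d)] + Dt[cbind(b, cc)]
      w1 <- sum(s1 < s2 & s1 < s3)
      w2 <- sum(s2 < s1 & s2 < s3)
      w3 <- sum(s3 < s1 & s3 < s2)
      tot <- w1 + w2 + w3
      W[ti, ] <- if (tot > 0) c(w1, w2, w3) / tot else rep(1 / 3, 3)
      used_method[ti] <- "sample"
    }
  }
  topo_names <- c(sprintf("((%s,%s),(%s,%s))", gn[1], gn[2], gn[3], gn[4]),
                  sprintf("((%s,%s),(%s,%s))", gn[1], gn[3], gn[2], gn[4]),
                  sprintf("((%s,%s),(%s,%s))", gn[1], gn[4], gn[2], gn[3]))
  colnames(W) <- topo_names
  ok <- !excluded
  maxw <- apply(W[ok, , drop = FALSE], 1, which.max)
  structure(list(weights = W, topologies = topo_names,
                 mean_weights = colMeans(W[ok, , drop = FALSE]),
                 max_weight_fraction = stats::setNames(
                   tabulate(maxw, 3) / sum(ok), topo_names),
                 method = used_method, excluded = excluded),
            class = "topology_weights")
}

#' @export
print.topology_weights <- function(x, ...) {
  cat("topology_weights:", nrow(x$weights), "windows,",
      sum(x$excluded), "excluded\n")
  m <- rbind(mean_weight = x$mean_weights,
             max_weight_fraction = x$max_weight_fraction)
  print(round(m, 4))
  invisible(x)
}

#' Allele-frequency covariance between populations
#'
#' Per-SNP sample allele frequencies are computed per population, centred by
#' the across-population mean, and their covariance across SNPs is returned
#' with a sampling-error correction `mean(p(1-p)/(2n))` subtracted from the
#' diagonal.
#'
#' @param g a [genotype_matrix()] with labels.
#' @param pops populations to include (>= 2).
#' @return pops x pops covariance matrix W (symmetric).
#' @export
allele_freq_covariance <- function(g, pops = NULL) {
  fm <- pop_freq_matrix(g, pops)
  cov_from_freqs(fm$freq, fm$nobs)
}

# per-population allele frequencies and haploid observation counts per SNP
pop_freq_matrix <- function(g, pops = NULL) {
  if (is.null(pops)) pops <- unique(g$pop_labels)
  if (length(pops) < 2) stop("need at least two populations")
  P <- length(pops)
  freq <- matrix(NA_real_, n_loci(g), P, dimnames = list(NULL, pops))
  nobs <- freq
  for (j in seq_len(P)) {
    ind <- pop_index(g, pops[j])
    sub <- g$genotypes[ind, , drop = FALSE]
    n_al <- 2 * colSums(!is.na(sub))
    if (all(n_al == 0)) stop("population ", pops[j], " has no genotyped sites")
    freq[, j] <- ifelse(n_al > 0, colSums(sub, na.rm = TRUE) / n_al, NA)
    nobs[, j] <- n_al
  }
  keep <- stats::complete.cases(freq)
  if (sum(keep) < 2) stop("fewer than two SNPs typed in all populations")
  list(freq = freq[keep, , drop = FALSE], nobs = nobs[keep, , drop = FALSE])
}

cov_from_freqs <- function(f, no) {
  dev <- f - rowMeans(f)
  W <- crossprod(dev) / (nrow(dev) - 1)
  corr <- colMeans(f * (1 - f) / no)
  diag(W) <- diag(W) - corr
  W
}

# design matrix of a rooted drift tree: one column per edge (excluding any
# edge spanning all tips), rows = vec of the pops x pops matrix; entry 1
# where both populations descend from the edge. Columns made collinear by
# the centering (e.g. the two root edges) are merged; edge_col maps each
# tree edge to its design column (NA for skipped edges).
drift_design <- function(tree, pops, centered = TRUE) {
  P <- length(pops)
  A <- diag(P) - matrix(1 / P, P, P)
  n_tip <- length(tree$tip.label)
  cols <- list()
  keys <- character(0)
  edge_col <- rep(NA_integer_, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    below <- if (node <= n_tip) tree$tip.label[node]
             else ape::extract.clade(tree, node)$tip.label
    u <- as.numeric(pops %in% below)
    if (sum(u) == P) next
    V <- tcrossprod(u)
    if (centered) V <- A %*% V %*% A
    key <- paste(round(as.vector(V), 10), collapse = ",")
    hit <- match(key, keys)
    if (is.na(hit)) {
      cols[[length(cols) + 1]] <- as.vector(V)
      keys <- c(keys, key)
      edge_col[e] <- length(cols)
    } else edge_col[e] <- hit
  }
  list(X = do.call(cbind, cols), edge_col = edge_col)
}

#' Fit a drift (allele-frequency covariance) population tree
#'
#' Searches rooted tree topologies exhaustively (up to 6 populations) and
#' fits branch lengths by nonnegative least squares under the drift model in
#' which the covariance of two populations equals the branch length shared
#' on their root path, pushed through the same across-population centering
#' that the empirical covariance estimator applies. The best topology is the
#' one with the smallest residual sum of squares (ties broken by newick
#' string order).
#'
#' @param W covariance matrix from [allele_freq_covariance()].
#' @param root_label optional outgroup population used to root the reported
#'   tree (topology search is unaffected).
#' @param centered model the across-population centering of the empirical
#'   estimator (set `FALSE` if `W` is an uncentred drift matrix).
#' @return object of class `population_tree`: `tree` (ape::phylo with drift
#'   branch lengths), `W`, `W_fit`, `residuals`, `variance_explained`, `rss`.
#' @export
fit_population_tree <- function(W, root_label = NULL, centered = TRUE) {
  W <- as.matrix(W)
  pops <- rownames(W)
  if (is.null(pops)) stop("W must have population names as dimnames")
  P <- length(pops)
  if (P > 6) stop("exhaustive topology search supports at most 6 populations")
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    # the diagonal sampling correction routinely pushes the (centred, hence
    # singular) estimate slightly below PSD; warn only on a substantial deficit
    if (min(ev) < -0.25 * max(abs(ev)))
      warning("W is far from positive semidefinite; projecting to nearest PSD")
    ee <- eigen(W, symmetric = TRUE)
    W <- ee$vectors %*% diag(pmax(ee$values, 0)) %*% t(ee$vectors)
    dimnames(W) <- list(pops, pops)
  }
  topos <- phangorn::allTrees(P, rooted = TRUE, tip.label = pops)
  y <- as.vector(W)
  best <- NULL
  for (topo_i in seq_along(topos)) {
    tr <- topos[[topo_i]]
    des <- drift_design(tr, pops, centered = centered)
    fit <- pracma::lsqnonneg(des$X, y)
    rss <- sum((y - des$X %*% fit$x)^2)
    nwk <- ape::write.tree(tr)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && nwk < best$newick)) {
      best <- list(tree = tr, rss = rss, b = fit$x, design = des, newick = nwk)
    }
  }
  W_fit <- matrix(best$design$X %*% best$b, P, P, dimnames = list(pops, pops))
  tree <- best$tree
  tree$edge.length <- rep(0, nrow(tree$edge))
  # assign each merged design column's length to its first carrying edge
  assigned <- logical(length(best$b))
  for (e in seq_len(nrow(tree$edge))) {
    cl <- best$design$edge_col[e]
    if (!is.na(cl) && !assigned[cl]) {
      tree$edge.length[e] <- best$b[cl]
      assigned[cl] <- TRUE
    }
  }
  sst <- sum((W - mean(W))^2)
  ve <- if (sst > 0) 1 - best$rss / sst else NA_real_
  if (!is.null(root_label)) {
    tree <- tryCatch(ape::root(tree, outgroup = root_label,
                               resolve.root = TRUE),
                     error = function(e) tree)
  }
  structure(list(tree = tree, W = W, W_fit = W_fit,
                 residuals = W - W_fit, variance_explained = ve,
                 rss = best$rss),
            class = "population_tree")
}

#' @export
print.population_tree <- function(x, ...) {
  cat("population_tree:", ape::write.tree(x$tree), "\n")
  cat(sprintf("  variance explained: %.5f\n", x$variance_explained))
  invisible(x)
}

#' Block bootstrap of the population tree
#'
#' Resamples consecutive SNP blocks with replacement (accounting for
#' linkage), refits the drift tree per replicate, and reports the
#' majority-rule consensus and per-split support.
#'
#' @param g a [genotype_matrix()] with labels.
#' @param pops populations to include.
#' @param block_size SNPs per block (500-1000 typical).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return list with `consensus` (ape::phylo), `support` (fraction of
#'   replicates containing each consensus split), and `trees`.
#' @export
bootstrap_tree <- function(g, pops = NULL, block_size = 500, n_boot = 100,
                           seed = 1L) {
  if (is.null(pops)) pops <- unique(g$pop_labels)
  L <- n_loci(g)
  n_blocks <- L %/% block_size
  if (n_blocks < 2) stop("not enough SNPs for two blocks; reduce block_size")
  if (!is.null(seed)) set.seed(seed)
  fm <- pop_freq_matrix(g, pops)
  trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    blocks <- sample.int(n_blocks, n_blocks, replace = TRUE)
    idx <- unlist(lapply(blocks, function(k)
      ((k - 1) * block_size + 1):(k * block_size)))
    idx <- idx[idx <= nrow(fm$freq)]
    W <- cov_from_freqs(fm$freq[idx, , drop = FALSE],
                        fm$nobs[idx, , drop = FALSE])
    trees[[b]] <- fit_population_tree(W)$tree
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  supp <- ape::prop.clades(cons, trees, rooted = TRUE) / n_boot
  list(consensus = cons, support = supp, trees = trees)
}
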