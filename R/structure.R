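#' Principal component analysis with mean imputation
#'
#' Missing entries are imputed to the column mean before the decomposition
#' (centering is applied by default; scaling to unit variance is optional and
#' skips zero-variance columns).
#'
#' @param m numeric matrix, individuals x variables.
#' @param center center columns.
#' @param scale. scale columns to unit variance.
#' @return list with `scores`, `loadings`, `explained` (variance fractions,
#'   descending, summing to 1 over returned components).
#' @export
pca <- function(m, center = TRUE, scale. = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least two rows")
  if (anyNA(m)) {
    cm <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- cm[idx[, 2]]
  }
  v <- apply(m, 2, stats::var)
  if (all(v == 0)) stop("degenerate input: all columns constant")
  if (scale.) m <- m[, v > 0, drop = FALSE]
  p <- stats::prcomp(m, center = center, scale. = scale.)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, explained = expl)
}

# Euclidean projection of rows onto the probability simplex
project_simplex <- function(Q) {
  if (ncol(Q) == 1) return(matrix(1, nrow(Q), 1))
  t(apply(Q, 1, function(y) {
    u <- sort(y, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(y - theta, 0)
  }))
}

snmf_objective <- function(X, Q, F, obs) {
  R <- X - Q %*% F
  sum(R[obs]^2, na.rm = TRUE)
}

# binomial cross-entropy of genotype codes g (0..2) given frequencies p
genotype_cross_entropy <- function(gcode, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- ifelse(gcode == 0L, 2 * log(1 - p),
        ifelse(gcode == 2L, 2 * log(p), log(2) + log(p) + log(1 - p)))
  -mean(ll)
}

snmf_single_run <- function(X, K, masked_fraction, alpha, max_iter, tol) {
  n <- nrow(X); L <- ncol(X)
  obs <- !is.na(X)
  obs_idx <- which(obs)
  n_mask <- max(1L, round(masked_fraction * length(obs_idx)))
  mask_idx <- sample(obs_idx, n_mask)
  fit_obs <- obs
  fit_obs[mask_idx] <- FALSE

  Q <- matrix(stats::rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  F <- matrix(stats::runif(K * L), K, L)
  Ximp <- X
  Ximp[!fit_obs] <- mean(X[fit_obs])

  obj <- snmf_objective(Ximp, Q, F, fit_obs)
  traj <- obj
  ridge <- 1e-8 * diag(K)
  for (it in seq_len(max_iter)) {
    Ximp[!fit_obs] <- (Q %*% F)[!fit_obs]
    # F update: ridge least squares clamped to [0,1], damped to keep the
    # observed-cell objective non-increasing
    Fcand <- pmin(pmax(solve(crossprod(Q) + ridge, crossprod(Q, Ximp)), 0), 1)
    for (half in 1:20) {
      if (snmf_objective(Ximp, Q, Fcand, fit_obs) <= obj + 1e-12) break
      Fcand <- (Fcand + F) / 2
    }
    F <- Fcand
    obj <- snmf_objective(Ximp, Q, F, fit_obs)
    # Q update: least squares rows projected onto the simplex, damped
    Qls <- t(solve(tcrossprod(F) + ridge + alpha * diag(K),
                   F %*% t(Ximp)))
    Qcand <- project_simplex(Qls)
    for (half in 1:20) {
      if (snmf_objective(Ximp, Qcand, F, fit_obs) <= obj + 1e-12) break
      Qcand <- project_simplex((Qcand + Q) / 2)
    }
    Q <- Qcand
    new_obj <- snmf_objective(Ximp, Q, F, fit_obs)
    traj <- c(traj, new_obj)
    if (obj > 0 && abs(obj - new_obj) / obj < tol) { obj <- new_obj; break }
    obj <- new_obj
  }
  P <- Q %*% F
  ce <- genotype_cross_entropy(round(2 * X[mask_idx]), P[mask_idx])
  list(Q = Q, F = F, cross_entropy = ce, objective = obj,
       objective_trajectory = traj)
}

#' sNMF-style ancestry estimation
#'
#' Factorizes the genotype matrix (codes 0/1/2 rescaled to [0,1]) as Q x F
#' with Q rows on the probability simplex and F in [0,1], by alternating
#' damped least squares with simplex projection. Missing genotypes are
#' excluded from the residuals (EM-style imputation inside the solver). Per
#' run, a random fraction of observed genotype entries is masked before
#' fitting and the binomial cross-entropy of their predictions is the run's
#' held-out criterion; the best of `n_runs` is returned.
#'
#' @param g a [genotype_matrix()] (ideally MAF-filtered) or a numeric matrix
#'   already scaled to [0,1].
#' @param K number of ancestral clusters (>= 1, <= individuals).
#' @param n_runs independent random restarts.
#' @param masked_fraction fraction of entries held out per run.
#' @param seed integer seed.
#' @param alpha ridge ("sparsity") regularization on Q (default 0).
#' @param max_iter,tol convergence controls.
#' @return object of class `ancestry_result`: `Q`, `F`, `K`,
#'   `cross_entropy` (all runs), `best_run`, objective trajectory of the
#'   best run, and `seed`.
#' @export
snmf_ancestry <- function(g, K, n_runs = 10, masked_fraction = 0.05,
                          seed = 1L, alpha = 0, max_iter = 200, tol = 1e-6) {
  X <- if (inherits(g, "genotype_matrix")) g$genotypes / 2 else as.matrix(g)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(X)) stop("K cannot exceed the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r)
    snmf_single_run(X, K, masked_fraction, alpha, max_iter, tol))
  ces <- vapply(runs, `[[`, numeric(1), "cross_entropy")
  best <- which.min(ces)
  res <- runs[[best]]
  structure(list(Q = structure(res$Q, dimnames = list(rownames(X), NULL)),
                 F = res$F, K = K, cross_entropy = ces, best_run = best,
                 objective_trajectory = res$objective_trajectory,
                 seed = seed),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("ancestry_result: K =", x$K, ",", nrow(x$Q), "individuals\n")
  cat(sprintf("  best run %d of %d, cross-entropy %.4f\n", x$best_run,
              length(x$cross_entropy), min(x$cross_entropy)))
  invisible(x)
}

#' Cross-validated choice of the number of clusters K
#'
#' Runs [snmf_ancestry()] over a range of K and selects the K with the
#' smallest mean held-out cross-entropy (ties resolved toward smaller K).
#'
#' @param g as in [snmf_ancestry()].
#' @param K_range integer vector of K values (default 2..14).
#' @param n_runs runs per K.
#' @param seed integer seed.
#' @param ... passed to [snmf_ancestry()].
#' @return list with `table` (K, mean/min cross-entropy), `best_K`, and the
#'   per-K `ancestry_result`s.
#' @export
choose_K <- function(g, K_range = 2:14, n_runs = 10, seed = 1L, ...) {
  fits <- list()
  tab <- data.frame(K = K_range, mean_cross_entropy = NA_real_,
                    min_cross_entropy = NA_real_)
  for (i in seq_along(K_range)) {
    fit <- snmf_ancestry(g, K_range[i], n_runs = n_runs,
                         seed = seed + i - 1L, ...)
    fits[[i]] <- fit
    tab$mean_cross_entropy[i] <- mean(fit$cross_entropy)
    tab$min_cross_entropy[i] <- min(fit$cross_entropy)
  }
  best <- K_range[which.min(tab$mean_cross_entropy)]
  list(table = tab, best_K = best, fits = fits)
}

#' Assign individuals to clusters from ancestry coefficients
#'
#' @param q an `ancestry_result` (or a Q matrix).
#' @param threshold minimum ancestry coefficient for assignment; individuals
#'   below it are labelled `"admixed"`.
#' @return character vector of cluster ids (`"cluster_k"`) or `"admixed"`.
#' @export
assign_clusters <- function(q, threshold = 0.6) {
  Q <- if (inherits(q, "ancestry_result")) q$Q else as.matrix(q)
  out <- apply(Q, 1, function(row) {
    k <- which.max(row)
    if (row[k] >= threshold) paste0("cluster_", k) else "admixed"
  })
  stats::setNames(out, rownames(Q))
}
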