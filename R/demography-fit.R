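#' Parameter prior specification
#'
#' One row per parameter: family (`uniform` or `loguniform`), lower and
#' upper bound. Priors double as the optimizer's initial search ranges.
#'
#' @param ... named `c(lower, upper)` pairs, or a single data.frame.
#' @param family families per parameter (recycled; default `"loguniform"`).
#' @return data.frame of class `prior_spec` (param, family, lower, upper).
#' @export
prior_spec <- function(..., family = "loguniform") {
  args <- list(...)
  if (length(args) == 1 && is.data.frame(args[[1]])) {
    out <- args[[1]]
  } else {
    out <- data.frame(param = names(args),
                      family = rep_len(family, length(args)),
                      lower = vapply(args, `[`, numeric(1), 1),
                      upper = vapply(args, `[`, numeric(1), 2),
                      row.names = NULL)
  }
  if (any(out$lower >= out$upper)) stop("prior lower must be < upper")
  if (any(out$family == "loguniform" & out$lower <= 0))
    stop("log-uniform priors require lower > 0")
  class(out) <- c("prior_spec", "data.frame")
  out
}

draw_from_ranges <- function(ranges, n) {
  # ranges: data.frame param/family/lower/upper
  out <- matrix(NA_real_, n, nrow(ranges),
                dimnames = list(NULL, ranges$param))
  for (i in seq_len(nrow(ranges))) {
    if (ranges$family[i] == "loguniform") {
      out[, i] <- exp(stats::runif(n, log(ranges$lower[i]),
                                   log(ranges$upper[i])))
    } else {
      out[, i] <- stats::runif(n, ranges$lower[i], ranges$upper[i])
    }
  }
  out
}

shrink_ranges <- function(ranges, center, factor, priors) {
  for (i in seq_len(nrow(ranges))) {
    p <- ranges$param[i]
    if (ranges$family[i] == "loguniform") {
      hw <- (log(ranges$upper[i]) - log(ranges$lower[i])) / 2 * factor
      lo <- exp(log(center[[p]]) - hw); hi <- exp(log(center[[p]]) + hw)
    } else {
      hw <- (ranges$upper[i] - ranges$lower[i]) / 2 * factor
      lo <- center[[p]] - hw; hi <- center[[p]] + hw
    }
    ranges$lower[i] <- max(lo, priors$lower[i])
    ranges$upper[i] <- min(hi, priors$upper[i])
    if (ranges$lower[i] >= ranges$upper[i]) {
      ranges$lower[i] <- priors$lower[i]
      ranges$upper[i] <- priors$upper[i]
    }
  }
  ranges
}

#' Demographic model templates
#'
#' A model template binds a parameter vector to a concrete
#' [demographic_model()]. `tmpl_divergence_pair()` is the two-population
#' divergence model for a cultivated/wild pair: the cultivated lineage
#' splits from the wild one `T_DIV` generations ago and (optionally) passes
#' through a bottleneck of size `N_BOT` from the split until
#' `T_BEND = B_FRAC * T_DIV`, after which it expands to its present size
#' `N_C`. The wild lineage has present size `N_W` and ancestral size
#' `N_ANC` above the split.
#'
#' @param bottleneck include the post-divergence bottleneck.
#' @param pop_names names for the (cultivated, wild) populations.
#' @param mu mutation rate per bp per generation.
#' @return object of class `model_template`: `name`, `params`, `build(par)`.
#' @export
tmpl_divergence_pair <- function(bottleneck = TRUE,
                                 pop_names = c("cultivated", "wild"),
                                 mu = 6.5e-9) {
  params <- c("N_C", "N_W", "N_ANC", "T_DIV")
  if (bottleneck) params <- c(params, "N_BOT", "B_FRAC")
  build <- function(par) {
    par <- as.list(par)
    ev <- list(event_split(par$T_DIV, pop_names[1], pop_names[2]),
               event_size_change(par$T_DIV, pop_names[2], par$N_ANC))
    if (bottleneck) {
      t_bend <- par$B_FRAC * par$T_DIV
      ev <- c(list(event_bottleneck(t_bend, par$T_DIV, pop_names[1],
                                    par$N_BOT)), ev)
    }
    demographic_model(pop_names, c(par$N_C, par$N_W), ev, mu = mu)
  }
  structure(list(name = if (bottleneck) "pair_divergence_bottleneck"
                 else "pair_divergence_constant",
                 params = params, build = build, pop_names = pop_names),
            class = "model_template")
}

#' Default priors for the pair divergence templates
#'
#' Log-uniform on sizes, log-uniform on the divergence time, uniform on the
#' bottleneck-end fraction.
#'
#' @param template a `model_template` from [tmpl_divergence_pair()].
#' @return a [prior_spec()].
#' @export
default_pair_priors <- function(template) {
  pr <- list(N_C = c(1e3, 1e6), N_W = c(1e3, 1e6), N_ANC = c(1e3, 1e6),
             T_DIV = c(1e3, 2e5), N_BOT = c(1e2, 1e6))
  rows <- lapply(template$params, function(p) {
    if (p == "B_FRAC")
      data.frame(param = p, family = "uniform", lower = 0.02, upper = 0.9)
    else
      data.frame(param = p, family = "loguniform", lower = pr[[p]][1],
                 upper = pr[[p]][2])
  })
  prior_spec(do.call(rbind, rows))
}

#' Four-population topology templates
#'
#' Generic 4-population divergence scenarios over the two cultivated and two
#' wild taxa: the three balanced pairings plus three ladder variants, each
#' with per-population sizes, within-group divergence times and a root
#' ancestral size, optionally with post-divergence bottlenecks on the two
#' cultivated lineages. Parameters: `N_1..N_4`, `N_ANC`, `T_A` (first
#' grouping), `T_B` (second grouping), `T_ROOT`, plus `N_BOT1`, `N_BOT2`,
#' `B_FRAC` when `bottleneck = TRUE`.
#'
#' @param pops four population names, cultivated first within each pair.
#' @param bottleneck add bottlenecks on `pops[1]` and `pops[3]`.
#' @return list of six `model_template`s.
#' @export
four_pop_templates <- function(pops = c("exilis", "longiflora", "iburua", "ternata"),
                               bottleneck = FALSE) {
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  ladders <- list(c(1, 2, 3, 4), c(3, 4, 1, 2), c(1, 3, 2, 4))
  mk <- function(ord, ladder) {
    a <- pops[ord[1]]; b <- pops[ord[2]]; cc <- pops[ord[3]]; d <- pops[ord[4]]
    nm <- if (ladder) sprintf("ladder_%s.%s_%s_%s", a, b, cc, d)
          else sprintf("pairs_%s.%s_%s.%s", a, b, cc, d)
    params <- c(paste0("N_", pops), "N_ANC", "T_A", "T_B", "T_ROOT")
    if (bottleneck) params <- c(params, "N_BOT1", "N_BOT2", "B_FRAC")
    build <- function(par) {
      par <- as.list(par)
      if (par$T_ROOT <= max(par$T_A, par$T_B))
        stop("T_ROOT must exceed T_A and T_B")
      ev <- list(event_split(par$T_A, a, b),
                 event_size_change(par$T_A, b, par$N_ANC))
      if (ladder) {
        if (par$T_B <= par$T_A) stop("ladder requires T_B > T_A")
        ev <- c(ev, list(event_split(par$T_B, cc, b),
                         event_size_change(par$T_B, b, par$N_ANC),
                         event_split(par$T_ROOT, d, b)))
      } else {
        ev <- c(ev, list(event_split(par$T_B, cc, d),
                         event_size_change(par$T_B, d, par$N_ANC),
                         event_split(par$T_ROOT, d, b)))
      }
      if (bottleneck) {
        for (cp in intersect(c(pops[1], pops[3]), c(a, cc))) {
          tsp <- if (cp == a) par$T_A else par$T_B
          nb <- if (cp == pops[1]) par$N_BOT1 else par$N_BOT2
          ev <- c(ev, list(event_bottleneck(par$B_FRAC * tsp, tsp, cp, nb)))
        }
      }
      demographic_model(pops, unlist(par[paste0("N_", pops)]), ev)
    }
    structure(list(name = nm, params = params, build = build,
                   pop_names = pops), class = "model_template")
  }
  c(lapply(pairings, mk, ladder = FALSE), lapply(ladders, mk, ladder = TRUE))
}

#' Monte-Carlo expected folded joint SFS
#'
#' Estimates, for each requested population pair, the expected proportions
#' of segregating sites in each folded joint frequency class, by simulating
#' independent genealogies and accumulating branch lengths weighted by each
#' branch's descendant counts (branch-length weighting has lower variance
#' than literal mutation dropping; `method = "mutation"` drops a single
#' branch-sampled mutation per genealogy instead).
#'
#' @param model a [demographic_model()].
#' @param samples named vector of diploid counts per population.
#' @param pairs list of 2-vectors of population names.
#' @param n_sims genealogies per pair.
#' @param seed integer seed.
#' @param method `"branch"` or `"mutation"`.
#' @return list per pair of folded expected-proportion matrices (class
#'   `joint_folded_sfs` shape; proportions over polymorphic classes sum
#'   to 1).
#' @export
expected_sfs <- function(model, samples, pairs, n_sims = 5000, seed = NULL,
                         method = c("branch", "mutation")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(pairs))
  names(out) <- vapply(pairs, paste, character(1), collapse = "_")
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    sub_samples <- samples[pr]
    if (method == "branch") {
      res <- run_engine(model, sub_samples, n_sims, want_sfs = TRUE,
                        focal = pr)
      Mw <- res$sfs_weights
    } else {
      res <- run_engine(model, sub_samples, n_sims, want_sites = TRUE,
                        one_snp_per_locus = TRUE)
      lay <- hap_layout(model, sub_samples)
      H <- matrix(as.integer(res$haplotypes), nrow = nrow(res$haplotypes))
      dA <- colSums(H[lay$pop_of_hap == pr[1], , drop = FALSE])
      dB <- colSums(H[lay$pop_of_hap == pr[2], , drop = FALSE])
      nA <- sum(lay$pop_of_hap == pr[1]); nB <- sum(lay$pop_of_hap == pr[2])
      Mw <- matrix(0, nA + 1, nB + 1)
      for (s in seq_along(dA)) Mw[dA[s] + 1, dB[s] + 1] <- Mw[dA[s] + 1, dB[s] + 1] + 1
    }
    Fm <- fold_joint(Mw)
    Fm[1, 1] <- 0
    tot <- sum(Fm)
    if (tot <= 0) stop("degenerate model: no polymorphic mass simulated")
    out[[k]] <- structure(Fm / tot, class = "joint_folded_sfs",
                          n_hap_A = nrow(Fm) - 1L, n_hap_B = ncol(Fm) - 1L,
                          n_sites = NA_integer_,
                          mean_tree_length = if (method == "branch")
                            sum(Mw) / n_sims else NA_real_)
  }
  out
}

#' Composite log-likelihood of observed folded joint SFS
#'
#' `lnL = sum over pairs, sum over polymorphic classes of
#' obs_count * ln(expected proportion)`, with expected proportions floored
#' at `eps`. The monomorphic class is excluded.
#'
#' @param obs list (or single) of observed `joint_folded_sfs` count matrices.
#' @param expected list (or single) of expected proportion matrices.
#' @param eps probability floor.
#' @param pool_below classes with observed count below this are pooled into
#'   one aggregate class (with summed observed counts and summed expected
#'   proportions) before the log-likelihood is taken; 0 disables pooling.
#'   Pooling by observed count is identical across parameter values, so it
#'   stabilises Monte-Carlo expected spectra without biasing comparisons.
#' @return the composite log-likelihood (scalar).
#' @export
composite_log_likelihood <- function(obs, expected, eps = 1e-12,
                                     pool_below = 0) {
  if (inherits(obs, "joint_folded_sfs")) obs <- list(obs)
  if (inherits(expected, "joint_folded_sfs")) expected <- list(expected)
  if (length(obs) != length(expected)) stop("obs/expected length mismatch")
  lnl <- 0
  for (k in seq_along(obs)) {
    O <- unclass(obs[[k]]); E <- unclass(expected[[k]])
    if (!all(dim(O) == dim(E))) stop("SFS dimension mismatch in pair ", k)
    O[1, 1] <- 0
    o <- as.vector(O); e <- as.vector(E)
    if (pool_below > 0) {
      rare <- o < pool_below
      o <- c(o[!rare], sum(o[rare]))
      e <- c(e[!rare], sum(e[rare]))
    }
    lnl <- lnl + sum(o * log(pmax(e, eps)))
  }
  lnl
}

#' Composite-likelihood parameter search
#'
#' Stochastic range-halving search over the prior box: per cycle,
#' `n_proposals` parameter vectors are drawn within the current ranges and
#' scored by the Monte-Carlo composite likelihood; after `reinit_after`
#' consecutive non-improving cycles the ranges are re-centred on the
#' incumbent best and shrunk by `range_shrink`. An optional refinement stage
#' re-evaluates proposals around the best point at higher precision.
#'
#' @param template a `model_template`.
#' @param priors a [prior_spec()] covering `template$params`.
#' @param obs observed folded joint SFS (list per pair, or single).
#' @param samples named diploid sample counts.
#' @param pairs population pairs matching `obs` (default: the template's two
#'   populations).
#' @param cycles optimisation cycles.
#' @param reinit_after non-improving cycles before re-centre + shrink.
#' @param range_shrink multiplicative range shrink factor.
#' @param n_proposals proposals per cycle.
#' @param n_sims genealogies per likelihood evaluation.
#' @param n_runs independent optimizer runs (best kept).
#' @param refine_sims genealogies for the final refinement (0 to skip).
#' @param total_bp total sequence length (bp) the observed SFS was computed
#'   over, per pair. When given, a per-site binomial term for the number of
#'   segregating sites (with polymorphism probability `mu x E[tree length]`)
#'   anchors the absolute scale of sizes and times; without it the folded
#'   SFS proportions only identify parameter ratios.
#' @param pool_below rare-class pooling threshold passed to
#'   [composite_log_likelihood()].
#' @param seed integer seed. Likelihood evaluations reuse one fixed stream
#'   of engine random numbers per run (common random numbers), so proposal
#'   comparisons are not drowned by independent Monte-Carlo noise.
#' @return object of class `model_fit`: `model_id`, `params`, `lnl`, `aic`,
#'   `n_parameters`, `trajectory`, `seed`.
#' @export
optimize_model <- function(template, priors, obs, samples, pairs = NULL,
                           cycles = 40, reinit_after = 3, range_shrink = 0.5,
                           n_proposals = 8, n_sims = 5000, n_runs = 1,
                           refine_sims = 2 * n_sims, total_bp = NULL,
                           pool_below = 10, seed = 1L) {
  if (inherits(obs, "joint_folded_sfs")) obs <- list(obs)
  if (is.null(pairs)) pairs <- list(template$pop_names[1:2])
  if (!all(template$params %in% priors$param))
    stop("priors must cover all template parameters")
  priors <- priors[match(template$params, priors$param), ]
  if (!is.null(total_bp)) total_bp <- rep_len(total_bp, length(obs))
  if (!is.null(seed)) set.seed(seed)

  # jointly rescaling every size and time parameter by c leaves the folded
  # SFS proportions untouched and scales the expected tree length by
  # exactly c, so given any proposed shape the global scale is profiled
  # out analytically against the segregating-sites anchor. Scale-bearing
  # parameters are the log-uniform ones (sizes, times); uniform parameters
  # (fractions) are shape-only.
  is_scale <- priors$family == "loguniform"
  S_obs <- vapply(obs, function(o) sum(unclass(o)) - unclass(o)[1, 1],
                  numeric(1))
  anchor <- function(cq) { # cq = mu * c * E[tree length], per pair
    if (any(!is.finite(cq) | cq <= 0 | cq >= 1)) return(-Inf)
    sum(S_obs * log(cq) + (total_bp - S_obs) * log1p(-cq))
  }
  eval_lnl <- function(par, ns, eval_seed) {
    res <- eval_fit(par, ns, eval_seed)
    res$lnl
  }
  eval_fit <- function(par, ns, eval_seed) {
    bad <- list(lnl = -Inf, par = par)
    m <- tryCatch(template$build(par), error = function(e) NULL)
    if (is.null(m)) return(bad)
    rng_state <- .Random.seed
    set.seed(eval_seed)
    expd <- tryCatch(expected_sfs(m, samples, pairs, n_sims = ns),
                     error = function(e) NULL)
    .Random.seed <<- rng_state
    if (is.null(expd)) return(bad)
    lnl <- composite_log_likelihood(obs, expd, pool_below = pool_below)
    if (is.null(total_bp)) return(list(lnl = lnl, par = par))
    q <- m$mu * vapply(expd, attr, numeric(1), "mean_tree_length")
    if (any(!is.finite(q) | q <= 0)) return(bad)
    # admissible joint rescaling keeping every scale parameter in its prior
    c_lo <- max(priors$lower[is_scale] / par[is_scale])
    c_hi <- min(priors$upper[is_scale] / par[is_scale])
    if (!any(is_scale) || c_lo > c_hi) return(list(lnl = lnl + anchor(q),
                                                   par = par))
    cs <- S_obs / (total_bp * q)       # per-pair closed-form optimum
    c_star <- min(max(stats::weighted.mean(cs, S_obs), c_lo), c_hi)
    if (length(S_obs) > 1) {           # multi-pair: tighten by 1-d search
      opt <- stats::optimize(function(lc) anchor(q * exp(lc)),
                             log(c(max(c_lo, c_star / 3),
                                   min(c_hi, c_star * 3))), maximum = TRUE)
      c_star <- exp(opt$maximum)
    }
    par[is_scale] <- par[is_scale] * c_star
    list(lnl = lnl + anchor(q * c_star), par = par)
  }

  best_overall <- NULL
  run_bests <- list()
  for (run in seq_len(n_runs)) {
    eval_seed <- sample.int(2^31 - 2, 1)
    ranges <- priors
    best <- NULL
    strikes <- 0
    traj <- numeric(0)
    for (cy in seq_len(cycles + 1)) {
      # the first pass is a dense initial exploration of the prior box so
      # the incumbent starts in a sensible basin; later cycles refine
      props <- draw_from_ranges(ranges,
                                if (cy == 1) 8L * n_proposals else n_proposals)
      improved <- FALSE
      for (r in seq_len(nrow(props))) {
        res <- eval_fit(props[r, ], n_sims, eval_seed)
        if (is.null(best) || res$lnl > best$lnl) {
          best <- list(params = res$par, lnl = res$lnl)
          improved <- TRUE
        }
      }
      traj <- c(traj, best$lnl)
      if (cy == 1) next
      if (improved) strikes <- 0 else strikes <- strikes + 1
      if (strikes >= reinit_after) {
        ranges <- shrink_ranges(ranges, as.list(best$params), range_shrink,
                                priors)
        strikes <- 0
      }
    }
    run_bests[[run]] <- best
    if (is.null(best_overall) || best$lnl > best_overall$lnl) {
      best_overall <- c(best, list(trajectory = traj))
    }
  }
  if (refine_sims > 0 && is.finite(best_overall$lnl)) {
    # final estimation from the best run's point values: with the engine
    # random numbers held fixed the surface is deterministic but jagged,
    # so the polish is a cyclic coordinate grid descent with shrinking
    # spans (robust to the Monte-Carlo jaggedness that traps smooth
    # optimizers)
    refine_seed <- sample.int(2^31 - 2, 1)
    to_x <- function(par) ifelse(priors$family == "loguniform",
                                 log(par), par)
    from_x <- function(x) {
      p <- ifelse(priors$family == "loguniform", exp(x), x)
      names(p) <- priors$param
      p
    }
    lo <- ifelse(priors$family == "loguniform", log(priors$lower),
                 priors$lower)
    hi <- ifelse(priors$family == "loguniform", log(priors$upper),
                 priors$upper)
    npar <- nrow(priors)
    scale_of <- ifelse(priors$family == "loguniform", 1, (hi - lo) / 4)
    # adaptive random-direction line search: random directions traverse the
    # correlated time/size ridges that axis-aligned moves cannot follow
    polish <- function(start_par, iters, ns, step = 0.5) {
      res0 <- eval_fit(start_par, ns, refine_seed)
      x <- pmin(pmax(to_x(res0$par), lo), hi)
      fx <- res0$lnl
      for (it in seq_len(iters)) {
        d <- stats::rnorm(npar) * scale_of
        d <- d / sqrt(sum(d^2))
        moved <- FALSE
        for (s in c(step, -step)) {
          xi <- pmin(pmax(x + s * d, lo), hi)
          res <- eval_fit(from_x(xi), ns, refine_seed)
          if (is.finite(res$lnl) && res$lnl > fx) {
            x <- pmin(pmax(to_x(res$par), lo), hi)
            fx <- res$lnl
            moved <- TRUE
            break
          }
        }
        step <- if (moved) min(step * 1.4, 1.0) else max(step * 0.93, 0.02)
      }
      list(x = x, lnl = fx)
    }
    # cheap multi-start pass from the best distinct run optima, then one
    # high-precision pass from the winner
    ord <- order(-vapply(run_bests, `[[`, numeric(1), "lnl"))
    starts <- run_bests[ord[seq_len(min(2, length(ord)))]]
    stage1 <- lapply(starts, function(b) polish(b$params, 180, n_sims))
    win <- stage1[[which.max(vapply(stage1, `[[`, numeric(1), "lnl"))]]
    stage2 <- polish(from_x(win$x), 120, refine_sims, step = 0.25)
    x <- stage2$x
    fx <- stage2$lnl
    # final axis-wise tightening on a small grid
    hw <- ifelse(priors$family == "loguniform", 0.15, 0.04 * (hi - lo))
    for (round in 1:2) {
      for (i in seq_len(npar)) {
        for (gv in seq(max(x[i] - hw[i], lo[i]), min(x[i] + hw[i], hi[i]),
                       length.out = 7)) {
          xi <- x
          xi[i] <- gv
          res <- eval_fit(from_x(xi), refine_sims, refine_seed)
          if (is.finite(res$lnl) && res$lnl > fx) {
            x <- pmin(pmax(to_x(res$par), lo), hi)
            fx <- res$lnl
          }
        }
      }
      hw <- hw * 0.4
    }
    best_overall$params <- from_x(x)
    best_overall$lnl <- fx
    best_overall$trajectory <- c(best_overall$trajectory, fx)
  }
  if (!is.finite(best_overall$lnl))
    stop("optimization failed: no finite composite likelihood found")
  k <- length(template$params)
  structure(list(model_id = template$name, params = best_overall$params,
                 lnl = best_overall$lnl, aic = 2 * k - 2 * best_overall$lnl,
                 n_parameters = k, trajectory = best_overall$trajectory,
                 seed = seed),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", x$model_id, "\n")
  cat(sprintf("  lnL = %.2f  AIC = %.2f  (k = %d)\n", x$lnl, x$aic,
              x$n_parameters))
  print(round(x$params, 2))
  invisible(x)
}

#' Fit and rank a set of demographic models by AIC
#'
#' @param obs observed folded joint SFS (list per pair).
#' @param samples named diploid counts.
#' @param templates list of `model_template`s.
#' @param priors a single [prior_spec()] or a list (one per template).
#' @param pairs population pairs matching `obs`.
#' @param seed integer seed (per-model seeds derived from it).
#' @param ... passed to [optimize_model()].
#' @return list with `table` (model, n_parameters, lnl, AIC, dAIC, ranked)
#'   and `fits`; failed models are recorded and skipped.
#' @export
compare_models <- function(obs, samples, templates, priors, pairs = NULL,
                           seed = 1L, ...) {
  if (length(templates) < 2) warning("comparing fewer than two models")
  fits <- list()
  errs <- list()
  for (i in seq_along(templates)) {
    pri <- if (inherits(priors, "prior_spec")) priors else priors[[i]]
    fit <- tryCatch(
      optimize_model(templates[[i]], pri, obs, samples, pairs = pairs,
                     seed = seed + i - 1L, ...),
      error = function(e) e)
    if (inherits(fit, "error")) errs[[templates[[i]]$name]] <- conditionMessage(fit)
    else fits[[templates[[i]]$name]] <- fit
  }
  if (!length(fits)) stop("all model fits failed")
  tab <- data.frame(model = names(fits),
                    n_parameters = vapply(fits, `[[`, numeric(1), "n_parameters"),
                    lnl = vapply(fits, `[[`, numeric(1), "lnl"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    row.names = NULL)
  tab <- tab[order(tab$aic), ]
  tab$daic <- tab$aic - tab$aic[1]
  list(table = tab, fits = fits, failures = errs)
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates pseudo-observed folded joint SFS datasets under the fitted
#' point estimates (independent non-recombining segments), refits each with
#' the optimizer initialized at the point values, and reports percentile
#' 95% confidence intervals per parameter.
#'
#' @param best a `model_fit`.
#' @param template,priors,samples,pairs as in [optimize_model()].
#' @param n_datasets pseudo-observed datasets.
#' @param n_segments segments per dataset.
#' @param segment_len segment length in bp.
#' @param seed integer seed.
#' @param ... passed to the refits (e.g. `cycles`, `n_sims`).
#' @return list with `ci` (param, lower, upper, point), `estimates` matrix,
#'   `n_refits`, `reliable` (FALSE when fewer than 10 refits succeeded),
#'   and the `scale` actually used.
#' @export
parametric_bootstrap <- function(best, template, priors, samples,
                                 pairs = NULL, n_datasets = 100,
                                 n_segments = 200000, segment_len = 1000,
                                 seed = 1L, ...) {
  if (is.null(pairs)) pairs <- list(template$pop_names[1:2])
  if (!is.null(seed)) set.seed(seed)
  model <- template$build(best$params)
  # refit ranges centred tightly on the point estimates
  pri <- priors[match(template$params, priors$param), ]
  start_ranges <- shrink_ranges(pri, as.list(best$params), 0.25, pri)
  ests <- matrix(NA_real_, n_datasets, length(template$params),
                 dimnames = list(NULL, template$params))
  for (b in seq_len(n_datasets)) {
    ds_seed <- sample.int(2^31 - 1, 1)
    sim <- simulate_unlinked_snps(model, samples[unique(unlist(pairs))],
                                  n_loci = n_segments,
                                  locus_len = segment_len, seed = ds_seed)
    obs_b <- lapply(pairs, function(pr)
      joint_folded_sfs(sim$genotypes, pr[1], pr[2], min_presence = 1))
    fit <- tryCatch(
      optimize_model(template, prior_spec(start_ranges), obs_b, samples,
                     pairs = pairs,
                     total_bp = as.double(n_segments) * segment_len,
                     seed = ds_seed %% 10000L, ...),
      error = function(e) NULL)
    if (!is.null(fit)) ests[b, ] <- fit$params
  }
  ok <- stats::complete.cases(ests)
  ci <- data.frame(param = template$params,
                   point = as.numeric(best$params[template$params]),
                   lower = apply(ests[ok, , drop = FALSE], 2,
                                 stats::quantile, 0.025, names = FALSE),
                   upper = apply(ests[ok, , drop = FALSE], 2,
                                 stats::quantile, 0.975, names = FALSE))
  list(ci = ci, estimates = ests, n_refits = sum(ok),
       reliable = sum(ok) >= 10,
       scale = list(n_datasets = n_datasets, n_segments = n_segments,
                    segment_len = segment_len))
}
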