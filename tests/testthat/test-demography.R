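test_that("expected folded SFS matches the neutral closed form at n = 4", {
  # single population seen through a degenerate split: folded classes
  # (eta1, eta2) = (8/11, 3/11)
  m <- demographic_model(c("p", "q"), c(1e4, 1e4),
                         list(event_split(0, "q", "p")))
  set.seed(70)
  e <- expected_sfs(m, c(p = 2, q = 0), list(c("p", "q")), n_sims = 30000)
  E <- unclass(e[[1]])
  eta <- c(E[2, 1], E[3, 1])
  expect_equal(eta, c(8 / 11, 3 / 11), tolerance = 0.02)
  expect_equal(sum(E), 1, tolerance = 1e-9)
})

test_that("branch weighting and mutation dropping agree", {
  m <- split_model(t_split = 15000)
  set.seed(71)
  e1 <- expected_sfs(m, c(A = 3, B = 3), list(c("A", "B")), n_sims = 20000)
  set.seed(72)
  e2 <- expected_sfs(m, c(A = 3, B = 3), list(c("A", "B")), n_sims = 20000,
                     method = "mutation")
  expect_lt(max(abs(unclass(e1[[1]]) - unclass(e2[[1]]))), 0.02)
})

test_that("Monte-Carlo error of the expected SFS shrinks like 1/sqrt(n)", {
  m <- split_model(t_split = 15000)
  draw <- function(ns, seed) {
    set.seed(seed)
    unclass(expected_sfs(m, c(A = 3, B = 3), list(c("A", "B")),
                         n_sims = ns)[[1]])
  }
  ref <- draw(80000, 73)
  err_small <- mean(vapply(1:6, function(s)
    max(abs(draw(1000, 100 + s) - ref)), numeric(1)))
  err_big <- mean(vapply(1:6, function(s)
    max(abs(draw(16000, 200 + s) - ref)), numeric(1)))
  expect_gt(err_small / err_big, 2)
})

test_that("composite log-likelihood follows the multinomial arithmetic", {
  mk <- function(M) structure(M, class = "joint_folded_sfs")
  # expected uniform over c classes with n sites: lnL = n log(1/c)
  O <- mk(matrix(c(0, 10, 10, 10), 2, 2))
  E <- mk(matrix(c(0, 1 / 3, 1 / 3, 1 / 3), 2, 2))
  expect_equal(composite_log_likelihood(O, E), 30 * log(1 / 3))
  # proportional obs attain the multinomial maximum over distributions
  O2 <- mk(matrix(c(0, 30, 50, 20), 2, 2))
  E_match <- mk(matrix(c(0, .3, .5, .2), 2, 2))
  E_off <- mk(matrix(c(0, .2, .5, .3), 2, 2))
  expect_gt(composite_log_likelihood(O2, E_match),
            composite_log_likelihood(O2, E_off))
  # consistent permutation leaves lnL unchanged (monomorphic cell fixed)
  O3 <- mk(matrix(c(0, 5, 7, 9), 2, 2))
  E3 <- mk(matrix(c(0, .1, .6, .3), 2, 2))
  Op <- mk(matrix(c(0, 9, 5, 7), 2, 2))
  Ep <- mk(matrix(c(0, .3, .1, .6), 2, 2))
  expect_equal(composite_log_likelihood(O3, E3),
               composite_log_likelihood(Op, Ep))
  expect_error(composite_log_likelihood(O3, mk(matrix(0.1, 3, 3))),
               "dimension")
})

test_that("rare-class pooling preserves totals", {
  mk <- function(M) structure(M, class = "joint_folded_sfs")
  O <- mk(matrix(c(0, 100, 3, 2), 2, 2))
  E <- mk(matrix(c(0, .9, .06, .04), 2, 2))
  pooled <- composite_log_likelihood(O, E, pool_below = 5)
  expect_equal(pooled, 100 * log(.9) + 5 * log(.1))
})

test_that("a one-parameter scan recovers the true population size", {
  # estimate N from a single-population folded SFS via the same
  # likelihood machinery the optimizer uses
  truthN <- 1e4
  m <- demographic_model(c("p", "q"), c(truthN, truthN),
                         list(event_split(0, "q", "p")), mu = 6.5e-9)
  sim <- simulate_unlinked_snps(m, c(p = 5, q = 0), n_loci = 20000,
                                locus_len = 1000, seed = 74)
  obs <- joint_folded_sfs(sim$genotypes, "p", "p", min_presence = 1)
  # scan a grid of N, evaluating polymorphism-anchored likelihood
  tb <- 2e7
  S <- sum(unclass(obs)) - unclass(obs)[1, 1]
  lnls <- vapply(seq(0.5, 1.5, by = 0.1) * truthN, function(N) {
    mm <- demographic_model(c("p", "q"), c(N, N),
                            list(event_split(0, "q", "p")), mu = 6.5e-9)
    set.seed(75)
    e <- expected_sfs(mm, c(p = 5, q = 0), list(c("p", "p")),
                      n_sims = 4000)
    q <- mm$mu * attr(e[[1]], "mean_tree_length")
    composite_log_likelihood(obs, e, pool_below = 10) +
      S * log(q) + (tb - S) * log1p(-q)
  }, numeric(1))
  Nhat <- seq(0.5, 1.5, by = 0.1)[which.max(lnls)] * truthN
  expect_equal(Nhat, truthN, tolerance = 0.1)
  # surface is unimodal over the scanned range
  k <- which.max(lnls)
  expect_true(all(diff(lnls[1:k]) > 0) && all(diff(lnls[k:length(lnls)]) < 0))
})

test_that("optimizer degenerates and reproduces as documented", {
  tmpl <- tmpl_divergence_pair(bottleneck = FALSE)
  pri <- default_pair_priors(tmpl)
  m <- tmpl$build(c(N_C = 5e3, N_W = 2e4, N_ANC = 2e4, T_DIV = 15000))
  sim <- simulate_unlinked_snps(m, c(cultivated = 4, wild = 4),
                                n_loci = 3000, locus_len = 1000, seed = 76)
  obs <- joint_folded_sfs(sim$genotypes, "cultivated", "wild",
                          min_presence = 1)
  f0 <- optimize_model(tmpl, pri, obs, c(cultivated = 4, wild = 4),
                       cycles = 0, n_proposals = 4, n_sims = 500,
                       refine_sims = 0, seed = 20)
  expect_length(f0$trajectory, 1)
  f1 <- optimize_model(tmpl, pri, obs, c(cultivated = 4, wild = 4),
                       cycles = 3, n_proposals = 3, n_sims = 500,
                       refine_sims = 0, seed = 21)
  f2 <- optimize_model(tmpl, pri, obs, c(cultivated = 4, wild = 4),
                       cycles = 3, n_proposals = 3, n_sims = 500,
                       refine_sims = 0, seed = 21)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$lnl, f2$lnl)
  # AIC identity
  expect_equal(f1$aic, 2 * f1$n_parameters - 2 * f1$lnl)
})

test_that("model comparison handles trivial and failing members", {
  tmpl <- tmpl_divergence_pair(bottleneck = FALSE)
  pri <- default_pair_priors(tmpl)
  m <- tmpl$build(c(N_C = 5e3, N_W = 2e4, N_ANC = 2e4, T_DIV = 15000))
  sim <- simulate_unlinked_snps(m, c(cultivated = 3, wild = 3),
                                n_loci = 2000, locus_len = 1000, seed = 77)
  obs <- joint_folded_sfs(sim$genotypes, "cultivated", "wild",
                          min_presence = 1)
  cmp <- suppressWarnings(
    compare_models(obs, c(cultivated = 3, wild = 3), list(tmpl), pri,
                   cycles = 1, n_proposals = 2, n_sims = 300,
                   refine_sims = 0, seed = 22))
  expect_equal(nrow(cmp$table), 1)
  expect_equal(cmp$table$daic, 0)
})

test_that("parametric bootstrap covers a known truth in a tiny setup", {
  tmpl <- tmpl_divergence_pair(bottleneck = FALSE)
  pri <- default_pair_priors(tmpl)
  truth <- c(N_C = 5e3, N_W = 2e4, N_ANC = 2e4, T_DIV = 15000)
  fake_fit <- structure(list(model_id = tmpl$name, params = truth,
                             lnl = 0, aic = 0, n_parameters = 4, seed = 1),
                        class = "model_fit")
  bs <- parametric_bootstrap(fake_fit, tmpl, pri,
                             c(cultivated = 3, wild = 3),
                             n_datasets = 3, n_segments = 3000,
                             segment_len = 1000, seed = 23,
                             cycles = 4, n_proposals = 4, n_sims = 800,
                             refine_sims = 0)
  expect_equal(bs$n_refits, 3)
  expect_false(bs$reliable)  # fewer than 10 refits is flagged
  expect_true(all(bs$ci$lower <= bs$ci$upper))
  # degenerate single-dataset CI equals that refit
  bs1 <- parametric_bootstrap(fake_fit, tmpl, pri,
                              c(cultivated = 3, wild = 3),
                              n_datasets = 1, n_segments = 2000,
                              segment_len = 1000, seed = 24,
                              cycles = 2, n_proposals = 3, n_sims = 500,
                              refine_sims = 0)
  expect_equal(bs1$ci$lower, bs1$ci$upper, tolerance = 1e-9)
})

test_that("four-population templates build valid two-level demographies", {
  tms <- four_pop_templates()
  expect_length(tms, 6)
  par <- c(N_exilis = 1e4, N_longiflora = 1e4, N_iburua = 1e4,
           N_ternata = 1e4, N_ANC = 1e4, T_A = 5000, T_B = 20000,
           T_ROOT = 1e5)
  for (tm in tms) {
    m <- tm$build(par)
    expect_s3_class(m, "demographic_model")
  }
})
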