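#' Simulation experiments at the study's conditions
#'
#' These functions reproduce, on synthetic data generated by the package's
#' own coalescent simulator, the headline simulation-anchored analyses of
#' the two-pair fonio domestication design: topology-weighting separation of
#' the two cultivated/wild pairs, the drift-tree fit to the allele-frequency
#' covariance, and divergence-time recovery by the SFS composite-likelihood
#' optimizer.
#'
#' @name experiments
NULL

# study-condition demography used by the window/SNP experiments: two
# cultivated/wild pairs, deep between-pair split, recent within-pair splits
study_two_pair_model <- function(bottlenecks = FALSE) {
  two_pair_model(sizes = c(1e4, 1e4, 1e4, 1e4),
                 t_split1 = 25000, t_split2 = 10000, t_deep = 150000,
                 bottleneck_sizes = if (bottlenecks) c(2e3, 5e3),
                 bottleneck_ends = c(2000, 3000),
                 n_anc = 1e4)
}

study_samples <- function() {
  c(exilis = 21, longiflora = 8, iburua = 19, ternata = 6)
}

#' Topology-weighting separation of the two pairs
#'
#' Simulates independent 50 kb windows under the deep two-pair divergence
#' model (no gene flow), builds per-window NJ trees from genotype
#' p-distances, computes exact topology weights over one-tip-per-group
#' quartets, and reports the percentage of windows whose maximum-weight
#' topology is the paired (cultivated,wild)x2 grouping.
#'
#' @param seed integer seed.
#' @param n_windows number of windows.
#' @param samples named diploid counts (defaults to the study's group sizes).
#' @return list: `percent_supporting`, `mean_weight_percent`, `n_windows`,
#'   and the `topology_weights` object.
#' @export
experiment_twisst_separation <- function(seed = 1L, n_windows = 500,
                                         samples = study_samples()) {
  model <- study_two_pair_model()
  sim <- simulate_windows(model, samples, n_windows, window_len = 50000,
                          seed = seed)
  trees <- window_nj_trees(sim$genotypes,
                           window_spec(50000, 50000),
                           min_snps_per_window = 20)
  groups <- split(sim$genotypes$individual_ids, sim$genotypes$pop_labels)
  groups <- groups[c("exilis", "longiflora", "iburua", "ternata")]
  tw <- twisst_weights(trees, groups, method = "exact", seed = seed)
  paired <- 1L # T1 = ((exilis,longiflora),(iburua,ternata))
  list(percent_supporting = 100 * unname(tw$max_weight_fraction[paired]),
       mean_weight_percent = 100 * unname(tw$mean_weights[paired]),
       n_windows = length(trees), weights = tw)
}

#' Drift-tree fit to simulated allele-frequency covariance
#'
#' Simulates unlinked SNPs under the strict two-pair tree, computes the
#' bias-corrected allele-frequency covariance, fits the best drift tree
#' over all rooted 4-taxon topologies, and reports the variance explained
#' and whether the paired topology was recovered.
#'
#' @param seed integer seed.
#' @param n_snps number of unlinked SNPs.
#' @param samples named diploid counts.
#' @return list: `variance_explained_percent`, `topology_correct`, `fit`.
#' @export
experiment_drift_tree <- function(seed = 1L, n_snps = 10000,
                                  samples = study_samples()) {
  model <- study_two_pair_model()
  sim <- simulate_unlinked_snps(model, samples, n_loci = n_snps,
                                seed = seed, one_snp_per_locus = TRUE)
  W <- allele_freq_covariance(sim$genotypes)
  fit <- fit_population_tree(W)
  correct <- is_pair_topology(fit$tree, c("exilis", "longiflora"),
                              c("iburua", "ternata"))
  list(variance_explained_percent = 100 * fit$variance_explained,
       topology_correct = correct, fit = fit)
}

# does the rooted 4-taxon tree group the two pairs?
is_pair_topology <- function(tree, pair1, pair2) {
  u <- ape::unroot(tree)
  bp <- ape::prop.part(u)
  labs <- attr(bp, "labels")
  splits <- lapply(bp, function(i) sort(labs[i]))
  any(vapply(splits, identical, logical(1), sort(pair1))) ||
    any(vapply(splits, identical, logical(1), sort(pair2)))
}

# simulate approximately n_sites segregating sites by Poisson mutation
# dropping (the process the branch-weighted expected SFS describes); a pilot
# batch estimates the per-locus yield
sim_pair_sites <- function(model, samples, n_sites, seed, locus_len = 1000) {
  set.seed(seed)
  pilot <- run_engine(model, samples, 200, locus_len, want_sites = TRUE)
  rate <- max(length(pilot$site_locus) / 200, 1e-3)
  n_loci <- ceiling(n_sites / rate)
  sim <- simulate_unlinked_snps(model, samples, n_loci = n_loci,
                                locus_len = locus_len, seed = seed + 1L)
  attr(sim, "total_bp") <- as.double(n_loci) * locus_len
  sim
}

# study-condition truth for one cultivated/wild pair
pair_truth <- function(pair = c("white", "black")) {
  pair <- match.arg(pair)
  if (pair == "white") {
    list(samples = c(cultivated = 21, wild = 8),
         params = c(N_C = 2e4, N_W = 5e4, N_ANC = 5e4, T_DIV = 25000,
                    N_BOT = 2e3, B_FRAC = 2000 / 25000))
  } else {
    list(samples = c(cultivated = 19, wild = 6),
         params = c(N_C = 3e4, N_W = 5e4, N_ANC = 5e4, T_DIV = 10000,
                    N_BOT = 5e3, B_FRAC = 3000 / 10000))
  }
}

#' Divergence-time recovery under the divergence-with-bottleneck scenario
#'
#' Parameterizes the two-population divergence+bottleneck model at the
#' study-scale point values for a cultivated/wild pair (divergence 25,000
#' generations ago for the white pair, 10,000 for the black pair), simulates
#' unlinked polymorphic sites, computes the folded joint SFS, and
#' re-estimates the parameters with the range-halving composite-likelihood
#' optimizer.
#'
#' @param pair `"white"` (samples 21+8 diploids) or `"black"` (19+6).
#' @param seed integer seed.
#' @param n_sites polymorphic sites in the pseudo-observed SFS.
#' @param cycles,n_sims,n_proposals,n_runs optimizer controls.
#' @return list: `t_div_estimate`, `t_div_truth`, `relative_error`, `fit`,
#'   `obs`.
#' @export
experiment_divergence_recovery <- function(pair = c("white", "black"),
                                           seed = 1L, n_sites = 50000,
                                           cycles = 40, n_sims = 5000,
                                           n_proposals = 8, n_runs = 3) {
  pair <- match.arg(pair)
  tru <- pair_truth(pair)
  tmpl <- tmpl_divergence_pair(bottleneck = TRUE)
  model <- tmpl$build(tru$params)
  names(tru$samples) <- tmpl$pop_names
  sim <- sim_pair_sites(model, tru$samples, n_sites, seed)
  obs <- joint_folded_sfs(sim$genotypes, tmpl$pop_names[1],
                          tmpl$pop_names[2], min_presence = 1)
  fit <- optimize_model(tmpl, default_pair_priors(tmpl), obs, tru$samples,
                        cycles = cycles, n_sims = n_sims,
                        n_proposals = n_proposals, n_runs = n_runs,
                        total_bp = attr(sim, "total_bp"), seed = seed + 1L)
  est <- unname(fit$params["T_DIV"])
  list(t_div_estimate = est, t_div_truth = unname(tru$params["T_DIV"]),
       relative_error = abs(est - tru$params[["T_DIV"]]) / tru$params[["T_DIV"]],
       fit = fit, obs = obs)
}

#' Bottleneck-vs-constant model choice on bottlenecked data
#'
#' Simulates a folded joint SFS under the divergence-with-bottleneck
#' scenario and asks [compare_models()] to rank the +bottleneck and
#' constant-size variants of the pair topology by AIC.
#'
#' @param seed integer seed.
#' @param n_sites polymorphic sites.
#' @param cycles,n_sims,n_proposals optimizer controls per model.
#' @return list: `ranking` (AIC table), `bottleneck_ranked_first`, `fits`.
#' @export
experiment_bottleneck_choice <- function(seed = 1L, n_sites = 30000,
                                         cycles = 20, n_sims = 3000,
                                         n_proposals = 6, n_runs = 2) {
  tru <- pair_truth("white")
  tmpl_b <- tmpl_divergence_pair(bottleneck = TRUE)
  tmpl_c <- tmpl_divergence_pair(bottleneck = FALSE)
  model <- tmpl_b$build(tru$params)
  names(tru$samples) <- tmpl_b$pop_names
  sim <- sim_pair_sites(model, tru$samples, n_sites, seed)
  obs <- joint_folded_sfs(sim$genotypes, tmpl_b$pop_names[1],
                          tmpl_b$pop_names[2], min_presence = 1)
  cmp <- compare_models(obs, tru$samples, list(tmpl_b, tmpl_c),
                        default_pair_priors(tmpl_b), seed = seed + 1L,
                        cycles = cycles, n_sims = n_sims,
                        n_proposals = n_proposals, n_runs = n_runs,
                        total_bp = attr(sim, "total_bp"))
  list(ranking = cmp$table,
       bottleneck_ranked_first =
         cmp$table$model[1] == "pair_divergence_bottleneck",
       fits = cmp$fits)
}
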