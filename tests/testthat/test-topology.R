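test_that("NJ recovers additive distances from random trees", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- tr$edge.length + 0.1
    D <- ape::cophenetic.phylo(tr)
    rec <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("window trees come from p-distances with skipping and clipping", {
  sim <- simulate_windows(split_model(), c(A = 3, B = 3), n_windows = 10,
                          window_len = 20000, seed = 60)
  trees <- window_nj_trees(sim$genotypes, window_spec(20000, 20000),
                           min_snps_per_window = 5)
  expect_gt(length(trees), 0)
  for (wt in trees) {
    expect_s3_class(wt$tree, "phylo")
    expect_true(all(wt$tree$edge.length >= 0))
    expect_true(all(wt$tree$tip.label %in% sim$genotypes$individual_ids))
  }
  # a window threshold higher than any SNP count skips everything
  none <- window_nj_trees(sim$genotypes, window_spec(20000, 20000),
                          min_snps_per_window = 1e6)
  expect_length(none, 0)
  # duplicated individual yields a zero-length terminal pair
  g <- sim$genotypes
  g2 <- genotype_matrix(rbind(g$genotypes, g$genotypes[1, ]),
                        g$chrom, g$pos, c(g$individual_ids, "dup"))
  tr <- window_nj_trees(g2, window_spec(20000, 20000), 5)[[1]]$tree
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d[g$individual_ids[1], "dup"], 0)
})

test_that("one tip per group gives weight 1 to the matching topology", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tw <- twisst_weights(list(tr), list(g1 = "a", g2 = "b", g3 = "c",
                                      g4 = "d"))
  expect_equal(unname(tw$weights[1, ]), c(1, 0, 0))
  tw2 <- twisst_weights(list(tr), list(g1 = "a", g2 = "c", g3 = "b",
                                       g4 = "d"))
  expect_equal(unname(tw2$weights[1, ]), c(0, 1, 0))
})

test_that("twisst weights sum to one exactly under enumeration", {
  sim <- simulate_windows(two_pair_model(),
                          c(exilis = 3, longiflora = 2, iburua = 3,
                            ternata = 2),
                          n_windows = 12, window_len = 30000, seed = 61)
  trees <- window_nj_trees(sim$genotypes, window_spec(30000, 30000), 5)
  groups <- split(sim$genotypes$individual_ids, sim$genotypes$pop_labels)
  tw <- twisst_weights(trees, groups, method = "exact")
  expect_equal(unname(rowSums(tw$weights)), rep(1, nrow(tw$weights)))
})

test_that("exact and sampled weights agree within binomial error", {
  sim <- simulate_windows(split_model(t_split = 5000),
                          c(A = 5, B = 5), n_windows = 6,
                          window_len = 30000, seed = 62)
  g <- sim$genotypes
  # four pseudo-groups from the two populations
  ids <- g$individual_ids
  groups <- list(g1 = ids[1:3], g2 = ids[4:5], g3 = ids[6:8],
                 g4 = ids[9:10])
  trees <- window_nj_trees(g, window_spec(30000, 30000), 5)
  ex <- twisst_weights(trees, groups, method = "exact")
  sa <- twisst_weights(trees, groups, method = "sample",
                       max_subsamples = 2000, seed = 9)
  for (i in seq_along(trees)) {
    se <- sqrt(pmax(ex$weights[i, ] * (1 - ex$weights[i, ]), 1e-6) / 2000)
    expect_true(all(abs(ex$weights[i, ] - sa$weights[i, ]) <= 4 * se + 0.01))
  }
})

test_that("panmictic windows spread weight across the three topologies", {
  m <- demographic_model("p", 1e4)
  sim <- simulate_windows(m, c(p = 8), n_windows = 60,
                          window_len = 20000, seed = 63)
  ids <- sim$genotypes$individual_ids
  groups <- list(g1 = ids[1:2], g2 = ids[3:4], g3 = ids[5:6],
                 g4 = ids[7:8])
  trees <- window_nj_trees(sim$genotypes, window_spec(20000, 20000), 5)
  tw <- twisst_weights(trees, groups, method = "exact")
  expect_equal(unname(tw$mean_weights), rep(1 / 3, 3), tolerance = 0.35)
})

test_that("allele frequency covariance is symmetric and tracks identity", {
  g <- toy_genotypes(n = 8, L = 120, seed = 64,
                     pops = rep(c("A", "B"), 4))
  # duplicate population: off-diagonal equals within-population variance
  W <- allele_freq_covariance(g, c("A", "B"))
  expect_equal(W, t(W))
  sim <- simulate_unlinked_snps(split_model(t_split = 40000),
                                c(A = 6, B = 6), n_loci = 2000,
                                seed = 65, one_snp_per_locus = TRUE)
  g2 <- sim$genotypes
  # relabel: split population A into two halves -> near-identical pops
  labs <- g2$pop_labels
  labs[which(labs == "A")[1:3]] <- "A1"
  labs[labs == "A"] <- "A2"
  g2$pop_labels <- labs
  W2 <- allele_freq_covariance(g2, c("A1", "A2", "B"))
  expect_gt(W2["A1", "A2"], 0.8 * max(W2["A1", "A1"], 0.001))
})

test_that("a noiseless drift matrix is inverted exactly", {
  pops <- c("w", "x", "y", "z")
  tr <- ape::read.tree(text = "((w:0.02,x:0.03):0.08,(y:0.01,z:0.05):0.06);")
  # build V from shared root paths, then push through the centering
  V <- matrix(0, 4, 4, dimnames = list(pops, pops))
  V["w", "x"] <- V["x", "w"] <- 0.08
  V["y", "z"] <- V["z", "y"] <- 0.06
  diag(V) <- c(0.02 + 0.08, 0.03 + 0.08, 0.01 + 0.06, 0.05 + 0.06)
  A <- diag(4) - matrix(1 / 4, 4, 4)
  W <- A %*% V %*% A
  dimnames(W) <- list(pops, pops)
  fit <- fit_population_tree(W)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-9)
  expect_true(foniokit:::is_pair_topology(fit$tree, c("w", "x"),
                                          c("y", "z")))
  # scale equivariance: scaling W scales branch lengths, same topology
  fit2 <- fit_population_tree(3 * W)
  expect_equal(sort(fit2$tree$edge.length),
               3 * sort(fit$tree$edge.length), tolerance = 1e-6)
  # permuting population order relabels but does not change the topology
  o <- c(3, 1, 4, 2)
  fit3 <- fit_population_tree(W[o, o])
  expect_true(foniokit:::is_pair_topology(fit3$tree, c("w", "x"),
                                          c("y", "z")))
})

test_that("block bootstrap is seeded and degenerates correctly at B = 1", {
  sim <- simulate_unlinked_snps(two_pair_model(),
                                c(exilis = 4, longiflora = 3, iburua = 4,
                                  ternata = 3),
                                n_loci = 3000, seed = 66,
                                one_snp_per_locus = TRUE)
  b1 <- bootstrap_tree(sim$genotypes, block_size = 300, n_boot = 5,
                       seed = 10)
  b2 <- bootstrap_tree(sim$genotypes, block_size = 300, n_boot = 5,
                       seed = 10)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  single <- bootstrap_tree(sim$genotypes, block_size = 300, n_boot = 1,
                           seed = 11)
  expect_equal(ape::dist.topo(ape::unroot(single$consensus),
                              ape::unroot(single$trees[[1]])), 0,
               ignore_attr = TRUE)
  # deep two-pair divergence: both pair splits at full support
  deep <- bootstrap_tree(sim$genotypes, block_size = 300, n_boot = 20,
                         seed = 12)
  expect_true(foniokit:::is_pair_topology(deep$consensus,
                                          c("exilis", "longiflora"),
                                          c("iburua", "ternata")))
})
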