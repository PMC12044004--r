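test_that("pairwise coalescence time matches the neutral expectation 2N", {
  m <- demographic_model("p", 1e4)
  set.seed(1)
  res <- foniokit:::run_engine(m, c(p = 1), 20000)
  expect_equal(mean(res$tmrca), 2e4, tolerance = 0.02)
})

test_that("a split at time zero behaves like one panmictic population", {
  m0 <- demographic_model(c("A", "B"), c(1e4, 1e4),
                          list(event_split(0, "A", "B")))
  m1 <- demographic_model("B", 1e4)
  set.seed(2)
  t0 <- foniokit:::run_engine(m0, c(A = 2, B = 2), 8000)$tmrca
  set.seed(3)
  t1 <- foniokit:::run_engine(m1, c(B = 4), 8000)$tmrca
  expect_equal(mean(t0), mean(t1), tolerance = 0.05)
})

test_that("between-population divergence matches 2*mu*(T + 2N_anc)", {
  t_split <- 30000
  m <- split_model(t_split = t_split)
  sim <- simulate_unlinked_snps(m, c(A = 2, B = 2), n_loci = 4000,
                                locus_len = 2000, seed = 4)
  dx <- dxy_da(sim$genotypes, "A", "B",
               window_spec(2000, 2000))
  mean_dxy <- sum(dx$dxy * 2000) / (4000 * 2000)
  expect_equal(mean_dxy, 2 * m$mu * (t_split + 2 * 1e4), tolerance = 0.05)
})

test_that("Watterson's expectation E[S] = theta * a_n * L holds", {
  m <- demographic_model("p", 1e4, mu = 6.5e-9)
  sim <- simulate_unlinked_snps(m, c(p = 5), n_loci = 10000,
                                locus_len = 1000, seed = 5)
  S <- n_loci(sim$genotypes)
  expS <- 4 * 1e4 * 6.5e-9 * 1000 * sum(1 / (1:9)) * 10000
  expect_equal(S, expS, tolerance = 0.02)
})

test_that("the folded SFS of a constant-size population fits 1/i + 1/(n-i)", {
  m <- demographic_model("p", 1e4, mu = 6.5e-9)
  sim <- simulate_unlinked_snps(m, c(p = 5), n_loci = 15000, seed = 6,
                                locus_len = 2000)
  sfs <- folded_sfs(sim$genotypes, "p", min_presence = 1)
  n <- attr(sfs, "n_hap")
  eta <- as.numeric(sfs)[-1]
  i <- seq_len(n %/% 2)
  expected <- (1 / i + 1 / (n - i)) / (1 + (i == n - i))
  expected <- expected / sum(expected) * sum(eta)
  chi2 <- sum((eta - expected)^2 / expected)
  expect_gt(stats::pchisq(chi2, df = length(i) - 1, lower.tail = FALSE),
            0.001)
})

test_that("simulated windows tile the chromosome with true trees attached", {
  m <- split_model()
  sim <- simulate_windows(m, c(A = 3, B = 3), n_windows = 100,
                          window_len = 10000, seed = 7)
  expect_equal(nrow(sim$windows), 100)
  expect_equal(sim$windows$start, (0:99) * 10000 + 1)
  expect_equal(length(sim$true_trees), 100)
  expect_true(all(diff(sim$genotypes$pos) > 0))
  # same seed is bit-identical
  sim2 <- simulate_windows(m, c(A = 3, B = 3), n_windows = 100,
                           window_len = 10000, seed = 7)
  expect_identical(sim2$genotypes$genotypes, sim$genotypes$genotypes)
  expect_identical(sim2$true_trees, sim$true_trees)
})

test_that("deep two-pair divergence yields pair-monophyletic window trees", {
  m <- two_pair_model(t_split1 = 2000, t_split2 = 2000, t_deep = 4e5)
  sim <- simulate_windows(m, c(exilis = 2, longiflora = 2, iburua = 2,
                               ternata = 2), n_windows = 30,
                          window_len = 20000, seed = 8)
  pair1 <- paste0("h", which(sim$hap_pop %in% c("exilis", "longiflora")))
  mono <- vapply(sim$true_trees, function(nwk) {
    tr <- ape::read.tree(text = nwk)
    ape::is.monophyletic(tr, pair1)
  }, logical(1))
  expect_true(all(mono))
})

test_that("sequences round-trip the simulated genotypes", {
  m <- split_model()
  sim <- simulate_windows(m, c(A = 2, B = 2), n_windows = 3,
                          window_len = 2000, seed = 9)
  dir <- tempfile()
  paths <- emit_sequences(sim, dir)
  expect_length(paths, 4)
  # recompute genotype codes at segregating positions from the FASTA
  set.seed(sim$seed)
  wl <- 2000
  bases <- c("A", "C", "G", "T")
  backgrounds <- lapply(1:3, function(l) sample(bases, wl, replace = TRUE))
  ids <- sim$genotypes$individual_ids
  for (i in seq_along(ids)) {
    recs <- Biostrings::readDNAStringSet(paths[ids[i]])
    for (l in 1:3) {
      posl <- sim$hap_pos[[l]]
      if (!length(posl)) next
      ref <- backgrounds[[l]][posl]
      h1 <- strsplit(as.character(recs[[paste0(ids[i], "_win", l, "_hap1")]]),
                     "")[[1]][posl]
      h2 <- strsplit(as.character(recs[[paste0(ids[i], "_win", l, "_hap2")]]),
                     "")[[1]][posl]
      codes <- (h1 != ref) + (h2 != ref)
      gpos <- sim$genotypes$pos %in% (posl + (l - 1) * wl)
      expect_equal(unname(codes),
                   unname(sim$genotypes$genotypes[i, gpos]))
    }
  }
})

test_that("zero segregating sites give identical sequences", {
  m <- demographic_model("p", 100, mu = 1e-12)
  sim <- simulate_windows(m, c(p = 2), n_windows = 1, window_len = 500,
                          seed = 10)
  dir <- tempfile()
  paths <- emit_sequences(sim, dir)
  seqs <- unlist(lapply(paths, function(p)
    as.character(Biostrings::readDNAStringSet(p))))
  expect_equal(length(unique(seqs)), 1)
})

test_that("missingness injection hits its target rate and its edge cases", {
  g <- toy_genotypes(n = 10, L = 1000)
  expect_identical(inject_missingness(g, 0, seed = 1)$genotypes,
                   g$genotypes)
  expect_true(all(is.na(inject_missingness(g, 1, seed = 1)$genotypes)))
  gm <- inject_missingness(g, 0.1, seed = 2)
  expect_equal(mean(is.na(gm$genotypes)), 0.1, tolerance = 0.1)
  expect_error(inject_missingness(g, 1.2), "rates")
})

test_that("malformed demographies are rejected", {
  expect_error(demographic_model(c("A", "B"), c(1e4, 1e4)), "merge")
  expect_error(demographic_model("p", -5), "positive")
  m <- demographic_model(c("A", "B"), c(1e4, 1e4),
                         list(event_split(100, "A", "B")))
  expect_error(foniokit:::run_engine(m, c(A = 0, B = 0), 1), "diploid")
})

test_that("bottlenecks never increase cultivated diversity", {
  base <- two_pair_model()
  bot <- two_pair_model(bottleneck_sizes = c(1e3, 1e3))
  sim_pi <- function(m, seed) {
    sim <- simulate_unlinked_snps(m, c(exilis = 5, longiflora = 2,
                                       iburua = 2, ternata = 2),
                                  n_loci = 3000, locus_len = 1000,
                                  seed = seed)
    d <- window_diversity(sim$genotypes, "exilis",
                          window_spec(1000, 1000))
    mean(d$pi)
  }
  expect_gt(sim_pi(base, 11), sim_pi(bot, 11))
})

test_that("simulator agrees with an independent coalescent engine (msprime)", {
  # single population, n = 10 haploids: compare mean S per locus
  m <- demographic_model("p", 1e4, mu = 1e-7)
  sim <- simulate_unlinked_snps(m, c(p = 5), n_loci = 3000,
                                locus_len = 500, seed = 12)
  S_mine <- n_loci(sim$genotypes) / 3000
  py <- paste(
    "import msprime",
    "tot = 0; r = 0",
    "reps = msprime.sim_ancestry(samples=5, population_size=10000,",
    "    sequence_length=500, num_replicates=3000, random_seed=12)",
    "for ts in reps:",
    "    r += 1",
    "    mts = msprime.sim_mutations(ts, rate=1e-7, random_seed=r,",
    "        discrete_genome=False)",
    "    tot += mts.num_sites",
    "print(tot / 3000)",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)),
                                  stdout = TRUE, stderr = TRUE))
  S_ms <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(S_ms))
  # 3 Monte-Carlo standard errors of the difference
  se <- stats::sd(tabulate(as.integer(factor(sim$genotypes$chrom)),
                           nbins = 3000)) / sqrt(3000)
  expect_lt(abs(S_mine - S_ms), 3 * sqrt(2) * se + 0.05 * S_ms)
})
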