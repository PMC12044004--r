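---
title: "Inferring independent domestication from population-genomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring independent domestication from population-genomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foniokit)
```

## The scientific question

White fonio (*Digitaria exilis*) and black fonio (*D. iburua*) are West
African cereal crops whose closest sampled wild relatives are
*D. longiflora* and *D. ternata*. The central question this package
addresses is whether the two cultivated species were domesticated
independently — that is, whether the four populations form two deeply
diverged cultivated/wild pairs with no gene flow between them, each
cultivated lineage carrying the signature of its own domestication
bottleneck.

`foniokit` implements the full inference stack needed to ask that question
of biallelic-SNP data: diversity and divergence statistics, reference-free
k-mer diversity, PCA and model-based ancestry, topology weighting of local
gene trees, drift-covariance population trees, and coalescent demographic
model comparison from folded joint site-frequency spectra (SFS). Because
the original sequencing data are not required for any of the methodology,
the package ships a coalescent simulator that generates data under the
same family of demographies; every analysis stage is validated against it.

## The coalescent generator and what it emulates

The simulator (`simulate_unlinked_snps()`, `simulate_windows()`) draws
independent genealogies under the standard structured n-coalescent with
piecewise-constant diploid sizes: within a population of size $N$, each
pair of lineages coalesces at rate $1/2N$ per generation; at a split
event (time measured backwards, in generations) the derived population's
lineages join the ancestral pool; bottlenecks are interval size changes.
Mutations fall on branches as a Poisson process with rate $\mu L$ per
generation under infinite sites ($\mu = 6.5\times 10^{-9}$ per bp per
generation by default, generation time 1 year — fonio is annual).

Design choices worth stating explicitly:

* **No recombination within a locus or window, free recombination between
  them.** This mirrors the non-recombining-segment design used for SFS
  bootstrapping and makes window genealogies exchangeable units.
* **No migration.** The accepted models for this system are
  divergence-without-gene-flow; migration events are deliberately out of
  scope.
* **Diploids are consecutive haplotype pairs.** Sample sizes are given in
  diploids; haploid counts are twice that.
* **Selfing** (fonio self-fertilises at ~99%) is not modelled explicitly;
  where needed it can be approximated by rescaling $N$, and it is off by
  default.
* The two-pair study demography is packaged as `two_pair_model()`:
  within-pair splits at 25,000 and 10,000 generations, a deep between-pair
  split (150,000 generations by default, i.e. several-fold older), sizes
  of order $10^4$, and optional post-divergence bottlenecks in the
  cultivated lineages that end 2,000–3,000 generations ago and are
  followed by expansion — the time scales the real system is reported to
  occupy.

What simulated data do *not* emulate: sequencing error, reference bias,
depth-dependent missingness structure, linked selection, and real LD decay
within windows. Tests passing on simulations therefore validate the
estimators and the inference machinery, not the upstream bioinformatics.

## Diversity statistics

`window_diversity()` computes $S$, $\pi$, Watterson's $\theta_W$ and
Tajima's D in sliding windows (default 50 kb / 10 kb step, the scale used
for the real data). Within each population, sites missing in more than
20% of that population's individuals are dropped. $\pi$ uses the
unbiased per-site estimator $2d(n-d)/(n(n-1))$ from pairwise-complete
allele counts; $\theta_W$ divides $S$ by $a_{n-1}=\sum_{i<n} 1/i$ at the
median haploid sample size of the window; D uses the standard (1989)
variance constants and is reported as `NA` when $S=0$ rather than 0.
Per-site values are normalised by the full window length (the number of
genotyped sites is reported alongside as `sites_used`, so users can
re-normalise by accessible sites if they prefer).

`dxy_da()` returns the mean cross-population per-site difference and the
net divergence $d_a = d_{xy} - (\pi_A+\pi_B)/2$ (which may legitimately
be negative). `ld_decay()` bins pairwise $r^2$ of genotype codes by
distance up to 500 kb (1 kb bins by default).

## Site-frequency spectra

`folded_sfs()` / `joint_folded_sfs()` index sites by minor-allele count,
excluding sites genotyped in fewer than 80% of individuals (the threshold
used for the real data). Sites with more genotypes than the target
dimension are *down-sampled hypergeometrically* with a fixed seed rather
than projected in expectation — the simplest policy that gives every site
the same spectrum dimension. Joint folding reflects entries whose total
allele count exceeds half the combined sample; the half-total diagonal is
merged deterministically onto the cell with the smaller first index. On
complete (simulated) data, `min_presence = 1` keeps the full dimension.

## k-mer diversity without a reference

`build_kmer_table()` decomposes per-individual sequences into canonical
31-mers (odd $k$, so no k-mer is its own reverse complement). Two filters
follow: a canonization-support filter — a k-mer is kept only when at
least 20% of its carriers observed it in both orientations, which on real
reads removes strand-artefact k-mers — and a presence/absence
minor-allele filter (count $\ge 2$, frequency $> 0.05$). Because the
orientation filter is only meaningful when both strands are scanned, the
builder scans each sequence and its reverse complement by default
(emulating reads from both strands); the filter can be disabled with
`min_canonized_fraction = NA`, which is appropriate for error-free
synthetic haplotypes. `jaccard_dissimilarity()` reproduces the
subsampling design used for the real data: 100 independent tables of
10,000 k-mers, within-group pairwise $1-|A\cap B|/|A\cup B|$ computed
inside each table, with the per-pair union taken within the subtable.

## Ancestry estimation

`snmf_ancestry()` factorises the rescaled genotype matrix
$X \in [0,1]^{n\times L}$ as $QF$ with $Q$ rows on the probability
simplex and $F \in [0,1]$, by alternating damped least squares: each
update is projected (clamping for $F$, exact Euclidean simplex projection
for $Q$) and then damped toward the previous value until the objective
does not increase, so the fit objective is monotone by construction.
Missing genotypes are excluded from the residuals via EM-style
imputation inside the solver (PCA, by contrast, mean-imputes — a
documented asymmetry). Per run, 5% of observed entries are masked and
the binomial cross-entropy of their predictions is the held-out
criterion; `choose_K()` selects the K minimising mean cross-entropy over
10 runs (ties to the smaller K). The sparsity weight `alpha` defaults to
0 (plain constrained factorisation) because no value is reported for the
real analysis; it is exposed as a parameter. Convergence: relative
objective change below $10^{-6}$ or 200 iterations; cross-entropy clamps
probabilities at $10^{-12}$.

## Topology weighting and the drift tree

`window_nj_trees()` builds one NJ tree per window from genotype
p-distances (mean absolute code difference / 2, pairwise-complete),
clipping negative NJ branch lengths at zero. `twisst_weights()` then
asks, for every combination of one tip per group (four groups), which of
the three unrooted quartet topologies the tree induces; the induced
quartet is read off topological distances with unit branch lengths, which
is exact for binary trees. Enumeration is exhaustive up to
`max_subsamples` combinations (the vectorised enumeration makes exact
weighting feasible for the study's group sizes) and seeded uniform
sampling beyond. Two summaries are reported, because "windows supporting
a topology" can mean either: the mean weight of each topology across
windows, and the fraction of windows in which each topology has maximum
weight (the headline statistic uses the latter).

`allele_freq_covariance()` centres each SNP's population frequencies by
the across-population mean and subtracts the binomial sampling term
$\overline{p(1-p)/2n}$ from the diagonal. `fit_population_tree()` fits
the drift model — covariance equals shared root-path branch length —
*pushed through the same centering*, by exhaustive rooted-topology search
(≤ 6 populations) with nonnegative least squares on branch lengths.
Centering makes the two root edges collinear (the root position is
unidentifiable from covariances alone), so collinear design columns are
merged; the small negative eigenvalue that the diagonal correction
introduces is silently projected away, with a warning only when the
deficit is substantial. `bootstrap_tree()` resamples SNP blocks (500–1000
SNPs) with replacement and reports the majority-rule consensus with
per-split support.

## SFS demographic inference

`expected_sfs()` estimates the expected folded joint spectrum of a
population pair by simulating genealogies and accumulating *branch
lengths* per descendant-count class (lower variance than mutation
dropping, which is also implemented). `composite_log_likelihood()` is
the multinomial composite likelihood over polymorphic classes with
expected proportions floored at $10^{-12}$.

Two numerical points matter in practice and are defaults here:

* **Scale anchoring and profiling.** Folded SFS *proportions* are
  invariant under a joint rescaling of all sizes and times, so they
  identify only ratios. When the total sequence length behind the
  observed spectrum is supplied (`total_bp`), the optimizer adds a
  per-site binomial term for the number of segregating sites with
  polymorphism probability $\mu\,E[\text{tree length}]$, which anchors
  the absolute scale through the fixed mutation rate — the
  infinite-sites analogue of fitting with monomorphic counts. Because
  that same invariance makes the expected tree length exactly linear in
  the joint scale, the optimal rescaling of every size and time
  parameter has a closed form given any proposed shape, and each
  likelihood evaluation profiles the global scale out analytically —
  removing the stiffest direction from the numerical search.
* **Noise control.** Each likelihood evaluation is Monte-Carlo; rare
  classes whose observed count is below 10 are pooled into one aggregate
  class (pooling is defined by the observed spectrum, hence identical
  across parameter values), and all evaluations within an optimizer run
  reuse one fixed stream of engine random numbers (common random
  numbers), making the surface deterministic for comparison purposes.

`optimize_model()` follows the 40-cycle stochastic schedule: uniform
(or log-uniform) proposals within the current ranges (with a denser
first-cycle exploration of the prior box), re-centring on the incumbent
and halving the ranges after three non-improving cycles, with
independent restarts (`n_runs`). A final estimation stage starts from
the best runs' point values and polishes them with an adaptive
random-direction line search on the fixed-seed surface — random
directions traverse the correlated time/size ridges that trap
axis-aligned or simplex methods on a jagged Monte-Carlo surface —
followed by a short high-precision pass and an axis-wise grid
tightening. `compare_models()`
ranks fits by AIC ($2k - 2\ln \hat L$); `parametric_bootstrap()` refits
pseudo-observed spectra simulated at the point estimates — initialised
from those values — and reports percentile 95% intervals, flagging the
result unreliable below 10 successful refits.

The six 4-population topologies used for the real data live in
supplementary material rather than the main text, so
`four_pop_templates()` ships a generic default set (three balanced
pairings, three ladders); the two-population divergence(+bottleneck)
template `tmpl_divergence_pair()` parameterises the bottleneck end as a
fraction of the divergence time (`B_FRAC`), which keeps every proposal
internally consistent during optimisation. Default priors are
log-uniform on sizes ($10^3$–$10^6$) and divergence time
($10^3$–$2\times10^5$ generations), uniform on the fraction. Exact prior
bounds for the real analysis are likewise supplementary-only; users
replicating it should set them from that source.

## Study-scale experiments and problem sizes

The `experiment_*()` functions re-run the headline analyses on synthetic
data at sizes chosen to finish on a single desktop core:

* `experiment_twisst_separation()`: 500 independent 50 kb windows, group
  sizes 21/8/19/6 diploids, exact enumeration (~19,000 quartets per
  window).
* `experiment_drift_tree()`: 10,000 unlinked SNPs (one segregating site
  per genealogy, branch-sampled).
* `experiment_divergence_recovery()`: ~50,000 segregating sites from
  1 kb non-recombining loci; truths for the two pairs place the
  divergence at 25,000 (white) and 10,000 (black) generations with
  post-divergence bottlenecks ending 2,000 / 3,000 generations ago. The
  fitted sizes around those times ($N$ of order $2\times10^3$–$5\times
  10^4$) are the package's own synthetic stand-ins — the real fitted
  values are supplementary-only — chosen so that bottleneck and
  diversity contrasts are of realistic magnitude. Three optimizer
  restarts, 5,000 genealogies per evaluation, 10,000 in refinement.
* `experiment_bottleneck_choice()`: the same design at ~30,000 sites,
  comparing the bottleneck and constant-size variants by AIC.

At these sizes, divergence-time recovery lands within about 5–15% of the
simulation truth; the residual error is a mix of data realisation noise,
Monte-Carlo likelihood noise, and genuine flatness of the composite
surface along the time/ancestral-size ridge. Recovery of the cultivated
present-day size `N_C` is markedly weaker — a recent post-bottleneck
expansion leaves few coalescences to date — and that parameter should be
read with its bootstrap interval, not as a point value.

## Degenerate inputs and tie-breaks

Windows with $S=0$ report D as undefined; NJ windows with fewer than 4
usable tips are skipped and logged; monomorphic locus pairs are excluded
from LD with a count of undefined pairs; Jaccard pairs with an empty
union within a subtable are `NA` and flagged; drift-tree topology ties
break on the newick string; equal-ancestry ties in `assign_clusters()`
resolve to the first maximum; the optimizer treats invalid parameter
combinations (e.g. a bottleneck outliving its divergence) as
$-\infty$ likelihood rather than errors.

## A small end-to-end run

```{r, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "foniokit")
out <- run_pipeline(cfg)
make_report(out)
```

The pipeline executes simulate → qc → diversity → k-mers → structure →
topology (→ demography if enabled), writes TSV/JSON/newick artifacts and
a manifest with per-stage seeds derived deterministically from the global
seed, and `make_report()` condenses them into one JSON and one text
report.

## Known limitations

* The simulator has no recombination within windows; window trees are
  single genealogies, so topology-weight variance between windows is
  somewhat higher than for real 50 kb windows with internal
  recombination.
* The composite likelihood treats sites within a locus as independent;
  with 1 kb loci this mildly overstates information, which the parametric
  bootstrap (resimulating whole segments) accounts for.
* The drift tree assumes pure drift on a tree; it reports — but cannot
  correct — misfit from unmodelled migration.
* The sNMF-style factorisation reproduces the estimator class, not any
  specific software's internals; cross-entropy values are comparable
  within this package only.
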