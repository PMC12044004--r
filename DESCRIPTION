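Package: foniokit
Title: Population-Genomic Inference of Independent Crop Domestication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether two cultivated lineages were domesticated
    independently from their wild relatives, built around the white and black
    fonio millet (Digitaria exilis / D. iburua) study system. Provides a
    coalescent simulator for two-pair domestication demographies (splits,
    bottlenecks, expansions), sliding-window diversity and divergence
    statistics (S, pi, Watterson's theta, Tajima's D, dxy, da, LD decay),
    reference-free k-mer presence/absence diversity with Jaccard
    dissimilarities, PCA and sparse-NMF-style ancestry estimation with
    cross-validation, neighbour-joining window trees with topology weighting,
    allele-frequency covariance (drift) population trees, and composite
    likelihood demographic model comparison from folded joint site-frequency
    spectra with AIC ranking and parametric bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    pracma,
    vcfR,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
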