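# deterministic toy genotype matrices and VCF text used across tests

toy_genotypes <- function(n = 6, L = 10, seed = 42, miss = 0,
                          pops = NULL) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (miss > 0) g[stats::runif(n * L) < miss] <- NA_integer_
  genotype_matrix(g, chrom = rep("chr1", L), pos = seq_len(L) * 100L,
                  individual_ids = sprintf("ind%02d", seq_len(n)),
                  pop_labels = pops)
}

random_genotype_matrix <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  L <- sample(5:25, 1)
  g <- matrix(sample(c(0:2, NA), n * L, replace = TRUE,
                     prob = c(.4, .2, .3, .1)), n, L)
  half <- L %/% 2
  chrom <- c(rep("c1", half), rep("c2", L - half))
  pos <- c(seq_len(half), seq_len(L - half)) * 10L
  genotype_matrix(g, chrom = chrom, pos = pos,
                  individual_ids = sprintf("s%d", seq_len(n)))
}

vcf_text <- function(records, samples = c("A", "B", "C")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

write_vcf_text <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

# simple two-population model for simulation-backed tests
split_model <- function(t_split = 20000, n1 = 1e4, n2 = 1e4, n_anc = 1e4,
                        mu = 6.5e-9) {
  demographic_model(c("A", "B"), c(n1, n2),
                    list(event_split(t_split, "A", "B"),
                         event_size_change(t_split, "B", n_anc)),
                    mu = mu)
}
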