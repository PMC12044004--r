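# derive a reproducible per-stage seed from the global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, qc = 2L, diversity = 3L, kmers = 4L,
            structure = 5L, topology = 6L, demography = 7L)
  as.integer((as.double(seed) * 7919 + offs[[stage]] * 104729) %% 2147483647)
}

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "foniokit_run",
    stages = list(simulate = TRUE, qc = TRUE, diversity = TRUE,
                  kmers = FALSE, structure = TRUE, topology = TRUE,
                  demography = FALSE),
    simulate = list(n_windows = 40, window_len = 50000,
                    samples = c(exilis = 6, longiflora = 4, iburua = 6,
                                ternata = 4),
                    model = "two_pair_bottleneck"),
    qc = list(max_locus_missing = 0.05, max_indiv_missing = 0.40,
              maf_min = 0.05),
    diversity = list(window_size = 50000, window_step = 10000),
    kmers = list(k = 31, n_tables = 20, table_size = 2000),
    structure = list(K = 2, n_runs = 3),
    topology = list(min_snps_per_window = 20),
    demography = list(pair = c("exilis", "longiflora"), cycles = 6,
                      n_sims = 500, n_proposals = 4)
  )
}

load_config <- function(cfg) {
  base <- default_config()
  user <- if (is.character(cfg)) yaml::read_yaml(cfg) else cfg
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, user)
  if (isTRUE(cfg$stages$structure) || isTRUE(cfg$stages$diversity) ||
      isTRUE(cfg$stages$topology)) {
    if (!isTRUE(cfg$stages$simulate) && is.null(cfg$input$vcf))
      stop("config invalid: downstream stages enabled without a simulate ",
           "stage or an input VCF")
    if (!isTRUE(cfg$stages$simulate) && is.null(cfg$input$labels))
      stop("config invalid: population labels required for analysis stages")
  }
  cfg
}

pipeline_log <- function(..., file = NULL) {
  msg <- sprintf("[foniokit %s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order
#' simulate -> qc -> diversity -> kmers -> structure -> topology ->
#' demography, writing per-stage artifacts (TSV/JSON/newick) and a manifest
#' into the output directory. The global seed expands into fixed per-stage
#' seeds so stages can be rerun in isolation; given the same configuration
#' the deterministic stages are bit-identical across runs.
#'
#' @param config a configuration list or the path to a YAML file; see
#'   `foniokit:::default_config()` for the recognised fields.
#' @return the output directory path, invisibly; artifacts and
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "pipeline.log")
  manifest <- list(package_version = as.character(utils::packageVersion("foniokit")),
                   seed = cfg$seed, stages = list())
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  g <- NULL
  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    sd <- stage_seed(cfg$seed, "simulate")
    pipeline_log("simulate: ", cfg$simulate$n_windows, " windows", file = logf)
    model <- if (identical(cfg$simulate$model, "two_pair_bottleneck"))
      two_pair_model(sizes = c(5e3, 5e4, 1e4, 5e4),
                     bottleneck_sizes = c(1e3, 2e3))
    else two_pair_model()
    sim <- simulate_windows(model, unlist(cfg$simulate$samples),
                            cfg$simulate$n_windows,
                            cfg$simulate$window_len, seed = sd)
    g <- sim$genotypes
    write_vcf(g, file.path(out, "simulated.vcf.gz"))
    writeLines(sim$true_trees, file.path(out, "true_trees.nwk"))
    manifest$stages$simulate <- list(seed = sd, n_snps = n_loci(g))
  } else if (!is.null(cfg$input$vcf)) {
    g <- read_vcf(cfg$input$vcf)
    if (!is.null(cfg$input$labels)) g <- read_pop_labels(g, cfg$input$labels)
  }
  if (is.null(g)) stop("no input: enable the simulate stage or provide input$vcf")

  if (isTRUE(cfg$stages$qc)) {
    th <- qc_thresholds(cfg$qc$max_locus_missing, cfg$qc$max_indiv_missing,
                        cfg$qc$maf_min)
    g <- filter_genotypes(g, th)
    rep <- attr(g, "filter_report")
    jsonlite::write_json(rep, file.path(out, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    pipeline_log("qc: retained ", rep$retained_loci, " loci", file = logf)
    manifest$stages$qc <- rep
  }

  if (isTRUE(cfg$stages$diversity)) {
    w <- window_spec(cfg$diversity$window_size, cfg$diversity$window_step)
    div <- window_diversity(g, w = w)
    utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pops <- unique(g$pop_labels)
    dx <- dxy_da(g, pops[1], pops[2], w = w)
    utils::write.table(dx, file.path(out, "dxy_da.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$diversity <- list(n_windows = nrow(div))
    pipeline_log("diversity: ", nrow(div), " window rows", file = logf)
  }

  if (isTRUE(cfg$stages$kmers)) {
    sd <- stage_seed(cfg$seed, "kmers")
    if (is.null(sim)) stop("kmers stage requires the simulate stage")
    fdir <- file.path(out, "fasta")
    paths <- emit_sequences(sim, fdir)
    kt <- build_kmer_table(paths, k = cfg$kmers$k,
                           min_canonized_fraction = NA)
    jd <- jaccard_dissimilarity(kt, split(g$individual_ids, g$pop_labels),
                                n_tables = cfg$kmers$n_tables,
                                table_size = cfg$kmers$table_size, seed = sd)
    utils::write.table(jd, file.path(out, "jaccard.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$kmers <- list(seed = sd, n_kmers = length(kt$kmers),
                                  group_means = as.list(attr(jd, "group_means")))
    pipeline_log("kmers: ", length(kt$kmers), " k-mers", file = logf)
  }

  if (isTRUE(cfg$stages$structure)) {
    sd <- stage_seed(cfg$seed, "structure")
    pc <- pca(g$genotypes)
    utils::write.table(pc$scores[, 1:min(10, ncol(pc$scores))],
                       file.path(out, "pca_scores.tsv"), sep = "\t",
                       quote = FALSE)
    anc <- snmf_ancestry(g, K = cfg$structure$K,
                         n_runs = cfg$structure$n_runs, seed = sd)
    Q <- anc$Q
    utils::write.table(Q, file.path(out, "ancestry_Q.tsv"), sep = "\t",
                       quote = FALSE, col.names = FALSE)
    manifest$stages$structure <- list(seed = sd, K = anc$K,
                                      pca_var1 = pc$explained[1],
                                      cross_entropy = min(anc$cross_entropy))
    pipeline_log("structure: PCA PC1 ",
                 sprintf("%.1f%%", 100 * pc$explained[1]), file = logf)
  }

  if (isTRUE(cfg$stages$topology)) {
    sd <- stage_seed(cfg$seed, "topology")
    w <- window_spec(cfg$diversity$window_size, cfg$diversity$window_size)
    trees <- window_nj_trees(g, w, cfg$topology$min_snps_per_window)
    groups <- split(g$individual_ids, g$pop_labels)
    if (length(groups) == 4) {
      tw <- twisst_weights(trees, groups, seed = sd)
      utils::write.table(tw$weights, file.path(out, "twisst_weights.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$topology <- list(
        seed = sd, n_trees = length(trees),
        mean_weights = as.list(tw$mean_weights),
        max_weight_fraction = as.list(tw$max_weight_fraction))
    }
    W <- allele_freq_covariance(g)
    pt <- fit_population_tree(W)
    ape::write.tree(pt$tree, file.path(out, "population_tree.nwk"))
    manifest$stages$topology$variance_explained <- pt$variance_explained
    pipeline_log("topology: drift tree VE ",
                 sprintf("%.4f", pt$variance_explained), file = logf)
  }

  if (isTRUE(cfg$stages$demography)) {
    sd <- stage_seed(cfg$seed, "demography")
    pr <- cfg$demography$pair
    obs <- joint_folded_sfs(g, pr[1], pr[2], min_presence = 0.8, seed = sd)
    tmpl <- tmpl_divergence_pair(bottleneck = TRUE, pop_names = pr)
    n_dip <- vapply(pr, function(p) length(pop_index(g, p)), integer(1))
    fit <- optimize_model(tmpl, default_pair_priors(tmpl), obs,
                          stats::setNames(n_dip, pr),
                          cycles = cfg$demography$cycles,
                          n_sims = cfg$demography$n_sims,
                          n_proposals = cfg$demography$n_proposals,
                          seed = sd)
    jsonlite::write_json(list(model = fit$model_id,
                              params = as.list(fit$params),
                              lnl = fit$lnl, aic = fit$aic),
                         file.path(out, "demography_fit.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$stages$demography <- list(seed = sd, lnl = fit$lnl)
    pipeline_log("demography: lnL ", sprintf("%.1f", fit$lnl), file = logf)
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Summarise pipeline outputs into a report
#'
#' Collects the per-stage artifacts of a [run_pipeline()] output directory
#' into one machine-readable JSON and one human-readable text report;
#' missing stages are marked absent. Regeneration is idempotent.
#'
#' @param out_dir pipeline output directory.
#' @return the report list, invisibly; writes `report.json` and
#'   `report.txt` in `out_dir`.
#' @export
make_report <- function(out_dir) {
  rep <- list()
  txt <- c("foniokit pipeline report", "========================")
  f <- function(...) file.path(out_dir, ...)
  if (file.exists(f("diversity.tsv"))) {
    div <- utils::read.table(f("diversity.tsv"), header = TRUE, sep = "\t")
    agg <- stats::aggregate(cbind(pi, theta_w) ~ pop, div, mean)
    rep$diversity <- agg
    txt <- c(txt, "", "Per-population mean diversity (per site):",
             utils::capture.output(print(agg)))
  } else rep$diversity <- "absent"
  if (file.exists(f("jaccard.tsv"))) {
    jd <- utils::read.table(f("jaccard.tsv"), header = TRUE, sep = "\t")
    gm <- stats::aggregate(dissimilarity ~ group, jd, mean)
    rep$jaccard <- gm
    txt <- c(txt, "", "Mean within-group k-mer Jaccard dissimilarity:",
             utils::capture.output(print(gm)))
  } else rep$jaccard <- "absent"
  man <- if (file.exists(f("manifest.json")))
    jsonlite::read_json(f("manifest.json")) else list()
  for (sec in c("structure", "topology", "demography")) {
    if (!is.null(man$stages[[sec]])) {
      rep[[sec]] <- man$stages[[sec]]
      txt <- c(txt, "", paste0(sec, ":"),
               paste0("  ", names(man$stages[[sec]]), " = ",
                      vapply(man$stages[[sec]], function(x)
                        paste(format(unlist(x)), collapse = ","),
                        character(1))))
    } else rep[[sec]] <- "absent"
  }
  jsonlite::write_json(rep, f("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  writeLines(txt, f("report.txt"))
  invisible(rep)
}
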