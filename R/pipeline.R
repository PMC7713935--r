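# Pipeline orchestration: YAML configuration, staged execution with
# deterministic TSV/JSON outputs, and a run manifest recording the seed, the
# parameter set and per-file checksums.

#' Default pipeline configuration
#'
#' Stage parameters default to the study's values: CPM >= 1 in >= 2 samples,
#' TMM normalization, 40% variance prefilter, FDR 0.05, signed-hybrid network
#' with deepSplit 2 / minModuleSize 30 / mergeCutHeight 0.15 / max block
#' 10,000, 250 bootstrap networks with 10% overlap and 70% reliability,
#' r > .85 consensus merging, k = 4 nMDS and 1,000 permutations.
#'
#' @param seed master seed.
#' @param ... overrides for any entry (e.g. `n_boot = 50`).
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    simulate = list(enabled = TRUE, n_genes = 2000),
    input = list(counts = NULL, design = NULL, gene_sets = NULL),
    preprocess = list(min_cpm = 1, min_samples = 2, drop_fraction = 0.40,
                      prior_count = 0.5),
    de = list(fdr = 0.05, prior_df = 10,
              contrasts = names(standard_contrasts())),
    network = list(maxBlockSize = 10000, minModuleSize = 30, deepSplit = 2,
                   mergeCutHeight = 0.15, beta = NULL),
    consensus = list(n_boot = 250, overlap_frac = 0.10, reliability = 0.70,
                     merge_r = 0.85, min_size = 30),
    eigengene = list(epsilon = 0.5, ratio = 2),
    ordinate = list(k = 4, n_perm = 1000, n_starts = 20, log_abundance = FALSE),
    enrich = list(min_term_size = 3, fdr = 0.05)
  )
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    else cfg[[nm]] <- override[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; entries override [default_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_config, c(list(seed = user$seed %||% 1),
                            user[setdiff(names(user), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages: simulate (or load inputs), preprocess, de, network, consensus,
#' eigengene, ordinate, enrich. Each stage writes deterministic TSV/JSON
#' outputs under `outdir`; a `manifest.json` records the seed, the full
#' parameter set, completed stages, and an md5 checksum per output file. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [default_config()] list (or path to a YAML file).
#' @param outdir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = "bootmods_run") {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  if (cfg$consensus$n_boot < 1) .stopf("bootstrap requires >=1 replicate")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages_done <- character(0)
  run_stage <- function(name, fun) {
    .log_msg("stage %s ...", name)
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    .log_msg("stage %s done (%.1fs)", name, as.numeric(Sys.time() - t0, units = "secs"))
    stages_done <<- c(stages_done, name)
    out
  }

  sim <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    inputs <- run_stage("simulate", function() {
      sim <- simulate_experiment(fixture_config(
        seed = cfg$seed, n_genes = cfg$simulate$n_genes))
      write_fixture(sim, file.path(outdir, "fixture"))
      files <<- c(files, file.path(outdir, "fixture",
                                   c("counts.tsv", "design.tsv", "truth.tsv", "annotation.tsv")))
      sim
    })
    sim <- inputs
    cm <- sim$counts; design <- sim$design; gsm <- sim$annotation
  } else {
    cm <- read_counts(cfg$input$counts)
    design <- read_design(cfg$input$design)
    gsm <- if (!is.null(cfg$input$gene_sets)) read_gene_sets(cfg$input$gene_sets) else NULL
    validate_samples(cm, design)
  }

  pp <- run_stage("preprocess", function() {
    fcm <- filter_low_expression(cm, cfg$preprocess$min_cpm, cfg$preprocess$min_samples)
    nf <- tmm_normalize(fcm)
    em <- log_cpm(fcm, nf, cfg$preprocess$prior_count)
    em_net <- variance_prefilter(em, cfg$preprocess$drop_fraction)
    files <<- c(files,
      write_counts(fcm, file.path(outdir, "filtered_counts.tsv")),
      .write_tsv(data.frame(sample_id = names(nf), tmm_factor = as.numeric(nf)),
                 file.path(outdir, "tmm_factors.tsv")),
      .write_tsv(data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE),
                 file.path(outdir, "log_cpm.tsv")))
    list(cm = fcm, nf = nf, em = em, em_net = em_net)
  })

  de <- run_stage("de", function() {
    disp <- estimate_dispersions(pp$cm, design, pp$nf, cfg$de$prior_df)
    res <- lapply(cfg$de$contrasts, function(cn) {
      tab <- fit_and_test(pp$cm, pp$nf, design, disp, cn)
      files <<- c(files, .write_tsv(tab, file.path(outdir, sprintf("de_%s.tsv", cn))))
      tab
    })
    names(res) <- cfg$de$contrasts
    venn <- NULL
    if (all(c("kauai_day7_vs_control", "mangaia_day7_vs_control") %in% names(res))) {
      venn <- venn_partition(res$kauai_day7_vs_control,
                             res$mangaia_day7_vs_control, cfg$de$fdr)
      p <- file.path(outdir, "venn_summary.json")
      jsonlite::write_json(venn, p, auto_unbox = TRUE, digits = NA)
      files <<- c(files, p)
    }
    list(tables = res, venn = venn, dispersions = disp)
  })

  net <- run_stage("network", function() {
    ma <- blockwise_modules(pp$em_net,
                            maxBlockSize = cfg$network$maxBlockSize,
                            beta = cfg$network$beta,
                            minModuleSize = cfg$network$minModuleSize,
                            deepSplit = cfg$network$deepSplit,
                            mergeCutHeight = cfg$network$mergeCutHeight,
                            seed = stage_seed(cfg$seed, "network"))
    files <<- c(files,
      .write_tsv(data.frame(gene_id = names(ma$labels), module_label = ma$labels),
                 file.path(outdir, "modules.tsv")))
    p <- file.path(outdir, "network_params.json")
    jsonlite::write_json(list(beta = attr(ma, "beta"), r2 = attr(ma, "r2"),
                              n_blocks = length(unique(attr(ma, "blocks")))),
                         p, auto_unbox = TRUE, digits = NA)
    files <<- c(files, p)
    ma
  })

  cons <- run_stage("consensus", function() {
    runs <- bootstrap_networks(pp$em_net, n_boot = cfg$consensus$n_boot,
                               beta = attr(net, "beta"),
                               maxBlockSize = cfg$network$maxBlockSize,
                               minModuleSize = cfg$network$minModuleSize,
                               deepSplit = cfg$network$deepSplit,
                               mergeCutHeight = cfg$network$mergeCutHeight,
                               seed = cfg$seed)
    cr <- consensus_filter(net, runs, cfg$consensus$reliability,
                           cfg$consensus$overlap_frac)
    cr <- finalize_consensus(pp$em_net, cr, cfg$consensus$merge_r,
                             cfg$consensus$min_size)
    files <<- c(files,
      .write_tsv(data.frame(gene_id = names(cr$labels), original_label = cr$original,
                            final_label = cr$labels, reliability = cr$reliability),
                 file.path(outdir, "consensus_modules.tsv")))
    p <- file.path(outdir, "consensus_audit.json")
    jsonlite::write_json(list(n_boot = cr$n_boot, audit = cr$audit), p,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <<- c(files, p)
    cr
  })

  eig <- run_stage("eigengene", function() {
    labels <- cons$labels
    mods <- setdiff(unique(labels), UNASSIGNED)
    if (length(mods)) {
      egs <- vapply(mods, function(m)
        module_eigengene(pp$em_net, names(labels)[labels == m])$scores,
        numeric(length(pp$em_net$sample_ids)))
      files <<- c(files,
        .write_tsv(data.frame(sample_id = pp$em_net$sample_ids, egs,
                              check.names = FALSE),
                   file.path(outdir, "eigengenes.tsv")),
        .write_tsv(module_anova_table(pp$em_net, labels, design),
                   file.path(outdir, "module_anova.tsv")),
        .write_tsv(classify_modules(pp$em_net, labels, design,
                                    cfg$eigengene$epsilon, cfg$eigengene$ratio),
                   file.path(outdir, "module_categories.tsv")))
    }
    invisible(NULL)
  })

  ord <- run_stage("ordinate", function() {
    ab <- normalized_abundance(pp$cm, pp$nf, log = cfg$ordinate$log_abundance)
    d <- bray_curtis(ab)
    mds <- nmds(d, k = cfg$ordinate$k, n_starts = cfg$ordinate$n_starts,
                seed = stage_seed(cfg$seed, "ordinate"))
    pmv <- permanova(d, design, n_perm = cfg$ordinate$n_perm,
                     seed = stage_seed(cfg$seed, "ordinate"))
    files <<- c(files,
      .write_tsv(data.frame(sample_id = rownames(mds$points), mds$points,
                            check.names = FALSE),
                 file.path(outdir, "nmds_coordinates.tsv")),
      .write_tsv(as.data.frame(pmv), file.path(outdir, "permanova.tsv")))
    p <- file.path(outdir, "nmds_stress.json")
    jsonlite::write_json(list(stress = mds$stress, k = cfg$ordinate$k,
                              converged = mds$converged),
                         p, auto_unbox = TRUE, digits = NA)
    files <<- c(files, p)
    list(d = d, mds = mds, permanova = pmv)
  })

  if (!is.null(gsm)) {
    run_stage("enrich", function() {
      universe <- pp$cm$gene_ids
      labels <- cons$labels
      mods <- setdiff(unique(labels), UNASSIGNED)
      rows <- lapply(mods, function(m) {
        tab <- fisher_enrichment(intersect(names(labels)[labels == m], universe),
                                 gsm, universe, cfg$enrich$min_term_size)
        cbind(module = m, tab)
      })
      if (length(rows))
        files <<- c(files, .write_tsv(do.call(rbind, rows),
                                      file.path(outdir, "enrichment.tsv")))
      invisible(NULL)
    })
  }

  manifest <- list(
    seed = cfg$seed,
    parameters = unclass(cfg),
    stages = stages_done,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
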