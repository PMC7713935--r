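# Negative-binomial count simulator with planted coexpression modules and full
# ground truth. The design mirrors the study layout: 2 populations x 3
# infestation stages x 3 pooled replicate libraries = 18 samples. Planted
# modules carry one of six response categories; module co-expression is induced
# by a per-module Gaussian latent factor added on the log2 scale with
# positive per-gene loadings, so modules are recoverable by a signed-hybrid
# network.

# Log2 fold-change profiles per category over the six design cells
# (kauai control/day4/day7, mangaia control/day4/day7), scaled by `effect`.
.category_profiles <- function(effect = 2) {
  list(
    shared_up   = c(0, effect / 2,  effect,      0, effect / 2,  effect),
    shared_down = c(0, -effect / 2, -effect,     0, -effect / 2, -effect),
    # same direction in both populations, much larger in kauai (ratio 3)
    I_amplified = c(0, 0.75 * effect, 1.5 * effect, 0, 0.25 * effect, 0.5 * effect),
    # response in kauai only
    II_one_population = c(0, effect / 2, effect,  0, 0, 0),
    # opposing day-7 responses
    III_opposed = c(0, effect / 2, effect,        0, -effect / 2, -effect),
    # day-4-only responses of opposite sign; both populations back to baseline
    # by day 7, so the difference is in the trajectory, not the day-7 contrast
    IV_timing   = c(0, effect, 0,                 0, -effect, 0)
  )
}

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 18 samples
#' (2 populations x 3 infestation stages x 3 pooled libraries), 10,000 genes,
#' two shared-response modules plus one module per population-by-infestation
#' category I-IV, and negative-binomial counts.
#'
#' @param n_genes total number of genes.
#' @param module_sizes named integer vector: planted module sizes by category.
#' @param within_module_cor target mean pairwise correlation of log-CPM
#'   profiles within a module (single value or one per module).
#' @param effect log2 fold change at the day-7 peak of the category profiles.
#' @param reps_per_group libraries per population x stage cell.
#' @param baseline_mean,baseline_sd log2-CPM baseline distribution. The default
#'   mean centres total CPM near 1e6 for `n_genes` genes.
#' @param dispersion negative-binomial dispersion phi: per-gene values are
#'   lognormal around this with `dispersion_sdlog` spread.
#' @param dispersion_sdlog lognormal sd of per-gene dispersions.
#' @param de_noise_frac fraction of non-module genes given independent random
#'   differential-expression shifts (DE but not co-expressed).
#' @param latent_frac minimum fraction of a module's covariance target carried
#'   by its module-specific latent factor (rather than the shared response
#'   profile); keeps modules with similar profiles separable.
#' @param lib_size_target mean library size; realized sizes vary uniformly
#'   within `lib_size_spread` of it.
#' @param lib_size_spread relative library-size spread (0.3 = +/-30%).
#' @param n_immune,n_stress sizes of the labeled "immune" and "stress"
#'   annotation sets (study-scale defaults 67 and 309).
#' @param seed master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       module_sizes = c(shared_up = 400, shared_down = 150,
                                        I_amplified = 120, II_one_population = 100,
                                        III_opposed = 60, IV_timing = 40),
                       within_module_cor = 0.8,
                       effect = 2,
                       reps_per_group = 3,
                       baseline_mean = log2(1e6 / n_genes) + 1,
                       baseline_sd = 2,
                       dispersion = 0.1,
                       dispersion_sdlog = 0.4,
                       de_noise_frac = 0.1,
                       latent_frac = 0.5,
                       lib_size_target = 5e6,
                       lib_size_spread = 0.3,
                       n_immune = 67,
                       n_stress = 309,
                       seed = 1) {
  if (sum(module_sizes) > n_genes) .stopf("module sizes exceed n_genes")
  if (dispersion <= 0) .stopf("dispersion must be positive")
  bad <- setdiff(names(module_sizes), names(.category_profiles()))
  if (length(bad)) .stopf("unknown module category: %s", bad[1])
  cor_vec <- rep_len(within_module_cor, length(module_sizes))
  if (any(cor_vec <= 0 | cor_vec >= 1)) .stopf("within_module_cor must be in (0,1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a two-population infestation RNA-seq experiment
#'
#' Counts are drawn as NB(mean = 2^(baseline + group shift + latent factor x
#' loading) x lib_size/1e6, dispersion phi_g). Each planted module shares one
#' N(0,1) latent factor per sample; per-gene loadings are calibrated against
#' the gene's expected log-scale sampling noise so the mean pairwise log-CPM
#' correlation within the module hits `within_module_cor`.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` ([count_matrix()]), `design` ([design_table()]),
#'   `truth` (data.frame gene_id/module_id/category), `modules` (list of
#'   per-module ground-truth records), and `annotation` ([gene_set_map()] with
#'   immune, stress and a random term).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "simulate"))

  n <- cfg$n_genes
  reps <- cfg$reps_per_group
  design <- design_table(data.frame(
    sample_id = sprintf("%s_%s_r%d",
                        rep(rep(POPULATIONS, each = 3 * reps), 1),
                        rep(rep(STAGES, each = reps), 2),
                        rep(seq_len(reps), 6)),
    population = rep(POPULATIONS, each = 3 * reps),
    infestation = rep(rep(STAGES, each = reps), 2)
  ))
  ns <- nrow(design)
  cell <- interaction(design$population, design$infestation, drop = TRUE)
  cell_index <- match(paste(design$population, design$infestation, sep = "."),
                      paste(rep(POPULATIONS, each = 3), rep(STAGES, 2), sep = "."))

  gene_ids <- sprintf("g%05d", seq_len(n))
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  phi <- stats::rlnorm(n, log(cfg$dispersion), cfg$dispersion_sdlog)
  lib <- round(cfg$lib_size_target *
                 stats::runif(ns, 1 - cfg$lib_size_spread, 1 + cfg$lib_size_spread))

  # assign module genes from the front; remainder are noise/unassigned
  profiles <- .category_profiles(cfg$effect)
  sizes <- cfg$module_sizes
  cor_vec <- rep_len(cfg$within_module_cor, length(sizes))
  module_id <- rep(UNASSIGNED, n)
  category <- rep(NA_character_, n)
  modules <- list()
  pos <- 0L
  # log2 shift per gene x sample, plus latent-factor contribution
  shift <- matrix(0, n, ns)
  for (m in seq_along(sizes)) {
    cat_m <- names(sizes)[m]
    idx <- pos + seq_len(sizes[[m]])
    pos <- pos + sizes[[m]]
    mid <- sprintf("M%d", m)
    module_id[idx] <- mid
    category[idx] <- cat_m
    prof <- profiles[[cat_m]]
    responsiveness <- stats::runif(length(idx), 0.8, 1.2)
    shift[idx, ] <- outer(responsiveness, prof[cell_index])
    # latent factor: loadings calibrated per gene so cor(log-CPM) ~ target.
    # Centered within design cells so planted co-expression is orthogonal to
    # the condition structure (the category response profile alone carries the
    # design signal), then standardized so realized factor variance is 1.
    f <- stats::rnorm(ns)
    f <- f - stats::ave(f, cell_index)
    f <- f / stats::sd(f)
    rho <- cor_vec[m]
    mu_expect <- 2^(baseline[idx]) * mean(lib) / 1e6 # expected baseline count
    v_noise <- (1 / mu_expect + phi[idx]) / log(2)^2 # delta-method log2 noise var
    # the shared response profile already correlates module genes; the latent
    # factor supplies the remainder of the covariance target, but never less
    # than `latent_frac` of it, so modules with near-collinear response
    # profiles remain separable by their module-specific co-variation
    var_profile <- stats::var(prof[cell_index])
    target_cov <- rho / (1 - rho) * v_noise
    lam <- sqrt(pmax(target_cov - var_profile, cfg$latent_frac * target_cov))
    shift[idx, ] <- shift[idx, ] + outer(lam, f)
    modules[[mid]] <- list(
      module_id = mid, category = cat_m, gene_ids = gene_ids[idx],
      effect_profile = matrix(prof, 2, 3, byrow = TRUE,
                              dimnames = list(POPULATIONS, STAGES)),
      within_module_cor = rho, latent = f
    )
  }
  # independent DE noise genes among the unassigned
  free <- which(module_id == UNASSIGNED)
  n_de_noise <- floor(cfg$de_noise_frac * length(free))
  if (n_de_noise > 0) {
    dn <- sample(free, n_de_noise)
    for (g in dn) {
      prof <- c(0, stats::rnorm(2, 0, cfg$effect / 2), 0, stats::rnorm(2, 0, cfg$effect / 2))
      shift[g, ] <- prof[cell_index]
    }
    category[dn] <- "de_noise"
  }

  log2cpm_mean <- baseline + shift
  mu <- 2^log2cpm_mean * matrix(lib, n, ns, byrow = TRUE) / 1e6
  counts <- matrix(
    stats::rnbinom(n * ns, mu = mu, size = rep(1 / phi, ns)),
    n, ns, dimnames = list(gene_ids, design$sample_id)
  )
  # enforce target library sizes approximately by construction only; realized
  # lib sizes are the column sums, as in real data
  cm <- count_matrix(counts)

  truth <- data.frame(gene_id = gene_ids, module_id = module_id,
                      category = ifelse(is.na(category), "none", category))

  # labeled annotation sets: immune overlaps one planted module heavily so
  # enrichment has a recoverable target; stress and a random term are controls
  first_mod <- if (length(modules)) modules[[1]]$gene_ids else character(0)
  n_immune <- min(cfg$n_immune, n)
  n_stress <- min(cfg$n_stress, n)
  n_imm_in <- min(n_immune, length(first_mod))
  immune <- c(first_mod[seq_len(n_imm_in)],
              sample(setdiff(gene_ids, first_mod), max(0, n_immune - n_imm_in)))
  stress <- sample(gene_ids, n_stress)
  rand <- sample(gene_ids, n_stress)
  annotation <- gene_set_map(
    list(immune_system_process = immune,
         response_to_stress = stress,
         random_k = rand),
    term_names = c(immune_system_process = "immune system process",
                   response_to_stress = "response to stress",
                   random_k = "random control set")
  )

  list(counts = cm, design = design, truth = truth, modules = modules,
       annotation = annotation, config = cfg)
}

#' Write a simulated experiment as a pipeline fixture
#'
#' Writes counts.tsv, design.tsv, truth.tsv and annotation.tsv in the
#' pipeline's interchange formats.
#'
#' @param sim result of [simulate_experiment()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(outdir, "counts.tsv"))
  write_design(sim$design, file.path(outdir, "design.tsv"))
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(sim$annotation, file.path(outdir, "annotation.tsv"))
  invisible(outdir)
}

#' Desk-scale fixture configuration
#'
#' 2,000 genes with the same six planted module categories at reduced sizes;
#' used by the examples and the test suite.
#'
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
fixture_config <- function(seed = 1, ...) {
  sizes <- c(shared_up = 150, shared_down = 120, I_amplified = 100,
             II_one_population = 80, III_opposed = 60, IV_timing = 40)
  n_genes <- list(...)$n_genes %||% 2000
  if (n_genes < 2000) # keep the planted fraction when scaled below fixture size
    sizes <- pmax(round(sizes * n_genes / 2000), 2)
  args <- list(
    n_genes = 2000,
    module_sizes = sizes,
    n_immune = min(67, floor(n_genes / 4)), n_stress = min(150, floor(n_genes / 4)),
    seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
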