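# Bootstrap module-stability consensus: networks are rebuilt on with-replacement
# resamples of the samples, resampled modules are matched to original modules by
# a 10% overlap rule, and a gene keeps its original module only if it is
# supported in at least 70% of replicates. Surviving modules are then merged at
# eigengene r > .85 and modules below the minimum size dissolved. Because genes
# can only be demoted, the final topology is biased toward the modules built
# from the full data: no new module can appear.

#' Build networks on bootstrap resamples of the samples
#'
#' Each replicate draws `n` sample columns with replacement (duplicates enter
#' the correlations with their multiplicity) and reruns [blockwise_modules()]
#' with the same parameters as the original network, including its
#' soft-threshold power. Replicates whose resample leaves more than half the
#' genes without expression variance are redrawn (logged).
#'
#' @param em an `expression_matrix`.
#' @param n_boot number of bootstrap networks (study default 250).
#' @param beta soft-threshold power of the original network.
#' @param maxBlockSize,minModuleSize,deepSplit,mergeCutHeight network
#'   parameters, as in [blockwise_modules()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return list of `bootstrap_run`s: each has `replicate`, `sample_idx`, and
#'   `assignment` (a `module_assignment`).
#' @export
bootstrap_networks <- function(em, n_boot = 250, beta,
                               maxBlockSize = 10000, minModuleSize = 30,
                               deepSplit = 2, mergeCutHeight = 0.15,
                               seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (n_boot < 1) .stopf("bootstrap requires >=1 replicate")
  ns <- length(em$sample_ids)
  runs <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(stage_seed(seed, "consensus", b))
    repeat {
      idx <- sample.int(ns, ns, replace = TRUE)
      sub <- em
      sub$values <- em$values[, idx, drop = FALSE]
      sub$sample_ids <- sprintf("bs%d_%d", seq_len(ns), idx)
      colnames(sub$values) <- sub$sample_ids
      v <- apply(sub$values, 1, stats::var)
      if (mean(v == 0) <= 0.5) break
      .log_msg("replicate %d: degenerate resample, redrawing", b)
    }
    ma <- blockwise_modules(sub, maxBlockSize = maxBlockSize, beta = beta,
                            minModuleSize = minModuleSize, deepSplit = deepSplit,
                            mergeCutHeight = mergeCutHeight,
                            seed = stage_seed(seed, "consensus", b))
    runs[[b]] <- structure(list(replicate = b, sample_idx = idx, assignment = ma),
                           class = "bootstrap_run")
  }
  runs
}

#' Match resampled modules to original modules by overlap
#'
#' A resampled module corresponds to an original module when it contains at
#' least `overlap_frac` of the original module's genes (boundary inclusive);
#' the overlapping genes are then marked as supporting that original module in
#' this replicate. One resampled module may correspond to several original
#' modules, in which case its genes are divided among them by their original
#' labels. The unassigned label never matches.
#'
#' @param original,resampled `module_assignment`s over the same genes.
#' @param overlap_frac minimum fraction of the original module contained in
#'   the resampled module.
#' @return logical vector over genes: supported toward the gene's own original
#'   module in this replicate.
#' @export
match_modules <- function(original, resampled, overlap_frac = 0.10) {
  lo <- original$labels
  lr <- resampled$labels[names(lo)]
  if (anyNA(lr)) .stopf("resampled assignment misses %d gene(s)", sum(is.na(lr)))
  supported <- stats::setNames(rep(FALSE, length(lo)), names(lo))
  orig_mods <- setdiff(unique(lo), UNASSIGNED)
  res_mods <- setdiff(unique(lr), UNASSIGNED)
  if (!length(orig_mods) || !length(res_mods)) return(supported)
  ov <- table(factor(lo, orig_mods), factor(lr, res_mods))
  orig_sizes <- table(factor(lo, orig_mods))
  for (o in orig_mods) {
    # epsilon guard keeps the inclusive boundary exact under floating point
    # (e.g. 10 genes of 100 at overlap_frac 0.10)
    hits <- res_mods[ov[o, ] >= overlap_frac * orig_sizes[[o]] - 1e-9]
    if (length(hits))
      supported[lo == o & lr %in% hits] <- TRUE
  }
  supported
}

#' Filter an assignment by bootstrap reliability
#'
#' A gene keeps its original label iff it was supported in at least
#' `reliability` of the replicates (boundary inclusive); otherwise it is moved
#' to the unassigned bin. Originally unassigned genes stay unassigned.
#'
#' @param original a `module_assignment`.
#' @param runs list of `bootstrap_run`s from [bootstrap_networks()].
#' @param reliability minimum supported fraction.
#' @param overlap_frac forwarded to [match_modules()].
#' @return a `consensus_result`: list with `labels` (filtered), `original`
#'   labels, `reliability` (per-gene supported fraction), `n_boot`.
#' @export
consensus_filter <- function(original, runs, reliability = 0.70,
                             overlap_frac = 0.10) {
  if (!length(runs)) .stopf("bootstrap requires >=1 replicate")
  support <- rowSums(vapply(runs, function(r)
    match_modules(original, r$assignment, overlap_frac),
    logical(length(original$labels))))
  rel <- support / length(runs)
  labels <- original$labels
  assigned <- labels != UNASSIGNED
  labels[assigned & rel < reliability - 1e-9] <- UNASSIGNED
  structure(list(labels = labels, original = original$labels,
                 reliability = stats::setNames(rel, names(original$labels)),
                 n_boot = length(runs)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  kept <- sum(x$labels != UNASSIGNED)
  was <- sum(x$original != UNASSIGNED)
  cat(sprintf("consensus_result: %d/%d originally assigned genes retained (%d replicates)\n",
              kept, was, x$n_boot))
  invisible(x)
}

#' Finalize a consensus assignment: merge, size cleanup, renumbering
#'
#' Merges surviving modules whose eigengene correlation is strictly greater
#' than `merge_r`, then dissolves named modules with fewer than `min_size`
#' genes (a module at exactly `min_size` is kept) and renumbers labels by
#' decreasing size.
#'
#' @param em an `expression_matrix` covering the genes.
#' @param cr a [consensus_filter()] result.
#' @param merge_r eigengene correlation above which modules merge (strict).
#' @param min_size minimum surviving module size.
#' @return the finalized `consensus_result` with an `audit` table of per-module
#'   retained/demoted counts.
#' @export
finalize_consensus <- function(em, cr, merge_r = 0.85, min_size = 30) {
  stopifnot(inherits(cr, "consensus_result"))
  ma <- structure(list(labels = cr$labels, dendrogram = NULL, cut_height = NA),
                  class = "module_assignment")
  ma <- merge_close_modules(em, ma, cutHeight = 1 - merge_r, strict = TRUE,
                            min_size = 1)
  labels <- ma$labels
  tab <- table(labels[labels != UNASSIGNED])
  labels[labels %in% names(tab)[tab < min_size]] <- UNASSIGNED
  labels <- .finalize_labels(labels, 1)
  orig_mods <- setdiff(unique(cr$original), UNASSIGNED)
  audit <- data.frame(
    module = orig_mods,
    original_size = as.integer(table(factor(cr$original, orig_mods))),
    retained = vapply(orig_mods, function(m)
      sum(cr$original == m & labels != UNASSIGNED), 0L),
    demoted = vapply(orig_mods, function(m)
      sum(cr$original == m & labels == UNASSIGNED), 0L),
    row.names = NULL
  )
  structure(list(labels = labels, original = cr$original,
                 reliability = cr$reliability, n_boot = cr$n_boot,
                 audit = audit),
            class = "consensus_result")
}

#' Full bootstrap consensus pipeline
#'
#' [blockwise_modules()] on the full data, [bootstrap_networks()],
#' [consensus_filter()] and [finalize_consensus()] in sequence.
#'
#' @param em an `expression_matrix` (preprocessed log-CPM).
#' @param n_boot bootstrap replicates (study default 250).
#' @param overlap_frac,reliability,merge_r,min_size consensus parameters.
#' @param maxBlockSize,minModuleSize,deepSplit,mergeCutHeight,beta network
#'   parameters.
#' @param seed master seed.
#' @return the finalized `consensus_result`; the original assignment is
#'   attached as attribute `original_assignment`.
#' @export
bootstrap_consensus <- function(em, n_boot = 250, overlap_frac = 0.10,
                                reliability = 0.70, merge_r = 0.85,
                                min_size = 30, maxBlockSize = 10000,
                                minModuleSize = 30, deepSplit = 2,
                                mergeCutHeight = 0.15, beta = NULL, seed = 1) {
  ma <- blockwise_modules(em, maxBlockSize = maxBlockSize, beta = beta,
                          minModuleSize = minModuleSize, deepSplit = deepSplit,
                          mergeCutHeight = mergeCutHeight,
                          seed = stage_seed(seed, "network"))
  runs <- bootstrap_networks(em, n_boot = n_boot, beta = attr(ma, "beta"),
                             maxBlockSize = maxBlockSize,
                             minModuleSize = minModuleSize, deepSplit = deepSplit,
                             mergeCutHeight = mergeCutHeight, seed = seed)
  cr <- consensus_filter(ma, runs, reliability = reliability,
                         overlap_frac = overlap_frac)
  out <- finalize_consensus(em, cr, merge_r = merge_r, min_size = min_size)
  attr(out, "original_assignment") <- ma
  out
}
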