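# Signed-hybrid weighted coexpression network construction: soft-threshold
# selection by scale-free fit, adjacency, topological overlap, average-linkage
# clustering with an adaptive height cut, eigengene-based module merging, and
# blockwise assembly for gene sets larger than the maximum block size.
#
# The dendrogram cut is a simplified adaptive height cut (no PAM stage, no
# recursive branch analysis): the tree is cut at a fixed quantile of the merge
# height range keyed to deepSplit, and branches below minModuleSize are left
# unassigned. Module recovery on planted data, not label-for-label parity with
# any particular cutter, is the validated property.

#' Signed-hybrid adjacency
#'
#' `a_ij = cor(x_i, x_j)^beta` when the Pearson correlation is positive,
#' otherwise 0; the diagonal is stored as 1. Zero-variance genes get zero
#' adjacency to everything, with a warning.
#'
#' @param em an `expression_matrix`.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric genes x genes matrix in \[0, 1\], class `adjacency`,
#'   with attribute `beta`.
#' @export
signed_hybrid_adjacency <- function(em, beta = 6) {
  stopifnot(inherits(em, "expression_matrix"))
  if (beta < 1) .stopf("beta must be >= 1")
  x <- t(em$values)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) .warnf("%d zero-variance gene(s); their adjacencies set to 0",
                            sum(sds == 0))
  a <- .cor_weighted(x)
  a[a <= 0] <- 0
  a <- a^beta
  a[!is.finite(a)] <- 0
  diag(a) <- 1
  dimnames(a) <- list(em$gene_ids, em$gene_ids)
  structure(a, beta = beta, class = c("adjacency", "matrix", "array"))
}

# Pearson correlation of columns; plain cor() with a guard for zero variance.
.cor_weighted <- function(x) {
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r
}

#' Pick the soft-threshold power by scale-free model fit
#'
#' For each candidate power the signed scale-free fit is the R-squared of a
#' linear regression of log10 p(k) on log10 k over 10 connectivity bins,
#' sign-corrected (negative slopes count positively). The smallest power whose
#' fit reaches `r2_target` is returned; if none qualifies, the fallback
#' default 6 with a warning.
#'
#' @param em an `expression_matrix`.
#' @param powers candidate integer powers.
#' @param r2_target minimum signed R-squared.
#' @return list: `beta`, `r2` (fit at the chosen power), `fit_table`
#'   (power, r2, mean_k), `fallback` flag.
#' @export
pick_soft_threshold <- function(em, powers = 1:20, r2_target = 0.80) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(em$sample_ids) < 3) .stopf("need at least 3 samples")
  r <- .cor_weighted(t(em$values))
  r[r <= 0] <- 0
  diag(r) <- 0
  fit <- vapply(powers, function(b) {
    k <- rowSums(r^b)
    c(.scale_free_fit(k), mean(k))
  }, c(0, 0))
  tab <- data.frame(power = powers, r2 = fit[1, ], mean_k = fit[2, ])
  ok <- which(tab$r2 >= r2_target)
  if (length(ok)) {
    b <- powers[ok[1]]
    list(beta = b, r2 = tab$r2[ok[1]], fit_table = tab, fallback = FALSE)
  } else {
    .warnf("no power reached scale-free fit R^2 >= %.2f; using default beta = 6", r2_target)
    list(beta = 6L, r2 = tab$r2[match(6, powers)], fit_table = tab, fallback = TRUE)
  }
}

# Signed scale-free fit R^2 from a connectivity vector.
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(0)
  lx <- log10(dk[keep]); ly <- log10(pk[keep])
  f <- stats::lm(ly ~ lx)
  r2 <- summary(f)$r.squared
  -sign(stats::coef(f)[2]) * r2
}

#' Topological overlap matrix
#'
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where u
#' ranges over all genes except i and j and `k_i = sum_{u != i} a_iu`.
#'
#' @param adj an [signed_hybrid_adjacency()] matrix.
#' @return list: `tom` (similarity) and `dissim` (1 - tom), both symmetric.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a                       # sum_u a_iu a_uj, includes u = i, j with diag 0
  num <- num + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom[!is.finite(tom)] <- 0
  tom <- (tom + t(tom)) / 2            # guard symmetry against FP noise
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissim = 1 - tom)
}

.deepsplit_frac <- function(deepSplit) {
  if (!deepSplit %in% 0:4) .stopf("deepSplit must be in 0..4")
  c(0.95, 0.90, 0.85, 0.80, 0.75)[deepSplit + 1]
}

#' Cluster the TOM dissimilarity and cut into modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity, cut at the
#' height `min + frac(deepSplit) * (max - min)` of the merge-height range;
#' branches smaller than `minModuleSize` are labeled `"unassigned"`. Labels
#' `"M1", "M2", ...` are ordered by decreasing module size.
#'
#' @param dissim symmetric dissimilarity matrix (1 - TOM).
#' @param minModuleSize smallest named module.
#' @param deepSplit 0..4; larger values cut lower and split more.
#' @return a `module_assignment`: list with `labels` (named character vector
#'   over genes), `dendrogram` (hclust), `cut_height`.
#' @export
cluster_and_cut <- function(dissim, minModuleSize = 30, deepSplit = 2) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  genes <- rownames(dissim)
  n <- nrow(dissim)
  if (n < minModuleSize) {
    return(structure(list(labels = stats::setNames(rep(UNASSIGNED, n), genes),
                          dendrogram = NULL, cut_height = NA_real_),
                     class = "module_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  h <- hc$height
  cut_h <- min(h) + .deepsplit_frac(deepSplit) * (max(h) - min(h))
  raw <- stats::cutree(hc, h = cut_h)
  labels <- .finalize_labels(stats::setNames(as.character(raw), genes), minModuleSize)
  structure(list(labels = labels, dendrogram = hc, cut_height = cut_h),
            class = "module_assignment")
}

# Demote small clusters to unassigned and relabel M1.. by decreasing size.
.finalize_labels <- function(labels, min_size) {
  tab <- table(labels[labels != UNASSIGNED])
  small <- names(tab)[tab < min_size]
  labels[labels %in% small] <- UNASSIGNED
  tab <- sort(table(labels[labels != UNASSIGNED]), decreasing = TRUE)
  map <- stats::setNames(sprintf("M%d", seq_along(tab)), names(tab))
  out <- ifelse(labels == UNASSIGNED, UNASSIGNED, map[labels])
  stats::setNames(out, names(labels))
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("module_assignment: %d genes, %d named modules, %d unassigned\n",
              length(x$labels), sum(names(tab) != UNASSIGNED),
              if (UNASSIGNED %in% names(tab)) tab[[UNASSIGNED]] else 0L))
  invisible(x)
}

# Eigengene score matrix (samples x modules) for the named modules of `ma`.
.module_eigengenes <- function(em, labels) {
  mods <- setdiff(unique(labels), UNASSIGNED)
  if (!length(mods)) return(NULL)
  scores <- vapply(mods, function(m) {
    module_eigengene(em, names(labels)[labels == m])$scores
  }, numeric(length(em$sample_ids)))
  colnames(scores) <- mods
  scores
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' while it exceeds `1 - cutHeight` (inclusive by default, strict when
#' `strict = TRUE`), recomputing eigengenes after every merge.
#'
#' @param em an `expression_matrix` covering the assigned genes.
#' @param ma a `module_assignment`.
#' @param cutHeight eigengene dissimilarity (1 - r) threshold.
#' @param strict require r strictly greater than `1 - cutHeight`.
#' @param min_size modules below this size after merging are demoted.
#' @return the merged `module_assignment`.
#' @export
merge_close_modules <- function(em, ma, cutHeight = 0.15, strict = FALSE,
                                min_size = 1) {
  labels <- ma$labels
  thr <- 1 - cutHeight
  repeat {
    mods <- setdiff(unique(labels), UNASSIGNED)
    if (length(mods) < 2) break
    eg <- .module_eigengenes(em, labels)
    r <- stats::cor(eg)
    diag(r) <- -Inf
    best <- which(r == max(r), arr.ind = TRUE)[1, ]
    # epsilon guards keep the boundary semantics exact under floating point:
    # strict means r equal to the threshold does NOT merge
    qualifies <- if (strict) max(r) > thr + 1e-9 else max(r) >= thr - 1e-9
    if (!qualifies) break
    a <- colnames(r)[best[2]]; b <- rownames(r)[best[1]]
    labels[labels == b] <- a
  }
  labels <- .finalize_labels(labels, min_size)
  structure(list(labels = labels, dendrogram = ma$dendrogram,
                 cut_height = ma$cut_height),
            class = "module_assignment")
}

#' Blockwise module construction
#'
#' For at most `maxBlockSize` genes: soft-threshold pick (unless `beta` is
#' supplied), adjacency, TOM, clustering/cutting, and eigengene merging in one
#' block. Larger gene sets are pre-partitioned by k-means on expression
#' profiles into blocks of at most `maxBlockSize`, the pipeline runs per
#' block, and modules are merged across blocks by eigengene correlation.
#'
#' @param em an `expression_matrix`.
#' @param maxBlockSize largest number of genes handled in one block.
#' @param beta soft-threshold power; `NULL` picks it by scale-free fit.
#' @param minModuleSize,deepSplit,mergeCutHeight cut/merge parameters.
#' @param seed seed for the k-means blocking.
#' @return a `module_assignment` with attributes `beta`, `r2`, `blocks`.
#' @export
blockwise_modules <- function(em, maxBlockSize = 10000, beta = NULL,
                              minModuleSize = 30, deepSplit = 2,
                              mergeCutHeight = 0.15, seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- length(em$gene_ids)
  r2 <- NA_real_
  if (is.null(beta)) {
    pick_em <- em
    if (n > maxBlockSize) {
      set.seed(stage_seed(seed, "blocks", 1L))
      sub <- sort(sample.int(n, maxBlockSize))
      pick_em <- em
      pick_em$values <- em$values[sub, , drop = FALSE]
      pick_em$gene_ids <- em$gene_ids[sub]
    }
    pick <- pick_soft_threshold(pick_em)
    beta <- pick$beta
    r2 <- pick$r2
  }
  if (n <= maxBlockSize) {
    blocks <- stats::setNames(rep(1L, n), em$gene_ids)
  } else {
    set.seed(stage_seed(seed, "blocks"))
    k <- ceiling(n / maxBlockSize)
    # cluster standardized profiles so blocks follow correlation, not baseline
    std <- t(scale(t(em$values)))
    std[!is.finite(std)] <- 0
    km <- stats::kmeans(std, centers = k, nstart = 5, iter.max = 50)
    blocks <- km$cluster
    # split any block still over the cap
    repeat {
      big <- which(table(blocks) > maxBlockSize)
      if (!length(big)) break
      b <- as.integer(names(big)[1])
      idx <- which(blocks == b)
      half <- idx[seq_len(ceiling(length(idx) / 2))]
      blocks[half] <- max(blocks) + 1L
    }
    blocks <- stats::setNames(blocks, em$gene_ids)
  }
  labels <- stats::setNames(rep(UNASSIGNED, n), em$gene_ids)
  for (b in sort(unique(blocks))) {
    idx <- which(blocks == b)
    sub <- em
    sub$values <- em$values[idx, , drop = FALSE]
    sub$gene_ids <- em$gene_ids[idx]
    adj <- signed_hybrid_adjacency(sub, beta)
    to <- topological_overlap(adj)
    ma_b <- cluster_and_cut(to$dissim, minModuleSize, deepSplit)
    ma_b <- merge_close_modules(sub, ma_b, mergeCutHeight, min_size = minModuleSize)
    lb <- ma_b$labels
    named <- lb != UNASSIGNED
    lb[named] <- sprintf("B%d_%s", b, lb[named])
    labels[idx] <- lb
  }
  ma <- structure(list(labels = labels, dendrogram = NULL, cut_height = NA_real_),
                  class = "module_assignment")
  if (length(unique(blocks)) > 1) {
    ma <- merge_close_modules(em, ma, mergeCutHeight, min_size = minModuleSize)
  } else {
    ma$labels <- .finalize_labels(ma$labels, minModuleSize)
  }
  attr(ma, "beta") <- beta
  attr(ma, "r2") <- r2
  attr(ma, "blocks") <- blocks
  ma
}
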