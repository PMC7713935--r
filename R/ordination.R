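# Bray-Curtis dissimilarity, nonmetric multidimensional scaling (Kruskal
# stress-1 via vegan's monotone-regression engine, best of seeded random
# restarts plus a metric start), and sequential PERMANOVA. The dissimilarity
# consumes TMM-scaled CPM (non-negative, abundance-like); a flag switches to
# shifted log-CPM.

#' TMM-scaled counts-per-million
#'
#' @param cm a [count_matrix()].
#' @param nf [tmm_normalize()] factors (or `NULL` for all-ones).
#' @param log return log2 values shifted to be non-negative instead.
#' @return samples x genes matrix of non-negative abundances.
#' @export
normalized_abundance <- function(cm, nf = NULL, log = FALSE) {
  if (is.null(nf)) nf <- stats::setNames(rep(1, length(cm$sample_ids)), cm$sample_ids)
  if (log) {
    v <- t(log_cpm(cm, nf)$values)
    return(v - min(v))
  }
  eff <- cm$lib_sizes * as.numeric(nf[cm$sample_ids])
  t(sweep(cm$counts, 2, eff, "/") * 1e6)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` over genes. A pair of all-zero
#' samples is defined as distance 0 with a warning.
#'
#' @param abund non-negative samples x genes matrix.
#' @return symmetric samples x samples matrix with zero diagonal, class
#'   `dissimilarity`.
#' @export
bray_curtis <- function(abund) {
  if (any(abund < 0)) .stopf("Bray-Curtis needs non-negative values")
  # vegdist warns on all-zero rows; the NA patch below makes that case explicit
  d <- as.matrix(suppressWarnings(vegan::vegdist(abund, method = "bray")))
  if (anyNA(d)) {
    .warnf("all-zero sample pair(s); their dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  structure(d, class = c("dissimilarity", "matrix", "array"))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 minimized by iterative majorization with monotone
#' regression (vegan's global-model engine), over `n_starts` seeded random
#' configurations plus one metric (principal-coordinate) start; the best
#' stress is kept. Coordinates are centered and rotated to principal axes.
#'
#' @param d a [bray_curtis()] matrix (or any symmetric dissimilarity).
#' @param k number of dimensions (study value 4).
#' @param n_starts random restarts.
#' @param max_iter,tol engine iteration cap and convergence tolerance.
#' @param seed seed for the random starts.
#' @return list of class `ordination`: `points` (n x k), `stress` (in \[0,1\]),
#'   `n_starts`, `converged`.
#' @export
nmds <- function(d, k = 4, n_starts = 20, max_iter = 300, tol = 1e-7, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n <= k) .stopf("need more samples than dimensions")
  dd <- stats::as.dist(d)
  run <- function(init) vegan::monoMDS(dd, y = init, k = k, model = "global",
                                       maxit = max_iter, smin = 1e-4,
                                       sfgrmin = tol, sratmax = 1 - 1e-9)
  # metric start: principal coordinates
  pco <- stats::cmdscale(dd, k = k, add = TRUE)$points
  best <- run(pco)
  set.seed(stage_seed(seed, "ordinate"))
  for (s in seq_len(n_starts)) {
    fit <- run(matrix(stats::rnorm(n * k), n, k))
    if (fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, scale = FALSE)
  pts <- pts %*% svd(pts)$v            # principal-axis rotation
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 converged = best$maxits == 0 || best$stress <= 1e-4 ||
                   best$icause %in% c(2L, 3L)),
            class = "ordination")
}

#' Sequential PERMANOVA on a dissimilarity matrix
#'
#' Gower-centered partition of the squared dissimilarities onto population,
#' infestation and their interaction in order (type-I), pseudo-F per term, and
#' permutation p-values with the +1 correction, permuting sample rows freely.
#'
#' @param d a [bray_curtis()] matrix.
#' @param design a [design_table()] matching the samples of `d`.
#' @param n_perm number of permutations (study value 1000).
#' @param seed permutation seed.
#' @return data.frame of class `permanova_table`: term, df, sum_sq, R2, F, p.
#' @export
permanova <- function(d, design, n_perm = 1000, seed = 1) {
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  d <- as.matrix(d)
  dat <- design[match(rownames(d), design$sample_id), ]
  if (anyNA(dat$sample_id)) .stopf("design misses samples present in d")
  set.seed(stage_seed(seed, "ordinate", 1L))
  fit <- vegan::adonis2(stats::as.dist(d) ~ population * infestation,
                        data = dat, permutations = n_perm, by = "terms")
  out <- data.frame(
    term = c("population", "infestation", "interaction", "residual", "total"),
    df = fit$Df, sum_sq = fit$SumOfSqs, R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
    row.names = NULL
  )
  class(out) <- c("permanova_table", "data.frame")
  out
}
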