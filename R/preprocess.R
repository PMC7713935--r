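# Expression filtering, TMM normalization, log-CPM (voom-style) transformation
# and the variance prefilter applied before network construction.
#
# TMM is implemented from its published definition: the scaling factor between
# a sample and the reference is 2^(weighted trimmed mean of the gene-wise
# log-ratios M), trimming fixed fractions of the M and A tails and weighting by
# inverse asymptotic (binomial) variances. Factors are rescaled to geometric
# mean 1.

#' Filter genes by minimum expression
#'
#' Retains genes with CPM >= `min_cpm` in at least `min_samples` samples,
#' with CPM computed on the raw library sizes (pre-normalization).
#'
#' @param cm a [count_matrix()].
#' @param min_cpm minimum counts-per-million (boundary inclusive).
#' @param min_samples minimum number of samples at or above `min_cpm`.
#' @return the filtered [count_matrix()] (library sizes are kept as the
#'   original totals are irrelevant downstream; column sums are recomputed).
#' @export
filter_low_expression <- function(cm, min_cpm = 1, min_samples = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lib_sizes <= 0)) .stopf("library sizes must be positive")
  cpm <- sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) .stopf("all genes removed by the expression filter")
  count_matrix(cm$counts[keep, , drop = FALSE])
}

.upper_quartile_cpm <- function(counts, lib) {
  apply(sweep(counts, 2, lib, "/") * 1e6, 2, function(x) stats::quantile(x[x > 0], 0.75))
}

# Weighted trimmed mean of M-values for one sample against the reference.
.tmm_one <- function(obs, ref, lib_obs, lib_ref,
                     logratio_trim = 0.30, sum_trim = 0.05, A_cutoff = -1e10) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) {
    .warnf("sample shares no expressed genes with the reference; factor set to 1")
    return(1)
  }
  o <- obs[pos] / lib_obs
  r <- ref[pos] / lib_ref
  M <- log2(o / r)
  A <- (log2(o) + log2(r)) / 2
  w <- (lib_obs - obs[pos]) / (lib_obs * obs[pos]) +
       (lib_ref - ref[pos]) / (lib_ref * ref[pos])
  keep_A <- A > A_cutoff
  M <- M[keep_A]; A <- A[keep_A]; w <- w[keep_A]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1) # identical composition
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per-sample scaling factors computed against a
#' reference sample over genes positive in both, with the stated trim
#' fractions of the M (log-ratio) and A (log-abundance) tails and
#' inverse-asymptotic-variance weights; factors are rescaled to geometric
#' mean 1.
#'
#' @param cm a [count_matrix()].
#' @param ref reference sample id, or `"auto"` to use the sample whose
#'   upper-quartile CPM is closest to the mean upper-quartile.
#' @param logratio_trim,sum_trim two-sided trim fractions for M and A.
#' @param A_cutoff genes with average log abundance at or below this are
#'   dropped before trimming.
#' @return named numeric vector of per-sample factors (class `norm_factors`),
#'   geometric mean 1.
#' @export
tmm_normalize <- function(cm, ref = "auto", logratio_trim = 0.30,
                          sum_trim = 0.05, A_cutoff = -1e10) {
  stopifnot(inherits(cm, "count_matrix"))
  ns <- length(cm$sample_ids)
  if (ns < 2) .stopf("TMM needs at least two samples")
  if (identical(ref, "auto")) {
    uq <- .upper_quartile_cpm(cm$counts, cm$lib_sizes)
    ref <- cm$sample_ids[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% cm$sample_ids) .stopf("reference sample '%s' not found", ref)
  ri <- match(ref, cm$sample_ids)
  f <- vapply(seq_len(ns), function(s) {
    if (s == ri) return(1)
    .tmm_one(cm$counts[, s], cm$counts[, ri], cm$lib_sizes[s], cm$lib_sizes[ri],
             logratio_trim, sum_trim, A_cutoff)
  }, 0)
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, cm$sample_ids), class = "norm_factors", ref = ref)
}

#' Log2 counts-per-million on effective library sizes
#'
#' `value = log2((count + prior) / (lib_size * f + 2 * prior) * 1e6)`.
#'
#' @param cm a [count_matrix()].
#' @param nf [tmm_normalize()] factors; `NULL` for all-ones.
#' @param prior pseudocount.
#' @return an `expression_matrix`: list with `values` (genes x samples),
#'   `gene_ids`, `sample_ids`, `prior_count`.
#' @export
log_cpm <- function(cm, nf = NULL, prior = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(nf)) nf <- stats::setNames(rep(1, length(cm$sample_ids)), cm$sample_ids)
  if (any(nf <= 0)) .stopf("normalization factors must be positive")
  eff <- cm$lib_sizes * as.numeric(nf[cm$sample_ids])
  vals <- log2(sweep(cm$counts + prior, 2, eff + 2 * prior, "/") * 1e6)
  structure(list(values = vals, gene_ids = cm$gene_ids,
                 sample_ids = cm$sample_ids, prior_count = prior),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (log2 CPM): %d genes x %d samples, prior %.2g\n",
              length(x$gene_ids), length(x$sample_ids), x$prior_count))
  invisible(x)
}

#' Voom-style precision weights
#'
#' Lowess fit of sqrt residual standard deviation against mean log2 count,
#' evaluated per observation and returned as inverse-variance weights. The
#' weights are exposed for completeness; the network and ordination stages
#' consume the unweighted log-CPM values.
#'
#' @param cm a [count_matrix()].
#' @param nf normalization factors.
#' @param design a [design_table()]; residuals are taken within
#'   population x infestation cells.
#' @param span lowess span.
#' @return matrix of weights, genes x samples.
#' @export
voom_weights <- function(cm, nf, design, span = 0.5) {
  em <- log_cpm(cm, nf)
  validate_samples(cm, design)
  grp <- interaction(design$population, design$infestation, drop = TRUE)[
    match(cm$sample_ids, design$sample_id)]
  fitted <- em$values
  for (g in levels(grp)) {
    cols <- which(grp == g)
    fitted[, cols] <- rowMeans(em$values[, cols, drop = FALSE])
  }
  res <- em$values - fitted
  df <- length(grp) - nlevels(grp)
  sd_g <- sqrt(rowSums(res^2) / df)
  mean_logcount <- rowMeans(log2(cm$counts + 0.5))
  lo <- stats::lowess(mean_logcount, sqrt(sd_g), f = span)
  fun <- stats::approxfun(lo, rule = 2)
  eff <- cm$lib_sizes * as.numeric(nf[cm$sample_ids])
  # predicted count scale per observation from fitted log-cpm
  pred_count <- 2^(fitted + log2(eff + 1)[col(fitted)] - log2(1e6))
  trend <- matrix(fun(log2(pred_count + 0.5)), nrow(pred_count))
  w <- 1 / pmax(trend, .Machine$double.eps)^4
  dimnames(w) <- dimnames(em$values)
  w
}

#' Drop the lowest-variance genes
#'
#' Removes exactly `floor(drop_fraction * n_genes)` genes with the smallest
#' sample variance across all samples; ties broken by gene order (stable).
#'
#' @param em an [log_cpm()] expression matrix.
#' @param drop_fraction fraction of genes to drop.
#' @return the filtered `expression_matrix`.
#' @export
variance_prefilter <- function(em, drop_fraction = 0.40) {
  stopifnot(inherits(em, "expression_matrix"))
  n <- length(em$gene_ids)
  if (n < 1) .stopf("no genes in expression matrix")
  ndrop <- floor(drop_fraction * n)
  if (ndrop == 0) return(em)
  v <- apply(em$values, 1, stats::var)
  ord <- order(v, seq_len(n)) # stable: ties broken by gene position
  keep <- sort(ord[seq.int(ndrop + 1, n)])
  em$values <- em$values[keep, , drop = FALSE]
  em$gene_ids <- em$gene_ids[keep]
  em
}
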