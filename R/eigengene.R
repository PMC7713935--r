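# Module eigengenes (first principal component of the standardized module
# expression), variance explained, per-module factorial ANOVA, and the
# classification of population-by-infestation response patterns into the four
# interaction categories plus shared responses.

#' Module eigengene
#'
#' Genes are standardized to mean 0, SD 1 across samples; the eigengene is the
#' first right-singular vector of the genes x samples matrix (unit norm), with
#' its sign fixed so the sum of gene loadings is positive. Variance explained
#' is the first squared singular value over the total.
#'
#' @param em an `expression_matrix`.
#' @param genes character vector of member gene ids (>= 2 present in `em`).
#' @return list of class `eigengene`: `scores` (named per sample, unit norm),
#'   `loadings` (per gene), `variance_explained`, `module_size`.
#' @export
module_eigengene <- function(em, genes) {
  stopifnot(inherits(em, "expression_matrix"))
  idx <- match(genes, em$gene_ids)
  if (anyNA(idx)) .stopf("%d gene(s) not present in the expression matrix", sum(is.na(idx)))
  x <- em$values[idx, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    .warnf("excluding %d zero-variance gene(s) from the eigengene", sum(sds == 0))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) .stopf("eigengene needs at least 2 genes with variance")
  xs <- t(scale(t(x)))                # standardize genes across samples
  sv <- svd(xs)
  scores <- sv$v[, 1]
  loadings <- sv$u[, 1]
  if (sum(loadings) < 0) { scores <- -scores; loadings <- -loadings }
  structure(list(
    scores = stats::setNames(scores, em$sample_ids),
    loadings = stats::setNames(loadings, rownames(xs)),
    variance_explained = sv$d[1]^2 / sum(sv$d^2),
    module_size = nrow(xs)
  ), class = "eigengene")
}

#' Two-way factorial ANOVA on an eigengene
#'
#' Fixed-effects population x infestation ANOVA with interaction on the
#' eigengene scores. The default design is balanced, so sequential sums of
#' squares equal partial ones.
#'
#' @param eg an [module_eigengene()] result (or a bare named score vector).
#' @param design a [design_table()] covering the score samples.
#' @return data.frame with one row per term (population, infestation,
#'   interaction): df, sum_sq, F, p.
#' @export
eigengene_anova <- function(eg, design) {
  scores <- if (inherits(eg, "eigengene")) eg$scores else eg
  d <- design[match(names(scores), design$sample_id), ]
  if (anyNA(d$sample_id)) .stopf("design misses samples present in the eigengene")
  if (any(table(d$population, d$infestation) == 0)) .stopf("empty design cell")
  fit <- stats::aov(scores ~ population * infestation, data = d)
  tab <- summary(fit)[[1]]
  terms <- c("population", "infestation", "population:infestation")
  rn <- trimws(rownames(tab))
  i <- match(terms, rn)
  data.frame(term = c("population", "infestation", "interaction"),
             df = tab$Df[i], sum_sq = tab$`Sum Sq`[i],
             F = tab$`F value`[i], p = tab$`Pr(>F)`[i], row.names = NULL)
}

#' ANOVA across all modules with per-term BH adjustment
#'
#' @param em an `expression_matrix`.
#' @param labels named module labels (e.g. `consensus_result$labels`).
#' @param design a [design_table()].
#' @return data.frame: module, variance_explained, then F/p/p_adj per term.
#' @export
module_anova_table <- function(em, labels, design) {
  mods <- setdiff(unique(labels), UNASSIGNED)
  mods <- mods[order(-as.integer(table(factor(labels, mods))[mods]))]
  rows <- lapply(mods, function(m) {
    eg <- module_eigengene(em, names(labels)[labels == m])
    a <- eigengene_anova(eg, design)
    data.frame(module = m, size = eg$module_size,
               variance_explained = eg$variance_explained,
               term = a$term, F = a$F, p = a$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::ave(out$p, out$term, FUN = bh_adjust)
  out
}

#' Classify a module's population-by-infestation response pattern
#'
#' Day-7-minus-control eigengene deltas per population, in pooled within-cell
#' SD units, are classified as: `I` same sign, both above `epsilon`, magnitude
#' ratio at least `ratio` (same direction, much stronger in one population);
#' `II` exactly one population responds; `III` opposite signs, both above
#' `epsilon`; `shared` same sign, both above `epsilon`, ratio below `ratio`;
#' `IV` when none of those hold but the day-4 trajectories differ in sign
#' pattern between the populations; otherwise `none`.
#'
#' @param eg an [module_eigengene()] result (or named score vector).
#' @param design a [design_table()].
#' @param epsilon response threshold in pooled-SD units.
#' @param ratio magnitude ratio separating category I from a shared response.
#' @param peak_frac a day-7 delta only counts as a response if it is at least
#'   this fraction of the population's peak delta across days; a day-4-peaked
#'   trajectory with a small day-7 residue is a timing pattern, not a day-7
#'   response.
#' @return list: `category`, `delta_day7` (named per population),
#'   `delta_day4`, `pooled_sd`.
#' @export
classify_response <- function(eg, design, epsilon = 0.5, ratio = 2,
                              peak_frac = 0.5) {
  scores <- if (inherits(eg, "eigengene")) eg$scores else eg
  d <- design[match(names(scores), design$sample_id), ]
  cellmean <- function(pop, stg) mean(scores[d$population == pop & d$infestation == stg])
  # pooled within-cell SD
  cells <- interaction(d$population, d$infestation, drop = TRUE)
  ss <- sum(tapply(scores, cells, function(v) sum((v - mean(v))^2)))
  pooled_sd <- sqrt(ss / (length(scores) - nlevels(cells)))
  if (pooled_sd == 0) pooled_sd <- .Machine$double.eps
  d7 <- vapply(POPULATIONS, function(p)
    (cellmean(p, "day7") - cellmean(p, "control")) / pooled_sd, 0)
  d4 <- vapply(POPULATIONS, function(p)
    (cellmean(p, "day4") - cellmean(p, "control")) / pooled_sd, 0)
  big <- abs(d7) > epsilon & abs(d7) >= peak_frac * pmax(abs(d7), abs(d4))
  cat_ <- if (all(big) && sign(d7[1]) == sign(d7[2])) {
    if (max(abs(d7)) / min(abs(d7)) >= ratio) "I" else "shared"
  } else if (sum(big) == 1) {
    "II"
  } else if (all(big)) {
    "III"
  } else {
    # day-7 deltas quiet in both: a timing difference shows up at day 4
    big4 <- abs(d4) > epsilon
    if (any(big4) && (sign(round(d4[1], 8)) != sign(round(d4[2], 8)) ||
                      xor(big4[1], big4[2]))) "IV" else "none"
  }
  list(category = cat_, delta_day7 = d7, delta_day4 = d4, pooled_sd = pooled_sd)
}

#' Classify every module in an assignment
#'
#' @inheritParams module_anova_table
#' @param epsilon,ratio,peak_frac forwarded to [classify_response()].
#' @return data.frame: module, category, day-7 and day-4 deltas per population.
#' @export
classify_modules <- function(em, labels, design, epsilon = 0.5, ratio = 2,
                             peak_frac = 0.5) {
  mods <- setdiff(unique(labels), UNASSIGNED)
  rows <- lapply(mods, function(m) {
    eg <- module_eigengene(em, names(labels)[labels == m])
    cl <- classify_response(eg, design, epsilon, ratio, peak_frac)
    data.frame(module = m, category = cl$category,
               delta_day7_kauai = cl$delta_day7[["kauai"]],
               delta_day7_mangaia = cl$delta_day7[["mangaia"]],
               delta_day4_kauai = cl$delta_day4[["kauai"]],
               delta_day4_mangaia = cl$delta_day4[["mangaia"]])
  })
  do.call(rbind, rows)
}
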