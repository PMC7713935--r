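# Internal helpers shared across stages.

POPULATIONS <- c("kauai", "mangaia")
STAGES <- c("control", "day4", "day7")
UNASSIGNED <- "unassigned"

# Fixed per-stage offsets so each stage is independently re-runnable from the
# master seed. Kept below 2^31 after addition for any small master seed.
.stage_offsets <- c(
  simulate = 0L, preprocess = 101L, de = 202L, network = 303L,
  consensus = 404L, eigengene = 505L, ordinate = 606L, enrich = 707L,
  blocks = 808L
)

#' Derive a stage seed from the master seed
#'
#' Stage seeds are the master seed plus a fixed per-stage offset, so any stage
#' can be re-run in isolation and reproduce the full-pipeline result.
#'
#' @param seed master seed (single integer).
#' @param stage stage name, one of `names(bootmods:::.stage_offsets)`.
#' @param extra additional offset (e.g. a bootstrap replicate index).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage, extra = 0L) {
  stage <- match.arg(stage, names(.stage_offsets))
  as.integer((as.numeric(seed) + .stage_offsets[[stage]] + as.numeric(extra)) %% 2147483647)
}

.log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))

#' Percentage of a count over a total
#'
#' @param count numerator count.
#' @param total denominator count.
#' @param digits decimals in the reported percentage.
#' @return `round(100 * count / total, digits)`; `NA` when `total` is 0.
#' @export
percent <- function(count, total, digits = 0) {
  if (total == 0) return(NA_real_)
  round(100 * count / total, digits)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; used
#' to score planted-module recovery. 1 means identical partitions (up to
#' relabeling), 0 is the expected agreement of independent partitions.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(0)
  (sum_ij - expected) / denom
}
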