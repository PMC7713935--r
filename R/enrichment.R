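# Gene-set over-representation by the one-sided Fisher exact
# (hypergeometric upper-tail) test, "classic" scoring: each term is tested
# independently against the annotated universe; no term-graph structure.

#' Fisher exact over-representation test
#'
#' For each term, the one-sided upper-tail hypergeometric probability of an
#' overlap at least as large as observed, given the universe size, the term's
#' annotated genes in the universe, and the selection size. Terms with fewer
#' than `min_term_size` genes in the universe are skipped. BH adjustment is
#' applied across the tested terms.
#'
#' @param selected character vector of selected gene ids (subset of universe).
#' @param gsm a [gene_set_map()].
#' @param universe character vector of all testable gene ids.
#' @param min_term_size smallest tested term.
#' @return data.frame of class `enrichment_result`: term_id, term_name,
#'   n_universe, n_annotated, n_selected, n_overlap, p_raw, p_adj; ordered by
#'   p_raw.
#' @export
fisher_enrichment <- function(selected, gsm, universe, min_term_size = 3) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!length(universe)) .stopf("empty universe")
  if (!length(selected)) .stopf("empty selection")
  extra <- setdiff(selected, universe)
  if (length(extra)) .stopf("%d selected gene(s) outside the universe", length(extra))
  N <- length(universe); n_sel <- length(selected)
  rows <- lapply(names(gsm), function(tid) {
    ann <- intersect(gsm[[tid]], universe)
    if (length(ann) < min_term_size) return(NULL)
    ov <- length(intersect(ann, selected))
    p <- stats::phyper(ov - 1, length(ann), N - length(ann), n_sel,
                       lower.tail = FALSE)
    data.frame(term_id = tid, term_name = attr(gsm, "term_names")[[tid]],
               n_universe = N, n_annotated = length(ann), n_selected = n_sel,
               n_overlap = ov, p_raw = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) .stopf("no term passed min_term_size = %d", min_term_size)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
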