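# Readers, writers and validators for the pipeline's interchange formats:
# counts (TSV or MatrixMarket), design tables, gene-set maps and result tables.
# TSV is the canonical interchange; MatrixMarket is accepted for counts only.

#' Construct a validated count matrix container
#'
#' A `count_matrix` holds a non-negative integer gene x sample matrix together
#' with per-sample library sizes (column sums). Gene and sample ids must be
#' unique; library sizes are always recomputed from the counts so they can
#' never drift out of sync.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @return an object of class `count_matrix` with elements `counts` (integer
#'   matrix), `gene_ids`, `sample_ids` and `lib_sizes`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must carry gene ids (rownames) and sample ids (colnames)")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (anyDuplicated(gene_ids))
    .stopf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(sample_ids))
    .stopf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    .stopf("non-integer or negative count at gene '%s', sample '%s' (value %s)",
           gene_ids[i[1]], sample_ids[i[2]], format(counts[bad[1]]))
  }
  storage.mode(counts) <- "double" # exact integers, but avoid int overflow in sums
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids,
         lib_sizes = colSums(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; median library size %s\n",
              length(x$gene_ids), length(x$sample_ids),
              format(stats::median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV: header row of sample ids, first column of gene ids. MatrixMarket:
#' `<stem>.mtx` plus `<stem>.genes.txt` and `<stem>.samples.txt` holding one
#' id per line (pass the `.mtx` path).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`; `"auto"` infers from the extension.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (!file.exists(path)) .stopf("counts file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE)
    if (nrow(df) == 0 || ncol(df) < 2) .stopf("no genes parsed from %s", path)
    gene_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- gene_ids
    count_matrix(m)
  } else {
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    sfile <- paste0(stem, ".samples.txt")
    if (!file.exists(gfile) || !file.exists(sfile))
      .stopf("MatrixMarket counts need row/column id files %s and %s", gfile, sfile)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gfile)
    samples <- readLines(sfile)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      .stopf("MatrixMarket dimensions (%d x %d) do not match id files (%d x %d)",
             nrow(m), ncol(m), length(genes), length(samples))
    if (nrow(m) == 0) .stopf("no genes parsed from %s", path)
    dimnames(m) <- list(genes, samples)
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' @param cm a [count_matrix()].
#' @param path output path; `.mtx` extension selects MatrixMarket (with
#'   sidecar id files), anything else TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(cm$sample_ids, paste0(stem, ".samples.txt"))
  } else {
    df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a validated design table
#'
#' @param df data.frame with columns `sample_id`, `population`, `infestation`.
#' @param populations,stages allowed factor level vocabularies; override to
#'   reuse the pipeline outside the default two-population, three-stage design.
#' @return a `design_table` data.frame with factor columns.
#' @export
design_table <- function(df, populations = POPULATIONS, stages = STAGES) {
  need <- c("sample_id", "population", "infestation")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("design is missing column(s): %s", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    .stopf("duplicate sample id in design: %s", df$sample_id[duplicated(df$sample_id)][1])
  bad_pop <- setdiff(unique(as.character(df$population)), populations)
  if (length(bad_pop)) .stopf("unknown population level(s): %s", paste(bad_pop, collapse = ", "))
  bad_inf <- setdiff(unique(as.character(df$infestation)), stages)
  if (length(bad_inf)) .stopf("unknown infestation level(s): %s", paste(bad_inf, collapse = ", "))
  df$population <- factor(as.character(df$population), levels = populations)
  df$infestation <- factor(as.character(df$infestation), levels = stages)
  df <- df[, need]
  class(df) <- c("design_table", "data.frame")
  df
}

#' Read a design table from TSV
#'
#' @inheritParams design_table
#' @param path TSV with columns `sample_id`, `population`, `infestation`.
#' @return a [design_table()].
#' @export
read_design <- function(path, populations = POPULATIONS, stages = STAGES) {
  if (!file.exists(path)) .stopf("design file not found: %s", path)
  design_table(utils::read.delim(path, colClasses = "character"),
               populations = populations, stages = stages)
}

#' Write a design table to TSV
#' @param design a [design_table()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that counts and design describe the same samples
#'
#' @param cm a [count_matrix()].
#' @param design a [design_table()].
#' @return invisibly `TRUE`; errors listing the symmetric difference otherwise.
#' @export
validate_samples <- function(cm, design) {
  only_counts <- setdiff(cm$sample_ids, design$sample_id)
  only_design <- setdiff(design$sample_id, cm$sample_ids)
  if (length(only_counts) || length(only_design))
    .stopf("sample mismatch between counts and design%s%s",
           if (length(only_counts)) paste0("; in counts only: ", paste(only_counts, collapse = ", ")) else "",
           if (length(only_design)) paste0("; in design only: ", paste(only_design, collapse = ", ")) else "")
  invisible(TRUE)
}

#' Read a gene-set (term -> genes) map from TSV
#'
#' One `(term_id, term_name, gene_id)` row per annotation pair.
#'
#' @param path TSV path.
#' @return a `gene_set_map`: named list of character vectors (gene ids), with
#'   a `term_names` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) .stopf("gene-set file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("term_id", "term_name", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("gene-set table missing column(s): %s", paste(miss, collapse = ", "))
  gene_set_map(split(df$gene_id, df$term_id),
               term_names = vapply(split(df$term_name, df$term_id), `[`, "", 1))
}

#' Construct a gene-set map
#' @param sets named list: term_id -> character vector of gene ids.
#' @param term_names optional named character vector of display names.
#' @return a `gene_set_map`.
#' @export
gene_set_map <- function(sets, term_names = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    .stopf("gene sets must be named by term id")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) .stopf("empty gene set: %s",
                                      names(sets)[lengths(sets) == 0][1])
  if (is.null(term_names)) term_names <- stats::setNames(names(sets), names(sets))
  structure(sets, term_names = term_names[names(sets)], class = "gene_set_map")
}

#' Write a gene-set map to TSV
#' @param gsm a [gene_set_map()].
#' @param path output path.
#' @export
write_gene_sets <- function(gsm, path) {
  tn <- attr(gsm, "term_names")
  df <- data.frame(
    term_id = rep(names(gsm), lengths(gsm)),
    term_name = rep(unname(tn), lengths(gsm)),
    gene_id = unlist(gsm, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
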