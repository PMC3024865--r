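#' Expression matrix with replicate provenance
#'
#' Container for a genes-by-tissues table of linear-scale expression signals
#' (microarray-like intensities). When a `replicate_map` is supplied, raw
#' columns mapping to the same tissue are collapsed to their arithmetic mean
#' and the mapping is retained as provenance.
#'
#' @param signal Numeric matrix, genes in rows (rownames = gene ids),
#'   columns either tissues or raw replicate columns (colnames required).
#'   All values must be finite and non-negative (linear scale).
#' @param replicate_map Optional named character vector mapping raw column
#'   name -> tissue id. Every raw column must be named; output tissue order
#'   follows first appearance.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `signal` (genes x tissues numeric matrix), `gene_ids`, `tissue_ids`
#'   and `replicate_map` (possibly `NULL`).
#' @export
expression_matrix <- function(signal, replicate_map = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix")
  gene_ids <- rownames(signal)
  cols <- colnames(signal)
  if (is.null(gene_ids) || is.null(cols))
    stop("`signal` must have rownames (gene ids) and colnames")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(signal)))
    stop("non-finite expression signal encountered")
  if (any(signal < 0)) {
    bad <- which(signal < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative signal at gene '%s', column '%s' (signals are intensities)",
                 gene_ids[bad[1]], cols[bad[2]]))
  }
  if (!is.null(replicate_map)) {
    if (is.null(names(replicate_map)) || any(names(replicate_map) == ""))
      stop("`replicate_map` must be a named vector (raw column -> tissue)")
    missing_cols <- setdiff(cols, names(replicate_map))
    if (length(missing_cols))
      stop("raw column(s) missing from replicate_map: ",
           paste(missing_cols, collapse = ", "))
    tissue_of <- unname(replicate_map[cols])
    tissues <- unique(tissue_of)
    collapsed <- vapply(tissues, function(t) {
      rowMeans(signal[, tissue_of == t, drop = FALSE])
    }, numeric(nrow(signal)))
    dimnames(collapsed) <- list(gene_ids, tissues)
    signal <- collapsed
  } else {
    dup_t <- cols[duplicated(cols)]
    if (length(dup_t))
      stop("duplicate tissue id(s): ", paste(unique(dup_t), collapse = ", "))
  }
  structure(list(signal = signal,
                 gene_ids = gene_ids,
                 tissue_ids = colnames(signal),
                 replicate_map = replicate_map),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d tissues\n",
              length(x$gene_ids), length(x$tissue_ids)))
  if (!is.null(x$replicate_map))
    cat(sprintf("  collapsed from %d raw replicate columns\n",
                length(x$replicate_map)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signal)

#' Read an expression table from TSV
#'
#' Expects a tab-separated file with a header row, first column `gene_id`,
#' remaining columns numeric signals (linear scale). Replicate columns are
#' averaged into tissues when `replicate_map` is given.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param replicate_map Optional named character vector, raw column -> tissue.
#' @return An [expression_matrix()] object.
#' @export
read_expression_table <- function(path, replicate_map = NULL) {
  df <- read_tsv(path)
  if (ncol(df) < 2)
    stop("expression table needs a gene_id column plus at least one tissue")
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  body <- df[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                     col[bad[1]], bad[1], gene_ids[bad[1]], names(body)[j]))
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- gene_ids
  expression_matrix(mat, replicate_map = replicate_map)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]: tab-separated, `gene_id` first
#' header cell, full-precision decimal representation so that
#' write-then-read round-trips bit-identically.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = x$gene_ids, x$signal,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
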