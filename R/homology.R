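#' Read a cross-species homology table
#'
#' Reads a two-column TSV of ortholog gene-id pairs (species A, species B)
#' and keeps only unique-hit pairs: any pair whose gene appears in more than
#' one row, in either species, is discarded entirely, leaving a strictly
#' one-to-one mapping.
#'
#' @param path Path to a two-column TSV with a header row.
#' @return A `HomologyMap`: a data.frame with columns `gene_a` and `gene_b`
#'   satisfying the one-to-one invariant, with attribute `n_discarded`.
#' @export
read_homology <- function(path) {
  df <- read_tsv(path)
  if (!nrow(df)) stop("empty homology file: ", path)
  if (ncol(df) != 2L)
    stop("homology table must have exactly 2 columns, got ", ncol(df))
  homology_map(as.character(df[[1]]), as.character(df[[2]]))
}

#' Construct a one-to-one homology map
#'
#' @param gene_a,gene_b Character vectors of equal length; row i pairs
#'   `gene_a[i]` with `gene_b[i]`.
#' @return See [read_homology()].
#' @export
homology_map <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  multi_a <- gene_a %in% gene_a[duplicated(gene_a)]
  multi_b <- gene_b %in% gene_b[duplicated(gene_b)]
  keep <- !(multi_a | multi_b)
  out <- data.frame(gene_a = gene_a[keep], gene_b = gene_b[keep],
                    stringsAsFactors = FALSE)
  if (sum(!keep))
    stage_log("homology", "discarded %d multi-hit pair(s); %d unique-hit pairs retained",
              sum(!keep), nrow(out))
  structure(out, class = c("HomologyMap", "data.frame"),
            n_discarded = sum(!keep))
}
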