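#' Read a gene-set collection from a GMT file
#'
#' Parses Broad-dialect GMT lines (`module_id <tab> description <tab>
#' gene1 <tab> gene2 ...`), intersects each module with the chip universe
#' and drops modules with too few surviving genes. The default minimum of
#' six members implements the "more than five genes on the chip" rule used
#' for GO/KEGG modules on expression arrays.
#'
#' @param path Path to a GMT file.
#' @param universe Character vector of gene ids on the chip (e.g. rownames of
#'   the expression matrix). Module members outside it are removed before the
#'   size filter.
#' @param min_size Minimum number of member genes present on the chip for a
#'   module to be retained (default 6, i.e. strictly more than five).
#' @return A `GeneSetCollection`: a named list of character vectors of gene
#'   ids, with a `namespace` attribute (one of `"GO"`, `"KEGG"`, `"other"`
#'   per module, inferred from the id prefix) and a `universe` attribute.
#' @export
read_gene_sets <- function(path, universe, min_size = 6L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                 short[1], path))
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate module id(s) in GMT: ", paste(unique(dup), collapse = ", "))
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- ids
  gene_set_collection(members, universe, min_size = min_size)
}

#' Build a gene-set collection from a named list
#'
#' @param modules Named list of character vectors of gene ids.
#' @param universe Chip universe to intersect against.
#' @param min_size Minimum post-intersection module size (default 6).
#' @return A `GeneSetCollection` (see [read_gene_sets()]).
#' @export
gene_set_collection <- function(modules, universe, min_size = 6L) {
  if (is.null(names(modules)) || any(names(modules) == ""))
    stop("modules must be a named list")
  universe <- unique(as.character(universe))
  filtered <- lapply(modules, function(g) intersect(unique(g), universe))
  keep <- lengths(filtered) >= min_size
  n_dropped <- sum(!keep)
  if (n_dropped)
    stage_log("gene_sets", "dropped %d/%d module(s) with < %d genes on the chip",
              n_dropped, length(modules), min_size)
  filtered <- filtered[keep]
  if (!length(filtered))
    stop("no module left after universe intersection and size filter (min_size = ",
         min_size, ")")
  ns <- ifelse(grepl("^GO", names(filtered)), "GO",
               ifelse(grepl("^(HSA|MMU|hsa|mmu|ko|map)", names(filtered)),
                      "KEGG", "other"))
  structure(filtered, class = "GeneSetCollection",
            namespace = stats::setNames(ns, names(filtered)),
            universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `GeneSetCollection` or named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-module descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  ids <- names(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(ids))
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
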