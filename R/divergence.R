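#' Fractional-rank (p-rank) transform of an expression matrix
#'
#' Within each tissue, signals are ranked ascending (rank 1 = lowest),
#' ties receive the average of their tied ranks, and ranks are divided by
#' the number of genes n. Values therefore lie in (0, 1], the maximum is 1
#' whenever the top signal is untied, and the transform depends on signal
#' order only (it is invariant to any strictly monotone rescaling).
#'
#' @param expr An [expression_matrix()] object or a numeric genes-by-tissues
#'   matrix with dimnames.
#' @return Numeric matrix of p-ranks with the same dimnames.
#' @export
prank_transform <- function(expr) {
  mat <- if (inherits(expr, "ExpressionMatrix")) expr$signal else expr
  if (nrow(mat) < 2L) stop("p-rank transform needs at least 2 genes")
  n <- nrow(mat)
  apply(mat, 2L, function(x) rank(x, ties.method = "average") / n)
}

#' Per-gene expression divergence between two tissues
#'
#' The divergence of gene i between tissues t1 and t2 is the absolute
#' difference of its p-ranks, `E_i = |p_i,t1 - p_i,t2|`. E is symmetric in
#' the tissue order and bounded by (n - 1)/n.
#'
#' @param pr A p-rank matrix from [prank_transform()].
#' @param t1,t2 Tissue column names.
#' @return Named numeric vector of E values (names = gene ids).
#' @export
gene_divergence <- function(pr, t1, t2) {
  for (t in c(t1, t2))
    if (!t %in% colnames(pr)) stop("unknown tissue: ", t)
  abs(pr[, t1] - pr[, t2])
}

#' Conservatively expressed genes for one tissue pair
#'
#' Genes whose divergence falls in the lowest `q` fraction of all gene
#' divergence values for the pair. The threshold is the empirical
#' q-quantile: with G untied E values exactly `ceiling(q * G)` genes are
#' returned; ties at the threshold are all included.
#'
#' @param div Named numeric vector of per-gene divergences
#'   (from [gene_divergence()]).
#' @param q Quantile fraction in (0, 1); default 0.05 (the lowest 5%).
#' @return Character vector of gene ids.
#' @export
conserved_genes <- function(div, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (is.null(names(div))) stop("`div` must be named by gene id")
  thr <- sort(div)[ceiling(q * length(div))]
  names(div)[div <= thr]
}

#' Ubiquitously conservatively expressed genes in a tissue group
#'
#' Default mode `"all_pairs"`: genes conserved (lowest-`q` divergence) in
#' every unordered tissue pair of the group, i.e. the intersection of the
#' per-pair [conserved_genes()] sets. Alternative mode `"top_expression"`:
#' genes whose p-rank is in the top `q` fraction in every tissue of the
#' group (highly expressed everywhere); provided because "expressed as the
#' top 5% in a group of tissues" also admits that reading.
#'
#' @param pr P-rank matrix.
#' @param group Character vector of at least two tissue ids.
#' @param q Fraction in (0, 1); default 0.05.
#' @param mode `"all_pairs"` (default) or `"top_expression"`.
#' @return Character vector of gene ids.
#' @export
ubiquitous_conserved <- function(pr, group, q = 0.05,
                                 mode = c("all_pairs", "top_expression")) {
  mode <- match.arg(mode)
  if (length(group) < 2L) stop("tissue group must contain at least 2 tissues")
  missing_t <- setdiff(group, colnames(pr))
  if (length(missing_t))
    stop("tissue(s) not in p-rank matrix: ", paste(missing_t, collapse = ", "))
  if (mode == "top_expression") {
    sub <- pr[, group, drop = FALSE]
    keep <- rowSums(sub >= 1 - q) == length(group)
    return(rownames(pr)[keep])
  }
  prs <- utils::combn(sort(group), 2L)
  sets <- lapply(seq_len(ncol(prs)), function(j) {
    conserved_genes(gene_divergence(pr, prs[1, j], prs[2, j]), q = q)
  })
  Reduce(intersect, sets)
}

#' Stratified divergence comparison across fate-map pair classes
#'
#' Pools per-gene divergences E over all tissue pairs of each class
#' (inner / mid / outer neighbor classes of the fate map) and compares the
#' pooled distributions between classes with two-sample t and
#' Kolmogorov-Smirnov tests. Per-pair mean divergences are reported as well
#' (the curve-per-pair view of the same stratification).
#'
#' @param pr P-rank matrix covering every leaf of `map`.
#' @param map A [fatemap()] object.
#' @param keep_values If `TRUE`, the pooled per-class E vectors are returned
#'   under `$pooled` (can be large).
#' @return A list with `summary` (per class: number of pairs, pooled values,
#'   mean E), `per_pair` (t1, t2, class, mean E), `tests` (class pairing,
#'   t-test and KS p-values; `NA` when a class is empty or degenerate) and
#'   optionally `pooled`.
#' @export
divergence_by_pair_class <- function(pr, map, keep_values = FALSE) {
  missing_t <- setdiff(map$leaves, colnames(pr))
  if (length(missing_t))
    stop("leaf tissue(s) missing from p-rank matrix: ",
         paste(missing_t, collapse = ", "))
  pc <- pair_classes(map)
  pooled <- list(inner = numeric(0), mid = numeric(0), outer = numeric(0))
  per_pair_mean <- numeric(nrow(pc))
  for (i in seq_len(nrow(pc))) {
    e <- gene_divergence(pr, pc$t1[i], pc$t2[i])
    pooled[[pc$class[i]]] <- c(pooled[[pc$class[i]]], e)
    per_pair_mean[i] <- mean(e)
  }
  classes <- c("inner", "mid", "outer")
  summary <- data.frame(
    class = classes,
    n_pairs = vapply(classes, function(k) sum(pc$class == k), 0L),
    n_values = vapply(pooled, length, 0L),
    mean_E = vapply(pooled, function(v) if (length(v)) mean(v) else NA_real_,
                    0),
    row.names = NULL, stringsAsFactors = FALSE)
  comps <- utils::combn(classes, 2L)
  tests <- data.frame(comparison = paste(comps[1, ], comps[2, ], sep = "_vs_"),
                      t_p = NA_real_, ks_p = NA_real_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(comps))) {
    a <- pooled[[comps[1, j]]]; b <- pooled[[comps[2, j]]]
    degenerate <- length(a) < 2L || length(b) < 2L ||
      (stats::sd(a) == 0 && stats::sd(b) == 0)
    if (!degenerate) {
      tests$t_p[j] <- stats::t.test(a, b)$p.value
      tests$ks_p[j] <- suppressWarnings(stats::ks.test(a, b)$p.value)
    }
  }
  out <- list(summary = summary,
              per_pair = cbind(pc, mean_E = per_pair_mean),
              tests = tests)
  if (keep_values) out$pooled <- pooled
  out
}
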