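#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing `k` or more interest genes in a module of size
#' `m` when `n_int` genes are drawn without replacement from a universe of
#' `N_u` genes:
#' `p = sum_{j >= k} C(m, j) C(N_u - m, n_int - j) / C(N_u, n_int)`.
#' `k = 0` gives p = 1, and p is monotone non-increasing in k.
#'
#' @param k Observed overlap count between the interest list and the module.
#' @param n_int Size of the interest gene list.
#' @param m Module size within the universe.
#' @param N_u Universe size.
#' @return Upper-tail p-value in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(k, n_int, m, N_u) {
  for (nm in c("k", "n_int", "m", "N_u")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop("'", nm, "' must be a single non-negative integer")
  }
  if (m > N_u) stop("'m' exceeds the universe size 'N_u'")
  if (n_int > N_u) stop("'n_int' exceeds the universe size 'N_u'")
  if (k > min(n_int, m)) stop("'k' exceeds min(n_int, m)")
  stats::phyper(k - 1, m, N_u - m, n_int, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies a p-value by the number of tests performed, capped at 1:
#' with n tests each significant with probability beta, the family-wise
#' chance of at least one significant call is below n * beta.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param n_tests Number of tests (>= 1).
#' @return Adjusted p-value(s), `pmin(1, p * n_tests)`.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (n_tests < 1 || n_tests != round(n_tests))
    stop("'n_tests' must be a positive integer")
  pmin(1, p * n_tests)
}

#' Module over-representation analysis of a gene list
#'
#' Tests every module of a collection for enrichment of an interest list
#' (e.g. the genes conservatively expressed in a tissue group) against the
#' chip universe, with Bonferroni correction over the modules tested.
#'
#' @param interest Character vector of interest gene ids; must be a subset
#'   of `universe`.
#' @param sets A `GeneSetCollection` or named list of gene id vectors.
#' @param universe Character vector of universe gene ids (the chip).
#' @return Data frame sorted by ascending p (ties broken by module id) with
#'   columns `module_id`, `k`, `n_int`, `m`, `N_u`, `p`, `p_adj`,
#'   `namespace`.
#' @export
enrich <- function(interest, sets, universe) {
  universe <- unique(as.character(universe))
  interest <- unique(as.character(interest))
  outside <- setdiff(interest, universe)
  if (length(outside))
    stop("interest gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  ns <- attr(sets, "namespace")
  if (is.null(ns)) ns <- stats::setNames(rep("other", length(sets)), names(sets))
  n_int <- length(interest)
  N_u <- length(universe)
  res <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    k <- length(intersect(interest, members))
    data.frame(module_id = id, k = k, n_int = n_int,
               m = length(members), N_u = N_u,
               p = hypergeom_pvalue(k, n_int, length(members), N_u),
               namespace = unname(ns[id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni_adjust(out$p, nrow(out))
  out <- out[order(out$p, out$module_id), ]
  rownames(out) <- NULL
  out[c("module_id", "k", "n_int", "m", "N_u", "p", "p_adj", "namespace")]
}
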