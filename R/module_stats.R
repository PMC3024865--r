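#' Log2 expression matrix
#'
#' Converts linear-scale signals to log2 after clamping at a floor
#' (default 1.0, so weak microarray intensities below one unit do not blow
#' up to large negative logs). All downstream distance and correlation
#' statistics operate on this scale.
#'
#' @param expr An [expression_matrix()] object or numeric matrix.
#' @param floor Lower clamp applied before log2 (default 1).
#' @return Numeric genes-by-tissues matrix of log2 signals.
#' @export
log_expression <- function(expr, floor = 1) {
  mat <- if (inherits(expr, "ExpressionMatrix")) expr$signal else expr
  log2(pmax(mat, floor))
}

#' Expression distance of a gene module between two tissues
#'
#' The distance of module g between tissues t1 and t2 is the size-normalized
#' squared difference of log2 expression,
#' `D = (1/n) * sum_i (S_i,t1 - S_i,t2)^2` over the n member genes
#' (`method = "mean_squared"`, the default). `method = "euclidean"` takes
#' the square root of that quantity. D is symmetric, non-negative, zero for
#' identical tissues, and invariant to a common multiplicative rescaling of
#' the raw signals (a log2 shift cancels in the differences).
#'
#' @param logexpr Log2 matrix from [log_expression()].
#' @param module Character vector of member gene ids.
#' @param t1,t2 Tissue column names.
#' @param method `"mean_squared"` (default) or `"euclidean"`.
#' @return Non-negative scalar D.
#' @export
module_distance <- function(logexpr, module, t1, t2,
                            method = c("mean_squared", "euclidean")) {
  method <- match.arg(method)
  missing_g <- setdiff(module, rownames(logexpr))
  if (length(missing_g))
    stop("module gene(s) absent from expression matrix: ",
         paste(missing_g, collapse = ", "))
  for (t in c(t1, t2))
    if (!t %in% colnames(logexpr)) stop("unknown tissue: ", t)
  d <- logexpr[module, t1] - logexpr[module, t2]
  ms <- mean(d^2)
  if (method == "euclidean") sqrt(ms) else ms
}

#' Module distances for all modules over a set of tissue pairs
#'
#' Vectorized sweep of [module_distance()] over a gene-set collection and a
#' pair list; used to build the pooled distance null and the per-pair
#' statistics table.
#'
#' @param logexpr Log2 expression matrix.
#' @param modules `GeneSetCollection` or named list of gene id vectors.
#' @param pairs Two-column matrix of tissue pairs; default all unordered
#'   pairs of the matrix columns.
#' @param method Passed to [module_distance()].
#' @return Data frame with columns `module_id`, `t1`, `t2`, `D`.
#' @export
all_pair_distances <- function(logexpr, modules, pairs = NULL,
                               method = c("mean_squared", "euclidean")) {
  method <- match.arg(method)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(sort(colnames(logexpr)), 2L))
  }
  idx <- lapply(modules, function(g) {
    missing_g <- setdiff(g, rownames(logexpr))
    if (length(missing_g))
      stop("module gene(s) absent from expression matrix: ",
           paste(missing_g, collapse = ", "))
    match(g, rownames(logexpr))
  })
  res <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    v <- (logexpr[, pairs[j, 1]] - logexpr[, pairs[j, 2]])^2
    D <- vapply(idx, function(ix) mean(v[ix]), 0)
    if (method == "euclidean") D <- sqrt(D)
    res[[j]] <- data.frame(module_id = names(modules),
                           t1 = pairs[j, 1], t2 = pairs[j, 2], D = D,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Fit the pooled normal null for module distances
#'
#' Module distances pooled over all modules and all tissue pairs of one
#' dataset are treated as approximately normal; this fits that null by the
#' sample mean and standard deviation (denominator n - 1) and reports
#' skewness and excess kurtosis as a normality diagnostic.
#'
#' @param all_D Numeric vector of pooled D values (or the data frame from
#'   [all_pair_distances()], whose `D` column is used). Intended pool size
#'   is large (hundreds or more); the fit itself requires only two distinct
#'   values.
#' @return Object of class `DistanceNull`: list with `mu`, `sigma`, `n`,
#'   `skewness`, `kurtosis_excess`.
#' @export
fit_distance_null <- function(all_D) {
  if (is.data.frame(all_D)) all_D <- all_D$D
  all_D <- as.numeric(all_D)
  if (length(all_D) < 2L) stop("need at least 2 distance values to fit a null")
  mu <- mean(all_D)
  sigma <- stats::sd(all_D)
  if (sigma == 0) stop("degenerate distance pool: zero variance")
  z <- (all_D - mu) / sigma
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  stage_log("distance_null",
            "fitted normal null on %d D values: mu=%.4g sigma=%.4g skewness=%.3f excess kurtosis=%.3f",
            length(all_D), mu, sigma, skew, kurt)
  structure(list(mu = mu, sigma = sigma, n = length(all_D),
                 skewness = skew, kurtosis_excess = kurt),
            class = "DistanceNull")
}

#' @export
print.DistanceNull <- function(x, ...) {
  cat(sprintf("DistanceNull: mu=%.4g sigma=%.4g (pool n=%d, skewness=%.3f)\n",
              x$mu, x$sigma, x$n, x$skewness))
  invisible(x)
}

#' Lower-tail p-value of a module distance
#'
#' `p = Phi((D - mu) / sigma)` under the fitted pooled null: a small p
#' means an unusually small distance, i.e. the module is conservatively
#' expressed in the tissue pair.
#'
#' @param D Module distance(s).
#' @param null A `DistanceNull` from [fit_distance_null()].
#' @return p-value(s) in `[0, 1]`, monotone increasing in D.
#' @export
distance_pvalue <- function(D, null) {
  stopifnot(inherits(null, "DistanceNull"))
  stats::pnorm(D, mean = null$mu, sd = null$sigma)
}

#' Integrated distance p-value for a tissue group
#'
#' The mean distance over a fate-map node's tissue pairs, `D_sub`, follows
#' `N(mu, sigma^2 / N)` under the null when the pooled fit holds, N being
#' the group sample size. The integrated p-value is the lower tail
#' `Phi((D_sub - mu) / (sigma / sqrt(N)))`; with a single pair it reduces
#' exactly to [distance_pvalue()].
#'
#' @param node_D Vector of D values for the node's tissue pairs.
#' @param null A `DistanceNull`.
#' @param n_size Group sample size N; defaults to `length(node_D)` (the
#'   number of pairwise values, matching the pairwise convention of the Z
#'   integration). Pass the number of tissues for the alternative
#'   convention.
#' @return Scalar integrated p-value.
#' @export
integrated_distance_pvalue <- function(node_D, null, n_size = NULL) {
  stopifnot(inherits(null, "DistanceNull"))
  if (!length(node_D)) stop("no distance values supplied for the group")
  if (is.null(n_size)) n_size <- length(node_D)
  stats::pnorm(mean(node_D), mean = null$mu, sd = null$sigma / sqrt(n_size))
}

#' Kolmogorov-Smirnov difference test for a module between two tissues
#'
#' Two-sample KS test comparing the module member genes' p-rank values in
#' the two tissues; a small p flags the module as differentially expressed
#' in the pair. The exact small-sample distribution is used when both
#' samples are at most `exact_max` (default 25), the asymptotic one
#' otherwise.
#'
#' @param pr P-rank matrix.
#' @param module Character vector of member gene ids.
#' @param t1,t2 Tissue column names.
#' @param exact_max Largest sample size for the exact p-value (default 25).
#' @return KS p-value in `[0, 1]`.
#' @export
module_ks <- function(pr, module, t1, t2, exact_max = 25L) {
  missing_g <- setdiff(module, rownames(pr))
  if (length(missing_g))
    stop("module gene(s) absent from p-rank matrix: ",
         paste(missing_g, collapse = ", "))
  x <- pr[module, t1]
  y <- pr[module, t2]
  exact <- length(x) <= exact_max && length(y) <= exact_max
  suppressWarnings(stats::ks.test(x, y, exact = exact))$p.value
}

#' Stouffer-style integration of pairwise KS p-values
#'
#' Each pairwise p-value is transformed to a normal quantile
#' `Z_ij = qnorm(p_ij)` and the group score is `Z_sub = sum(Z_ij) / sqrt(n)`
#' over the n pairwise values, so that under the null (uniform p) Z_sub is
#' standard normal. The returned p-value is the lower tail `pnorm(Z_sub)`:
#' a significantly small Z_sub marks the module as differentially expressed
#' within the tissue group. p-values at exactly 0 or 1 are clamped to
#' `[1e-15, 1 - 1e-15]` with a warning before the quantile transform.
#'
#' @param p_list Numeric vector of pairwise KS p-values.
#' @return List with `z_sub` and `p` (= `pnorm(z_sub)`); for a single
#'   p-value the returned p equals the input.
#' @export
integrate_ks <- function(p_list) {
  if (!length(p_list)) stop("no p-values supplied")
  if (any(p_list < 0 | p_list > 1)) stop("p-values must lie in [0, 1]")
  p <- clamp_pvalues(p_list)
  z <- stats::qnorm(p)
  z_sub <- sum(z) / sqrt(length(z))
  list(z_sub = z_sub, p = stats::pnorm(z_sub))
}

#' Pearson profile correlation of a module between two tissues
#'
#' Correlation across the module's member genes between the two tissue
#' expression profiles, by default on the log2 scale (`scale = "log2"`;
#' `scale = "prank"` correlates the p-rank profiles instead). A high r
#' flags a linearly correlated expression pattern; r is invariant to
#' per-tissue affine rescaling of the profile.
#'
#' @param mat Log2 expression matrix (or p-rank matrix for
#'   `scale = "prank"`).
#' @param module Character vector of member gene ids (at least 3).
#' @param t1,t2 Tissue column names.
#' @param scale Label of the input scale; informational only, the matrix
#'   supplied is used as-is.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when a profile is
#'   constant (r undefined).
#' @export
module_correlation <- function(mat, module, t1, t2,
                               scale = c("log2", "prank")) {
  scale <- match.arg(scale)
  missing_g <- setdiff(module, rownames(mat))
  if (length(missing_g))
    stop("module gene(s) absent from matrix: ",
         paste(missing_g, collapse = ", "))
  if (length(module) < 3L) stop("correlation needs a module of at least 3 genes")
  x <- mat[module, t1]
  y <- mat[module, t2]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(sprintf("constant profile for module in '%s'/'%s': r undefined",
                    t1, t2))
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-pair module statistics table
#'
#' Computes, for every module and every requested tissue pair, the three
#' pairwise measurements: distance D (log2 scale), KS difference p-value
#' (p-rank scale) and Pearson correlation r (log2 scale).
#'
#' @param logexpr Log2 expression matrix.
#' @param pr P-rank matrix (same dimnames).
#' @param modules `GeneSetCollection` or named list.
#' @param pairs Two-column matrix of tissue pairs; default all pairs.
#' @param method Distance variant, see [module_distance()].
#' @param exact_max KS exact-p switch, see [module_ks()].
#' @return Data frame `module_id, t1, t2, D, p_ks, r`.
#' @export
module_pair_stats <- function(logexpr, pr, modules, pairs = NULL,
                              method = c("mean_squared", "euclidean"),
                              exact_max = 25L) {
  method <- match.arg(method)
  if (is.null(pairs)) pairs <- t(utils::combn(sort(colnames(logexpr)), 2L))
  out <- all_pair_distances(logexpr, modules, pairs, method = method)
  ks <- numeric(nrow(out)); r <- numeric(nrow(out))
  k <- 1L
  for (j in seq_len(nrow(pairs))) {
    for (m in names(modules)) {
      ks[k] <- module_ks(pr, modules[[m]], pairs[j, 1], pairs[j, 2],
                         exact_max = exact_max)
      r[k] <- module_correlation(logexpr, modules[[m]],
                                 pairs[j, 1], pairs[j, 2])
      k <- k + 1L
    }
  }
  out$p_ks <- ks
  out$r <- r
  out
}

#' Node-level module summary and classification
#'
#' Aggregates the per-pair statistics of one fate-map node's tissue pairs
#' into the three group-level measures and flags each module:
#' * conserved: integrated distance p (`D_sub` against the pooled null with
#'   variance shrunk by the group size) below `alpha`;
#' * differential: lower-tail p of the Stouffer-integrated KS Z below
#'   `alpha`;
#' * correlated: mean pairwise Pearson r above `r_threshold`.
#' Raw (uncorrected) p-values drive the flags; Benjamini-Hochberg adjusted
#' columns are emitted additionally for reference.
#'
#' @param pair_stats Data frame from [module_pair_stats()] restricted to the
#'   node's pairs; every module must have a row for every pair.
#' @param null A `DistanceNull`.
#' @param alpha Significance level for the distance and KS flags
#'   (default 0.05).
#' @param r_threshold Group correlation threshold (default 0.9).
#' @param n_size Group sample size for the integrated distance p; default
#'   the number of pairs (see [integrated_distance_pvalue()]).
#' @return Data frame with one row per module (`module_id`, `n_pairs`,
#'   `D_sub`, `p_distance`, `z_sub`, `p_ks`, `r_mean`, BH columns, flags),
#'   with the per-measure flagged-module counts in attribute `counts`.
#' @export
summarize_node <- function(pair_stats, null, alpha = 0.05,
                           r_threshold = 0.9, n_size = NULL) {
  stopifnot(inherits(null, "DistanceNull"))
  mods <- unique(pair_stats$module_id)
  n_pairs_tot <- nrow(unique(pair_stats[c("t1", "t2")]))
  by_mod <- split(pair_stats, pair_stats$module_id)
  bad <- names(by_mod)[vapply(by_mod, nrow, 0L) != n_pairs_tot]
  if (length(bad))
    stop("missing pair statistics for module(s): ",
         paste(bad, collapse = ", "))
  rows <- lapply(by_mod[mods], function(df) {
    ks <- integrate_ks(df$p_ks)
    r_ok <- !is.na(df$r)
    if (any(!r_ok))
      warning(sprintf("module %s: %d undefined r value(s) excluded from r_mean",
                      df$module_id[1], sum(!r_ok)))
    data.frame(module_id = df$module_id[1],
               n_pairs = nrow(df),
               D_sub = mean(df$D),
               p_distance = integrated_distance_pvalue(df$D, null,
                                                       n_size = n_size),
               z_sub = ks$z_sub,
               p_ks = ks$p,
               r_mean = if (any(r_ok)) mean(df$r[r_ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_distance_bh <- stats::p.adjust(out$p_distance, method = "BH")
  out$p_ks_bh <- stats::p.adjust(out$p_ks, method = "BH")
  out$conserved <- out$p_distance < alpha
  out$differential <- out$p_ks < alpha
  out$correlated <- !is.na(out$r_mean) & out$r_mean > r_threshold
  attr(out, "counts") <- c(conserved = sum(out$conserved),
                           differential = sum(out$differential),
                           correlated = sum(out$correlated))
  out
}
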