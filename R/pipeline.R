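#' Pipeline run configuration
#'
#' Bundles the input locations (or in-memory objects) and the analysis
#' parameters of one end-to-end run. All thresholds default to the standard
#' values of the method: conservative-gene quantile q = 0.05, module
#' significance alpha = 0.05, correlation thresholds r > 0.9 and
#' r_mean > 0.9.
#'
#' @param expression Path to an expression TSV or an
#'   [expression_matrix()] object.
#' @param gene_sets Path to a GMT file or a `GeneSetCollection`.
#' @param fate_map Path to a Newick file or a [fatemap()] object.
#' @param fate_map_meta Path to the YAML sidecar (required when `fate_map`
#'   is a path).
#' @param replicate_map Optional: named character vector
#'   (raw column -> tissue) or path to a two-column TSV
#'   (`raw_column`, `tissue`).
#' @param homology Optional: path to an ortholog pair TSV or a
#'   `HomologyMap` (carried through for cross-species work).
#' @param out_dir Output directory for the report TSVs; `NULL` disables
#'   writing.
#' @param q Conservative-gene divergence quantile (default 0.05).
#' @param alpha Module significance level (default 0.05).
#' @param r_threshold Group correlation threshold (default 0.9).
#' @param log2_floor Signal clamp before log2 (default 1).
#' @param distance_method `"mean_squared"` (default) or `"euclidean"`.
#' @param n_convention Group size N for the integrated distance p:
#'   `"pairs"` (default, the number of pairwise values) or `"tissues"`.
#' @param ks_exact_max Exact-KS sample-size switch (default 25).
#' @param min_module_size Minimum module size on the chip (default 6).
#' @param nodes Optional character vector restricting the per-node analysis
#'   to these internal nodes; default all internal nodes with >= 2 leaves.
#' @param seed Integer seed recorded in the provenance header (the analysis
#'   itself is deterministic).
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(expression, gene_sets, fate_map,
                       fate_map_meta = NULL, replicate_map = NULL,
                       homology = NULL, out_dir = NULL,
                       q = 0.05, alpha = 0.05, r_threshold = 0.9,
                       log2_floor = 1,
                       distance_method = c("mean_squared", "euclidean"),
                       n_convention = c("pairs", "tissues"),
                       ks_exact_max = 25L, min_module_size = 6L,
                       nodes = NULL, seed = 1L) {
  distance_method <- match.arg(distance_method)
  n_convention <- match.arg(n_convention)
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1,
            r_threshold >= -1, r_threshold <= 1, log2_floor > 0)
  structure(list(expression = expression, gene_sets = gene_sets,
                 fate_map = fate_map, fate_map_meta = fate_map_meta,
                 replicate_map = replicate_map, homology = homology,
                 out_dir = out_dir, q = q, alpha = alpha,
                 r_threshold = r_threshold, log2_floor = log2_floor,
                 distance_method = distance_method,
                 n_convention = n_convention,
                 ks_exact_max = as.integer(ks_exact_max),
                 min_module_size = as.integer(min_module_size),
                 nodes = nodes, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A `RunConfig`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("expression", "gene_sets", "fate_map", "fate_map_meta",
                "replicate_map", "homology", "out_dir")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
        !grepl("^/", cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  }
  do.call(run_config, cfg)
}

resolve_inputs <- function(config) {
  rep_map <- config$replicate_map
  if (is.character(rep_map) && length(rep_map) == 1L && file.exists(rep_map)) {
    df <- read_tsv(rep_map)
    rep_map <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  }
  expr <- config$expression
  if (is.character(expr)) expr <- read_expression_table(expr, rep_map)
  stopifnot(inherits(expr, "ExpressionMatrix"))

  map <- config$fate_map
  if (is.character(map)) {
    if (is.null(config$fate_map_meta))
      stop("fate_map_meta (YAML sidecar) is required with a Newick path")
    map <- read_fatemap(map, config$fate_map_meta)
  }
  stopifnot(inherits(map, "FateMap"))

  sets <- config$gene_sets
  if (is.character(sets))
    sets <- read_gene_sets(sets, universe = expr$gene_ids,
                           min_size = config$min_module_size)
  hom <- config$homology
  if (is.character(hom)) hom <- read_homology(hom)
  list(expr = expr, map = map, sets = sets, homology = hom)
}

provenance_header <- function(config) {
  c(sprintf("fatemapExpr %s",
            as.character(utils::packageVersion("fatemapExpr"))),
    sprintf("q=%g alpha=%g r_threshold=%g log2_floor=%g", config$q,
            config$alpha, config$r_threshold, config$log2_floor),
    sprintf("distance_method=%s n_convention=%s ks_exact_max=%d min_module_size=%d seed=%d",
            config$distance_method, config$n_convention, config$ks_exact_max,
            config$min_module_size, config$seed))
}

#' Run the full lineage-aware expression analysis
#'
#' Executes the pipeline end to end: read inputs, p-rank transform,
#' stratified per-gene divergence comparison, per-pair module statistics
#' (distance / KS / correlation), pooled distance-null fit, per-node module
#' summaries and flag counts, per-node conserved-gene calling and
#' hypergeometric enrichment. The pipeline is a pure function of
#' (inputs, config): identical inputs yield identical outputs, and the
#' written report files carry a provenance header echoing the parameters.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [load_run_config()]).
#' @return A list of class `PipelineResult` with elements `expr`, `prank`,
#'   `map`, `sets`, `null` (the fitted `DistanceNull`),
#'   `class_comparison`, `pair_stats`, `node_summary`, `node_counts`,
#'   `conserved_genes`, `enrichment`, `config`; written files (when
#'   `out_dir` is set) under attribute `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  inp <- tryCatch(resolve_inputs(config),
                  error = function(e) stop("stage 'read': ",
                                           conditionMessage(e), call. = FALSE))
  expr <- inp$expr; map <- inp$map; sets <- inp$sets
  stage_log("read", "%d genes x %d tissues; %d modules; %d fate-map leaves",
            length(expr$gene_ids), length(expr$tissue_ids), length(sets),
            length(map$leaves))
  missing_leaves <- setdiff(map$leaves, expr$tissue_ids)
  if (length(missing_leaves))
    stop("stage 'read': fate-map leaf tissue(s) missing from expression data: ",
         paste(missing_leaves, collapse = ", "))

  pr <- prank_transform(expr)
  logexpr <- log_expression(expr, floor = config$log2_floor)
  stage_log("prank", "transformed %d genes in %d tissues",
            nrow(pr), ncol(pr))

  cls <- divergence_by_pair_class(pr, map)
  stage_log("gene_divergence",
            "pair classes inner/mid/outer = %s; mean E = %s",
            paste(cls$summary$n_pairs, collapse = "/"),
            paste(sprintf("%.4f", cls$summary$mean_E), collapse = "/"))

  nodes <- config$nodes
  if (is.null(nodes)) nodes <- analysis_nodes(map)
  unknown <- setdiff(nodes, map$tree$node.label)
  if (length(unknown))
    stop("stage 'nodes': unknown node(s): ", paste(unknown, collapse = ", "))

  node_pair_list <- lapply(nodes, function(nd) node_pairs(map, nd))
  names(node_pair_list) <- nodes
  needed <- unique(do.call(rbind, node_pair_list))

  all_pairs <- t(utils::combn(sort(map$leaves), 2L))
  allD <- all_pair_distances(logexpr[, map$leaves, drop = FALSE],
                             sets, all_pairs, method = config$distance_method)
  null <- fit_distance_null(allD)
  stats_tab <- module_pair_stats(logexpr, pr, sets, pairs = needed,
                                 method = config$distance_method,
                                 exact_max = config$ks_exact_max)
  stage_log("module_stats", "%d modules x %d pairs evaluated (%d pairs pooled for the null)",
            length(sets), nrow(needed), nrow(all_pairs))

  pair_key <- function(df) paste(df$t1, df$t2, sep = "|")
  summaries <- vector("list", length(nodes))
  counts <- vector("list", length(nodes))
  conserved <- vector("list", length(nodes))
  enrich_tabs <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    keys <- paste(node_pair_list[[nd]][, 1], node_pair_list[[nd]][, 2],
                  sep = "|")
    sub <- stats_tab[pair_key(stats_tab) %in% keys, , drop = FALSE]
    n_size <- if (config$n_convention == "tissues")
      length(leaf_group(map, nd)) else NULL
    smry <- summarize_node(sub, null, alpha = config$alpha,
                           r_threshold = config$r_threshold, n_size = n_size)
    counts[[i]] <- data.frame(node = nd,
                              n_leaves = length(leaf_group(map, nd)),
                              n_pairs = nrow(node_pair_list[[nd]]),
                              n_modules = nrow(smry),
                              t(attr(smry, "counts")),
                              stringsAsFactors = FALSE)
    summaries[[i]] <- cbind(node = nd, smry, stringsAsFactors = FALSE)

    genes_nd <- ubiquitous_conserved(pr, leaf_group(map, nd), q = config$q)
    conserved[[i]] <- if (length(genes_nd))
      data.frame(node = nd, gene_id = genes_nd, stringsAsFactors = FALSE)
    if (length(genes_nd)) {
      etab <- enrich(genes_nd, sets, expr$gene_ids)
      enrich_tabs[[i]] <- cbind(node = nd, etab, stringsAsFactors = FALSE)
    }
    stage_log("node", "%s: %d leaves, %d pairs, flags C/D/R = %s, %d conserved genes",
              nd, length(leaf_group(map, nd)), nrow(node_pair_list[[nd]]),
              paste(attr(smry, "counts"), collapse = "/"), length(genes_nd))
  }

  res <- structure(list(
    expr = expr, prank = pr, map = map, sets = sets, null = null,
    class_comparison = cls,
    pair_stats = stats_tab,
    node_summary = do.call(rbind, summaries),
    node_counts = do.call(rbind, counts),
    conserved_genes = do.call(rbind, conserved),
    enrichment = do.call(rbind, enrich_tabs),
    homology = inp$homology,
    config = config), class = "PipelineResult")

  if (!is.null(config$out_dir)) {
    hdr <- provenance_header(config)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(pair_stats = "pair_stats.tsv",
               node_summary = "node_summary.tsv",
               node_counts = "node_counts.tsv",
               class_comparison = "class_comparison.tsv",
               class_tests = "class_tests.tsv",
               conserved_genes = "conserved_genes.tsv",
               enrichment = "enrichment.tsv")
    paths <- file.path(config$out_dir, files)
    names(paths) <- names(files)
    write_tsv(res$pair_stats, paths[["pair_stats"]], hdr)
    write_tsv(res$node_summary, paths[["node_summary"]], hdr)
    write_tsv(res$node_counts, paths[["node_counts"]], hdr)
    write_tsv(res$class_comparison$summary, paths[["class_comparison"]], hdr)
    write_tsv(res$class_comparison$tests, paths[["class_tests"]], hdr)
    if (!is.null(res$conserved_genes))
      write_tsv(res$conserved_genes, paths[["conserved_genes"]], hdr)
    if (!is.null(res$enrichment))
      write_tsv(res$enrichment, paths[["enrichment"]], hdr)
    attr(res, "files") <- paths
    stage_log("write", "report bundle written to %s", config$out_dir)
  }
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d genes, %d tissues, %d modules, %d nodes analyzed\n",
              length(x$expr$gene_ids), length(x$expr$tissue_ids),
              length(x$sets), nrow(x$node_counts)))
  invisible(x)
}

#' Cross-species comparison of significant-module proportions
#'
#' For two node-summary tables covering the same fate-map nodes, computes
#' per node and per measure (distance / KS / correlation) the percentage of
#' significant modules out of each species' own analyzed module total, the
#' size-adjusted comparison appropriate when the two chips carry different
#' module numbers.
#'
#' @param summary_a,summary_b `node_summary` data frames from
#'   [run_pipeline()] results (must contain `node` and the three flag
#'   columns).
#' @param homology Optional `HomologyMap`; accepted for provenance, the
#'   proportion comparison itself is module-based and needs no gene
#'   pairing.
#' @return Data frame `node`, `measure`, `pct_a`, `pct_b`, `n_modules_a`,
#'   `n_modules_b`.
#' @export
cross_species_compare <- function(summary_a, summary_b, homology = NULL) {
  for (nm in c("node", "conserved", "differential", "correlated")) {
    if (!nm %in% names(summary_a) || !nm %in% names(summary_b))
      stop("summaries must contain column '", nm, "'")
  }
  if (!is.null(homology)) stopifnot(inherits(homology, "HomologyMap"))
  nodes_a <- unique(summary_a$node)
  nodes_b <- unique(summary_b$node)
  if (!setequal(nodes_a, nodes_b))
    stop("node sets differ between species; only in A: [",
         paste(setdiff(nodes_a, nodes_b), collapse = ", "),
         "]; only in B: [",
         paste(setdiff(nodes_b, nodes_a), collapse = ", "), "]")
  measures <- c(distance = "conserved", ks = "differential",
                correlation = "correlated")
  res <- lapply(sort(nodes_a), function(nd) {
    a <- summary_a[summary_a$node == nd, ]
    b <- summary_b[summary_b$node == nd, ]
    data.frame(node = nd, measure = names(measures),
               pct_a = 100 * vapply(measures, function(f) mean(a[[f]]), 0),
               pct_b = 100 * vapply(measures, function(f) mean(b[[f]]), 0),
               n_modules_a = nrow(a), n_modules_b = nrow(b),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
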