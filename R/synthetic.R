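#' Specification for a fate-map-structured synthetic dataset
#'
#' Describes a genes-by-tissues expression dataset whose tissues are the
#' leaves of a fate map and whose log2 expression evolves along the tree by
#' Brownian diffusion: each gene starts from a root value drawn from
#' `N(baseline_mean, baseline_sd^2)` and accumulates independent normal
#' increments of variance `tau2 * branch length` along every edge, so that
#' leaf-leaf covariance decays with tree distance — the structure behind
#' the inner < mid < outer divergence ordering. Planted module effects make
#' every pipeline stage testable against ground truth:
#' * conserved modules: diffusion variance inside the target clade
#'   multiplied by `conserved_factor` (< 1), so within-clade distances
#'   shrink;
#' * divergent modules: each tissue of the target clade expresses the
#'   member genes at a distinct level — tissue j of the clade is shifted by
#'   `divergent_shift * (j - (k + 1)/2)` log2 units (a zero-centered ladder
#'   with adjacent tissues `divergent_shift` apart), i.e. graded
#'   tissue-specific regulation;
#' * correlated modules: a single shared gene profile across all tissues
#'   plus per-tissue noise of sd `correlated_noise_sd`.
#' Signals are exponentiated back to linear scale and each tissue is
#' emitted as `n_replicates` replicate columns with multiplicative noise
#' (log2 sd `replicate_sd`).
#'
#' @param fate_map A [fatemap()] with branch lengths; default the shipped
#'   24-tissue map.
#' @param n_genes Number of genes (default 2000).
#' @param n_modules,module_size Module layout: `n_modules` non-overlapping
#'   blocks of `module_size` genes (default 100 x 20).
#' @param n_conserved,n_divergent,n_correlated Numbers of planted modules
#'   of each role (defaults 10, 10, 0); the remainder are unplanted.
#' @param target_node Internal node whose clade carries the planted
#'   conserved/divergent effects (default `"Brain"`, six neural tissues).
#' @param baseline_mean,baseline_sd Root log2 signal distribution
#'   (defaults 6 and 2, microarray-like).
#' @param tau2 Brownian diffusion variance per unit branch length
#'   (default 0.2).
#' @param conserved_factor Within-clade diffusion multiplier for conserved
#'   modules (default 0.05; must be > 0).
#' @param divergent_shift Spacing delta, in log2 units, between the graded
#'   per-tissue expression levels of divergent modules (default 1.0).
#' @param correlated_noise_sd Per-tissue log2 noise around the shared
#'   profile of correlated modules (default 0.25).
#' @param n_replicates,replicate_sd Replicate columns per tissue and their
#'   log2 noise sd (defaults 2 and 0.1).
#' @param seed Integer seed; fully determines the dataset.
#' @return An object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(fate_map = default_fatemap(),
                           n_genes = 2000L,
                           n_modules = 100L,
                           module_size = 20L,
                           n_conserved = 10L,
                           n_divergent = 10L,
                           n_correlated = 0L,
                           target_node = "Brain",
                           baseline_mean = 6,
                           baseline_sd = 2,
                           tau2 = 0.2,
                           conserved_factor = 0.05,
                           divergent_shift = 1.0,
                           correlated_noise_sd = 0.25,
                           n_replicates = 2L,
                           replicate_sd = 0.1,
                           seed = 1L) {
  stopifnot(inherits(fate_map, "FateMap"))
  if (is.null(fate_map$tree$edge.length))
    stop("the fate map must carry branch lengths for simulation")
  if (module_size > n_genes)
    stop("module_size exceeds the number of genes")
  if (n_modules * module_size > n_genes)
    stop("module layout exceeds the number of genes (",
         n_modules, " x ", module_size, " > ", n_genes, ")")
  if (n_conserved + n_divergent + n_correlated > n_modules)
    stop("more planted modules than modules in the layout")
  if (conserved_factor <= 0) stop("conserved_factor must be > 0")
  if (!target_node %in% fate_map$tree$node.label)
    stop("unknown target node: ", target_node)
  if (length(leaf_group(fate_map, target_node)) < 2L)
    stop("target node must dominate at least 2 leaves")
  structure(list(fate_map = fate_map, n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 n_conserved = as.integer(n_conserved),
                 n_divergent = as.integer(n_divergent),
                 n_correlated = as.integer(n_correlated),
                 target_node = target_node,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 tau2 = tau2, conserved_factor = conserved_factor,
                 divergent_shift = divergent_shift,
                 correlated_noise_sd = correlated_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Remove all planted effects from a synthetic spec
#'
#' Returns the same specification with the planted conserved, divergent and
#' correlated module counts set to zero — the matched null (calibration)
#' dataset generator.
#'
#' @param spec A `SyntheticSpec`.
#' @return A `SyntheticSpec` with no planted effects.
#' @export
null_spec <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  spec$n_conserved <- 0L
  spec$n_divergent <- 0L
  spec$n_correlated <- 0L
  spec
}

#' Simulate a fate-map-structured expression dataset
#'
#' Draws one dataset from a [synthetic_spec()]. The random stream is seeded
#' once from `spec$seed` and consumed in a fixed order (root values, edge
#' increments in cladewise edge order, correlated-module profiles and
#' noise, replicate noise), so an identical spec yields a bit-identical
#' dataset.
#'
#' @param spec A `SyntheticSpec`.
#' @return A list of class `SyntheticDataset`:
#'   `expr` (replicate-averaged [expression_matrix()]),
#'   `raw` (linear-scale matrix of replicate columns),
#'   `replicate_map` (raw column -> tissue),
#'   `modules` (the module layout as a `GeneSetCollection`),
#'   `truth` (data frame `module_id`, `role`, `target_node`),
#'   `spec`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  tree <- spec$fate_map$tree
  ntip <- length(tree$tip.label)
  G <- spec$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))

  width <- max(3L, nchar(as.character(spec$n_modules)))
  module_ids <- sprintf("M%0*d", width, seq_len(spec$n_modules))
  members <- split(gene_ids[seq_len(spec$n_modules * spec$module_size)],
                   rep(seq_len(spec$n_modules), each = spec$module_size))
  names(members) <- module_ids
  roles <- rep("null", spec$n_modules)
  roles[seq_len(spec$n_conserved)] <- "conserved"
  roles[spec$n_conserved + seq_len(spec$n_divergent)] <- "divergent"
  roles[spec$n_conserved + spec$n_divergent +
          seq_len(spec$n_correlated)] <- "correlated"
  conserved_genes_idx <- match(unlist(members[roles == "conserved"],
                                      use.names = FALSE), gene_ids)

  # edges inside the target clade: parent is the target node or below it
  target_num <- ntip + match(spec$target_node, tree$node.label)
  eo <- ape::reorder.phylo(tree, "cladewise")
  in_clade <- logical(ntip + tree$Nnode)
  in_clade[target_num] <- TRUE
  edge_in_clade <- logical(nrow(eo$edge))
  for (k in seq_len(nrow(eo$edge))) {
    if (in_clade[eo$edge[k, 1]]) {
      edge_in_clade[k] <- TRUE
      in_clade[eo$edge[k, 2]] <- TRUE
    }
  }

  # Brownian diffusion along the tree
  vals <- matrix(NA_real_, G, ntip + tree$Nnode)
  vals[, ntip + 1L] <- stats::rnorm(G, spec$baseline_mean, spec$baseline_sd)
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    sd_edge <- rep(sqrt(spec$tau2 * eo$edge.length[k]), G)
    if (edge_in_clade[k] && length(conserved_genes_idx))
      sd_edge[conserved_genes_idx] <- sd_edge[conserved_genes_idx] *
        sqrt(spec$conserved_factor)
    vals[, child] <- vals[, par] + stats::rnorm(G, 0, sd_edge)
  }
  S <- vals[, seq_len(ntip), drop = FALSE]
  dimnames(S) <- list(gene_ids, tree$tip.label)

  # divergent modules: zero-centered ladder of per-tissue levels, adjacent
  # clade tissues (in tip order) divergent_shift log2 units apart
  clade_tips <- leaf_group(spec$fate_map, spec$target_node)
  clade_tips <- tree$tip.label[tree$tip.label %in% clade_tips]  # tip order
  if (spec$n_divergent > 0) {
    k <- length(clade_tips)
    levels <- spec$divergent_shift * (seq_len(k) - (k + 1) / 2)
    div_idx <- match(unlist(members[roles == "divergent"], use.names = FALSE),
                     gene_ids)
    for (j in seq_len(k))
      S[div_idx, clade_tips[j]] <- S[div_idx, clade_tips[j]] + levels[j]
  }

  # correlated modules: one shared profile plus small per-tissue noise
  if (spec$n_correlated > 0) {
    cor_idx <- match(unlist(members[roles == "correlated"], use.names = FALSE),
                     gene_ids)
    shared <- stats::rnorm(length(cor_idx), spec$baseline_mean,
                           spec$baseline_sd)
    S[cor_idx, ] <- shared +
      matrix(stats::rnorm(length(cor_idx) * ntip, 0, spec$correlated_noise_sd),
             length(cor_idx), ntip)
  }

  # linear-scale replicates with multiplicative noise
  raw_cols <- as.vector(t(outer(tree$tip.label,
                                seq_len(spec$n_replicates),
                                function(t, r) paste0(t, "_r", r))))
  replicate_map <- stats::setNames(rep(tree$tip.label,
                                       each = spec$n_replicates), raw_cols)
  raw <- matrix(NA_real_, G, length(raw_cols),
                dimnames = list(gene_ids, raw_cols))
  for (cn in raw_cols)
    raw[, cn] <- 2^(S[, replicate_map[[cn]]] +
                      stats::rnorm(G, 0, spec$replicate_sd))

  truth <- data.frame(module_id = module_ids, role = roles,
                      target_node = ifelse(roles %in% c("conserved",
                                                        "divergent"),
                                           spec$target_node, NA_character_),
                      stringsAsFactors = FALSE)
  structure(list(expr = expression_matrix(raw, replicate_map = replicate_map),
                 raw = raw,
                 replicate_map = replicate_map,
                 modules = gene_set_collection(members, gene_ids),
                 truth = truth,
                 spec = spec),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d genes x %d tissues (%d raw columns), %d modules (%s)\n",
              x$spec$n_genes, length(x$expr$tissue_ids), ncol(x$raw),
              x$spec$n_modules,
              paste(sprintf("%d %s", table(x$truth$role),
                            names(table(x$truth$role))), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk in the standard input formats
#'
#' Emits exactly the files the readers consume: the raw replicate-level
#' expression TSV, the replicate map, the module GMT, the fate-map Newick
#' and YAML sidecar, and the ground-truth table.
#'
#' @param sim A `SyntheticDataset` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             replicate_map = file.path(dir, "replicate_map.tsv"),
             gene_sets = file.path(dir, "modules.gmt"),
             fate_map = file.path(dir, "fatemap.nwk"),
             fate_map_meta = file.path(dir, "fatemap.yaml"),
             truth = file.path(dir, "truth.tsv"))
  df <- data.frame(gene_id = rownames(sim$raw), sim$raw,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, paths[["expression"]])
  write_tsv(data.frame(raw_column = names(sim$replicate_map),
                       tissue = unname(sim$replicate_map),
                       stringsAsFactors = FALSE),
            paths[["replicate_map"]])
  write_gene_sets(sim$modules, paths[["gene_sets"]])
  ape::write.tree(sim$spec$fate_map$tree, file = paths[["fate_map"]])
  yaml::write_yaml(list(germ_layer_nodes = sim$spec$fate_map$germ_layer_nodes,
                        super_nodes = sim$spec$fate_map$super_nodes),
                   paths[["fate_map_meta"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Planted-enrichment fixture
#'
#' Builds a universe, a module collection and an interest list in which a
#' designated module is strongly over-represented: `planted_overlap` of the
#' interest genes come from the planted module and the remainder are drawn
#' from outside it. Unplanted modules are random draws from the universe.
#'
#' @param universe_size,n_modules,module_size Layout (defaults 1000, 50, 30).
#' @param interest_size,planted_overlap Interest-list construction
#'   (defaults 20 and 15).
#' @param seed Integer seed.
#' @return List with `interest`, `sets` (a `GeneSetCollection`), `universe`
#'   and `planted_module` (the enriched module id).
#' @export
simulate_enrichment_fixture <- function(universe_size = 1000L,
                                        n_modules = 50L,
                                        module_size = 30L,
                                        interest_size = 20L,
                                        planted_overlap = 15L,
                                        seed = 1L) {
  stopifnot(planted_overlap <= interest_size,
            planted_overlap <= module_size,
            module_size <= universe_size)
  set.seed(seed)
  universe <- sprintf("u%05d", seq_len(universe_size))
  ids <- sprintf("M%03d", seq_len(n_modules))
  sets <- lapply(seq_len(n_modules),
                 function(i) sample(universe, module_size))
  names(sets) <- ids
  planted <- sets[[1L]]
  interest <- c(sample(planted, planted_overlap),
                sample(setdiff(universe, planted),
                       interest_size - planted_overlap))
  list(interest = interest,
       sets = gene_set_collection(sets, universe),
       universe = universe,
       planted_module = ids[1L])
}
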