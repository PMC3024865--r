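#' Developmental fate map
#'
#' A rooted tree whose leaves are the assayed adult tissues and whose
#' internal nodes are developmental stages (zygote, germ layers, segments).
#' Three internal nodes are designated germ layers (ectoderm, mesoderm,
#' endoderm) and a set of internal nodes are designated super-nodes: the
#' groups of "neighbor tissues" used for the inner pair class. Super-nodes
#' are declared explicitly rather than inferred from topology, so the pair
#' classification is reproducible and auditable.
#'
#' @param tree An [ape::phylo] tree with unique tip labels and unique,
#'   non-empty internal node labels. Branch lengths are optional for the
#'   analysis (the synthetic generator requires them).
#' @param germ_layer_nodes Character vector of internal node labels (normally
#'   three) partitioning the leaves into germ layers.
#' @param super_nodes Character vector of internal node labels, each
#'   dominating at least two leaves; each super-node must lie within a single
#'   germ layer (so inner pairs always share a germ layer).
#' @return An object of class `FateMap` with elements `tree`,
#'   `germ_layer_nodes`, `super_nodes`, `leaves`, and precomputed
#'   `groups` (node label -> leaf set).
#' @export
fatemap <- function(tree, germ_layer_nodes, super_nodes) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  tips <- tree$tip.label
  internals <- tree$node.label
  if (is.null(internals) || any(!nzchar(internals)))
    stop("every internal node must carry a label")
  labels <- c(tips, internals)
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicate node label(s): ", paste(unique(dup), collapse = ", "))

  # postorder accumulation of descendant leaves per node
  ntip <- length(tips)
  groups <- c(as.list(tips), vector("list", tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    groups[[par]] <- c(groups[[par]], groups[[child]])
  }
  names(groups) <- labels

  unknown <- setdiff(c(germ_layer_nodes, super_nodes), internals)
  if (length(unknown))
    stop("designated node(s) not internal labels: ",
         paste(unknown, collapse = ", "))
  gl_cover <- unlist(groups[germ_layer_nodes], use.names = FALSE)
  if (any(duplicated(gl_cover)))
    stop("germ-layer nodes must be non-overlapping")
  if (!setequal(gl_cover, tips))
    stop("every leaf must descend from exactly one germ-layer node; uncovered: ",
         paste(setdiff(tips, gl_cover), collapse = ", "))
  small <- super_nodes[lengths(groups[super_nodes]) < 2L]
  if (length(small))
    stop("super-node(s) dominating < 2 leaves: ", paste(small, collapse = ", "))

  germ_of <- rep(NA_character_, ntip); names(germ_of) <- tips
  for (g in germ_layer_nodes) germ_of[groups[[g]]] <- g
  super_of <- rep(NA_character_, ntip); names(super_of) <- tips
  for (s in super_nodes) {
    clash <- groups[[s]][!is.na(super_of[groups[[s]]])]
    if (length(clash))
      stop("super-nodes must be non-overlapping; leaf in two: ",
           paste(clash, collapse = ", "))
    super_of[groups[[s]]] <- s
  }
  # inner implies a shared germ layer: each super-node within one germ layer
  for (s in super_nodes) {
    gl <- unique(germ_of[groups[[s]]])
    if (length(gl) != 1L)
      stop(sprintf("super-node '%s' spans germ layers (%s)",
                   s, paste(gl, collapse = ", ")))
  }

  structure(list(tree = tree,
                 leaves = tips,
                 germ_layer_nodes = germ_layer_nodes,
                 super_nodes = super_nodes,
                 groups = groups,
                 germ_of = germ_of,
                 super_of = super_of),
            class = "FateMap")
}

#' @export
print.FateMap <- function(x, ...) {
  cat(sprintf("FateMap: %d tissues, %d internal nodes (%d super-nodes, germ layers: %s)\n",
              length(x$leaves), x$tree$Nnode, length(x$super_nodes),
              paste(x$germ_layer_nodes, collapse = ", ")))
  invisible(x)
}

#' Read a fate map from Newick plus a YAML sidecar
#'
#' @param newick_path Newick file with labeled internal nodes.
#' @param meta_path YAML file with keys `germ_layer_nodes` and `super_nodes`
#'   (lists of internal node labels).
#' @return A [fatemap()] object.
#' @export
read_fatemap <- function(newick_path, meta_path) {
  tree <- ape::read.tree(newick_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$germ_layer_nodes) || is.null(meta$super_nodes))
    stop("fate-map sidecar must define 'germ_layer_nodes' and 'super_nodes'")
  fatemap(tree, as.character(meta$germ_layer_nodes),
          as.character(meta$super_nodes))
}

#' The default 24-tissue embryogenesis fate map
#'
#' The topology shipped with the package: zygote splitting into mesendoderm
#' and ectoderm, the three germ layers, developmental segments
#' (primitive gut, paraxial/intermediate/lateral-plate mesoderm, neural
#' crest/tube, brain) and 24 adult leaf tissues. Terminal sibling groups
#' (e.g. the four Brain1 tissues, testis/ovary under Gonad) are the declared
#' super-nodes. Branch lengths are nominal developmental stage counts used
#' by the synthetic generator.
#'
#' @return A [fatemap()] object.
#' @export
default_fatemap <- function() {
  read_fatemap(system.file("extdata", "fatemap_default.nwk",
                           package = "fatemapExpr", mustWork = TRUE),
               system.file("extdata", "fatemap_default.yaml",
                           package = "fatemapExpr", mustWork = TRUE))
}

#' Leaves of the subtree rooted at a node
#'
#' @param map A `FateMap`.
#' @param node A node label (leaf or internal).
#' @return Character vector of tissue ids; for a leaf, the singleton set.
#' @export
leaf_group <- function(map, node) {
  stopifnot(inherits(map, "FateMap"))
  if (!node %in% names(map$groups)) stop("unknown node label: ", node)
  map$groups[[node]]
}

#' All unordered tissue pairs under a node
#'
#' @param map A `FateMap`.
#' @param node An internal node label dominating at least two leaves.
#' @return A two-column character matrix (`t1`, `t2`) of all C(L, 2) pairs of
#'   the node's leaf set, in lexicographic order.
#' @export
node_pairs <- function(map, node) {
  leaves <- sort(leaf_group(map, node))
  if (length(leaves) < 2L)
    stop(sprintf("node '%s' dominates fewer than 2 leaves", node))
  prs <- t(utils::combn(leaves, 2L))
  colnames(prs) <- c("t1", "t2")
  prs
}

#' Classify a tissue pair as inner, mid or outer
#'
#' Inner pairs are neighbor tissues (both under a common super-node); mid
#' pairs share a germ layer but no super-node; outer pairs come from
#' different germ layers.
#'
#' @param map A `FateMap`.
#' @param t1,t2 Distinct leaf (tissue) labels.
#' @return One of `"inner"`, `"mid"`, `"outer"`.
#' @export
classify_pair <- function(map, t1, t2) {
  stopifnot(inherits(map, "FateMap"))
  for (t in c(t1, t2))
    if (!t %in% map$leaves) stop("not a leaf tissue: ", t)
  if (t1 == t2) stop("pair classification needs two distinct tissues")
  s1 <- map$super_of[[t1]]; s2 <- map$super_of[[t2]]
  if (!is.na(s1) && !is.na(s2) && s1 == s2) return("inner")
  if (map$germ_of[[t1]] == map$germ_of[[t2]]) return("mid")
  "outer"
}

#' Classify every tissue pair of a fate map
#'
#' @param map A `FateMap`.
#' @return Data frame with columns `t1`, `t2` (lexicographic) and `class`.
#' @export
pair_classes <- function(map) {
  prs <- node_pairs(map, root_label(map))
  cls <- vapply(seq_len(nrow(prs)),
                function(i) classify_pair(map, prs[i, 1], prs[i, 2]), "")
  data.frame(t1 = prs[, 1], t2 = prs[, 2], class = cls,
             stringsAsFactors = FALSE)
}

root_label <- function(map) {
  tree <- map$tree
  root <- length(tree$tip.label) + 1L
  tree$node.label[root - length(tree$tip.label)]
}

# internal node labels dominating >= min_leaves leaves
analysis_nodes <- function(map, min_leaves = 2L) {
  internals <- map$tree$node.label
  internals[vapply(internals, function(n) length(map$groups[[n]]), 0L) >= min_leaves]
}
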