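#' Read a Newick tree with validation
#'
#' Parses a Newick string (or a file containing one tree) into an [ape::phylo]
#' object and validates it for comparative analysis: unique tip labels,
#' non-negative branch lengths, branch lengths present on all non-root edges.
#' Polytomies are accepted and treated as hard multifurcations; zero-length
#' branches are retained.
#'
#' @param x A Newick string, or the path of a file holding one tree.
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()], [prune_to_taxa()]
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl(";", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  np <- nchar(gsub("[^(]", "", x)) - nchar(gsub("[^)]", "", x))
  if (np != 0L) {
    stop("unbalanced parentheses in Newick input (", np, " unmatched '(')")
  }
  tr <- ape::read.tree(text = x)
  if (is.null(tr)) stop("could not parse Newick input")
  validate_tree(tr)
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` tree.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Structural checks shared by every entry point that accepts a tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  if (any(tree$edge.length < 0)) {
    i <- which(tree$edge.length < 0)[1L]
    stop("negative branch length on edge to node ", tree$edge[i, 2L])
  }
  invisible(tree)
}

#' Test ultrametricity
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param tree A `"phylo"` tree.
#' @param tol Relative tolerance on the spread of tip depths.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d, .Machine$double.eps)
}

#' Root-to-node depths
#'
#' Distance (sum of branch lengths) from the root to every node, tips first
#' then internal nodes, in ape node numbering.
#'
#' @param tree A `"phylo"` tree.
#' @return Numeric vector of length `Ntip + Nnode`. A `root.edge` (stem
#'   retained by [prune_to_taxa()]) is included, so depths keep the
#'   original time axis.
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree) + (tree$root.edge %||% 0)
}

#' Node ages in Myr before present
#'
#' On an ultrametric tree the age of a node is its distance to the tips.
#' On non-ultrametric trees ages are measured from the deepest tip.
#'
#' @param tree A `"phylo"` tree.
#' @return Numeric vector of ages, one per node.
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `keep`: degree-2 internal nodes are
#' collapsed with their branch lengths summed, so all pairwise patristic
#' distances among retained tips are preserved. The stem path between the
#' original root and the retained taxa's MRCA is kept as the pruned tree's
#' `root.edge`, so root-to-tip depths (the time axis) are also preserved.
#'
#' @param tree A `"phylo"` tree.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `"phylo"` tree on the retained tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  stem <- node_depths(tree)[ape::getMRCA(tree, keep)]
  out <- ape::keep.tip(tree, keep)
  stem <- stem + (tree$root.edge %||% 0)
  if (stem > 0) out$root.edge <- stem
  out
}

#' Phylogenetic trait covariance matrix
#'
#' Expected trait covariance among tips under Brownian motion or a stationary
#' Ornstein-Uhlenbeck process on the tree. Under BM, entry (i, j) is
#' `sigma2` times the shared root-to-MRCA path length. Under OU on an
#' ultrametric tree of depth T with MRCA depth s,
#' entry (i, j) = sigma2/(2 alpha) * exp(-2 alpha (T - s)) * (1 - exp(-2 alpha s)).
#'
#' @param tree A rooted `"phylo"` tree (ultrametric required for OU).
#' @param model `"BM"` or `"OU"`.
#' @param sigma2 Evolutionary rate (trait units squared per Myr), > 0.
#' @param alpha OU pull strength (per Myr), > 0; required for `"OU"`.
#' @return Covariance matrix indexed by tip labels, with attributes
#'   `structure` and `params`.
#' @export
vcv_matrix <- function(tree, model = c("BM", "OU"), sigma2 = 1, alpha = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  stopifnot(sigma2 > 0)
  s <- ape::vcv(tree)            # shared depths (unit-rate BM)
  if (model == "BM") {
    V <- sigma2 * s
    params <- list(sigma2 = sigma2)
  } else {
    if (is.null(alpha) || alpha <= 0) stop("OU requires alpha > 0")
    if (!is_ultrametric(tree)) {
      stop("OU covariance is defined here only for ultrametric trees")
    }
    T_depth <- max(diag(s))
    V <- sigma2 / (2 * alpha) * exp(-2 * alpha * (T_depth - s)) *
      (1 - exp(-2 * alpha * s))
    dimnames(V) <- dimnames(s)
    params <- list(sigma2 = sigma2, alpha = alpha)
  }
  attr(V, "structure") <- model
  attr(V, "params") <- params
  V
}

#' Nodes along a line of descent
#'
#' The ordered chain of nodes from an ancestral node to a descendant tip,
#' with node ages (Myr before present, strictly decreasing tip-ward).
#'
#' @param tree A `"phylo"` tree.
#' @param from_node Internal node id (ape numbering), an ancestor of the tip.
#' @param to_tip Tip label.
#' @return Data frame with columns `node`, `label` (tip label or `""`), `age`.
#' @export
lineage_path <- function(tree, from_node, to_tip) {
  tip <- match(to_tip, tree$tip.label)
  if (is.na(tip)) stop("tip not found: ", to_tip)
  from_node <- as.integer(from_node)
  path <- root_path(tree, tip)
  pos <- match(from_node, path)
  if (is.na(pos)) {
    stop("node ", from_node, " is not an ancestor of tip '", to_tip, "'")
  }
  nodes <- path[pos:length(path)]
  ages <- node_ages(tree)[nodes]
  lab <- ifelse(nodes <= length(tree$tip.label), tree$tip.label[nodes], "")
  data.frame(node = nodes, label = lab, age = ages)
}

# Chain of nodes from the root down to `node` (inclusive), ape numbering.
root_path <- function(tree, node) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- node
  while (node != root) {
    node <- parent[node]
    path <- c(node, path)
  }
  path
}

#' Most recent common ancestor of a set of taxa
#'
#' @param tree A `"phylo"` tree.
#' @param taxa Character vector of two or more tip labels.
#' @return Internal node id (ape numbering).
#' @export
mrca_node <- function(tree, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least two taxa")
  ape::getMRCA(tree, taxa)
}
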