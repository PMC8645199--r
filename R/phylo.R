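#' Read a time-calibrated phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is the
#' backbone of every analysis in this package: contrasts, phylogenetic
#' covariances, branch epochs and the variable-rates model all derive from
#' it, so malformed input is rejected here rather than downstream.
#'
#' @param text A Newick string (must contain branch lengths).
#' @param file Alternatively, path to a Newick file; exactly one of `text`
#'   or `file` must be given.
#' @param require_ultrametric If `TRUE` (default), verify that all
#'   root-to-tip path lengths agree to a relative tolerance of 1e-6, as
#'   expected of a time tree with branch lengths in My.
#' @return An object of class `"phylo"` (ape), rooted, with branch lengths.
#' @export
read_newick <- function(text = NULL, file = NULL, require_ultrametric = TRUE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    # locate the first offending character for the error message:
    # either where the parenthesis depth first goes negative, or the first
    # character outside the Newick alphabet, or the end of the string
    chars <- strsplit(text, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    pos <- which(depth < 0)[1]
    if (is.na(pos) && depth[length(depth)] != 0) pos <- length(chars)
    if (is.na(pos)) pos <- regexpr("[^(),:;[:alnum:]_.' \t-]", text)
    if (is.na(pos) || pos < 1) pos <- nchar(text)
    stop(sprintf("Newick parse error near character %d ('%s')",
                 pos, substr(text, pos, pos)), call. = FALSE)
  }
  validate_phylogeny(tree, require_ultrametric = require_ultrametric)
  if (!is.null(tree$node.label) && any(nzchar(tree$node.label))) {
    warning("internal node labels present; they are ignored")
    tree$node.label <- NULL
  }
  tree
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if omitted the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the structural invariants of an input phylogeny
#'
#' Checks that the tree is rooted, has positive branch lengths everywhere,
#' unique tip labels, and (optionally) is ultrametric to relative tolerance
#' 1e-6.
#'
#' @param tree A `phylo` object.
#' @param require_ultrametric Enforce equal root-to-tip depths.
#' @return The tree, invisibly. Errors describe the violated invariant.
#' @export
validate_phylogeny <- function(tree, require_ultrametric = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be > 0")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  # structural rootedness: exactly one node without a parent (covers star
  # trees, which ape::is.rooted treats as unrooted)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop("tree must have exactly one root")
  if (any(table(tree$edge[, 2]) > 1)) stop("a node has more than one parent")
  if (require_ultrametric && !ape::is.ultrametric(tree, option = 2, tol = 1e-6)) {
    stop("tree is not ultrametric (root-to-tip depths differ by > 1e-6 relative)")
  }
  invisible(tree)
}

#' Node ages (My before present) of an ultrametric tree
#'
#' Tips have age 0; the root age equals the maximum root-to-tip path
#' length; a parent is always older than its children by exactly the
#' connecting branch length.
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector of ages indexed by ape node number
#'   (1..n tips, then internals), tip/node labels as names where available.
#' @export
node_ages <- function(tree) {
  validate_phylogeny(tree, require_ultrametric = TRUE)
  depth <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  ages <- max(depth) - depth
  ages[seq_len(ape::Ntip(tree))] <- 0  # exact zeros at the tips
  names(ages) <- c(tree$tip.label, rep("", tree$Nnode))
  ages
}

#' Patristic distance matrix between tips
#'
#' d(i, j) is the sum of branch lengths along the path between tips i and
#' j. On an ultrametric tree this equals twice the age of the most recent
#' common ancestor. Used as the phylogenetic control in the partial Mantel
#' test.
#'
#' @param tree A `phylo` object.
#' @return A symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree, require_ultrametric = FALSE)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic covariance matrix (shared path lengths)
#'
#' C[i, j] is the path length shared between the root and the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Under Brownian motion with rate sigma^2 the tip values are multivariate
#' normal with covariance sigma^2 * C.
#'
#' @param tree A `phylo` object.
#' @return Symmetric positive semi-definite matrix, tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree, require_ultrametric = FALSE)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Prune a phylogeny to a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels to keep (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to_tips <- function(tree, tips) {
  tips <- unique(as.character(tips))
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(tips) < 2) stop("need at least 2 tips after pruning")
  ape::keep.tip(tree, tips)
}

# Internal: edge table with parent/child ages and tip-descendant sets.
# Shared plumbing for branch epochs, clade scalars and contrast ordering.
edge_table <- function(tree) {
  ages <- node_ages(tree)
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = tree$edge.length,
    older = ages[tree$edge[, 1]],
    younger = ages[tree$edge[, 2]],
    row.names = NULL
  )
}

# Internal: for each edge, the indices of all edges in the clade it subtends
# (including the edge itself). Returned as a list indexed by edge number.
clade_edge_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_edge <- nrow(tree$edge)
  child_edges <- split(seq_len(n_edge), tree$edge[, 1])  # by parent node
  out <- vector("list", n_edge)
  # postorder over edges: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in ord) {
    ch <- tree$edge[e, 2]
    below <- if (ch <= n_tip) integer(0) else unlist(out[child_edges[[as.character(ch)]]])
    out[[e]] <- c(e, below)
  }
  out
}

# Internal: stable branch identifiers keyed by the child node:
# tip label for terminal branches, "node<k>" for internal ones.
branch_ids <- function(tree) {
  n_tip <- ape::Ntip(tree)
  ch <- tree$edge[, 2]
  ifelse(ch <= n_tip, tree$tip.label[ch], paste0("node", ch))
}
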