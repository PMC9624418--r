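#' @importFrom stats median phyper rbinom rexp rpois runif setNames
#' @importFrom utils head read.delim write.table tail
NULL

# Internal flat representation of a rooted, binary, ultrametric genealogy.
# Nodes 1..n are leaves (age 0), nodes (n+1)..(2n-1) are internal; `parent`
# holds the parent id of every node (0 for the root) and `age` the node age
# in generations.  This layout keeps coalescent simulation and per-node
# clade statistics O(n) without pointer chasing.

#' Construct a local genealogy
#'
#' A local tree is one genealogy of the haploid sample at a single genomic
#' position, with node ages measured in generations (leaves at age 0).
#'
#' @param parent integer vector over all 2n-1 nodes; `parent[v]` is the
#'   parent node id of `v`, 0 for the root.
#' @param age numeric node ages in generations; leaves must be 0.
#' @param labels character leaf labels for nodes `1..n`.
#' @param position 1-based bp coordinate of the tree on its contig.
#' @return an object of class `local_tree`.
#' @export
local_tree <- function(parent, age, labels, position = NA_real_) {
  x <- structure(
    list(parent = as.integer(parent), age = as.numeric(age),
         labels = as.character(labels), position = as.numeric(position)),
    class = "local_tree")
  validate_local_tree(x)
  x
}

new_local_tree <- function(parent, age, labels, position = NA_real_) {
  # trusted fast-path constructor (simulator); no validation
  structure(
    list(parent = as.integer(parent), age = as.numeric(age),
         labels = as.character(labels), position = as.numeric(position)),
    class = "local_tree")
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("<local_tree> %d leaves, height %.6g generations, position %s\n",
              n_leaves(x), tree_height(x),
              if (is.na(x$position)) "NA" else format(x$position)))
  invisible(x)
}

#' Number of leaves of a local tree
#' @param x a `local_tree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(x) length(x$labels)

#' Tree height (root age) in generations
#' @param x a `local_tree`.
#' @return numeric root age.
#' @export
tree_height <- function(x) x$age[tree_root(x)]

tree_root <- function(x) which(x$parent == 0L)

#' Validate a local tree
#'
#' Checks that the topology is a rooted binary tree, leaves sit at age 0,
#' and every child is strictly younger than its parent.
#'
#' @param x a `local_tree`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_local_tree <- function(x) {
  n <- n_leaves(x)
  m <- length(x$parent)
  if (m != 2L * n - 1L)
    stop("local_tree must have 2n-1 nodes for n leaves; got ", m,
         " nodes for ", n, " leaves")
  if (length(x$age) != m) stop("age vector length must match node count")
  root <- which(x$parent == 0L)
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (root <= n) stop("root cannot be a leaf")
  if (anyDuplicated(x$labels)) stop("duplicate leaf labels")
  kids <- tabulate(x$parent[x$parent > 0L], nbins = m)
  if (any(kids[seq_len(n)] > 0L)) stop("a leaf has children")
  internal <- setdiff(seq_len(m), seq_len(n))
  if (any(kids[internal] != 2L))
    stop("tree is not binary: internal node(s) with child count != 2")
  if (any(abs(x$age[seq_len(n)]) > 0))
    stop("leaf ages must be exactly 0 (ultrametric baseline)")
  ch <- which(x$parent > 0L)
  bad <- ch[x$age[ch] >= x$age[x$parent[ch]]]
  if (length(bad))
    stop("child age >= parent age at node(s) ", paste(bad, collapse = ", "))
  invisible(x)
}

# children list: children[[v]] integer vector (empty for leaves)
tree_children <- function(x) {
  m <- length(x$parent)
  ch <- vector("list", m)
  idx <- which(x$parent > 0L)
  sp <- split(idx, x$parent[idx])
  ch[as.integer(names(sp))] <- sp
  ch
}

# Sum per-leaf values up the tree: returns a vector (or matrix) over all
# nodes where entry v is the sum of `leaf_values` over leaves under v
# (a node counts itself if it is a leaf).  Correctness relies on strictly
# increasing ages along every root path.
accumulate_clades <- function(x, leaf_values) {
  n <- n_leaves(x)
  m <- length(x$parent)
  if (is.matrix(leaf_values)) {
    vals <- matrix(0, nrow = m, ncol = ncol(leaf_values))
    vals[seq_len(n), ] <- leaf_values
    for (v in order(x$age)) {
      p <- x$parent[v]
      if (p > 0L) vals[p, ] <- vals[p, ] + vals[v, ]
    }
  } else {
    vals <- numeric(m)
    vals[seq_len(n)] <- leaf_values
    for (v in order(x$age)) {
      p <- x$parent[v]
      if (p > 0L) vals[p] <- vals[p] + vals[v]
    }
  }
  vals
}

# leaves under each node
node_leaf_counts <- function(x) accumulate_clades(x, rep(1L, n_leaves(x)))

#' Serialize a local tree to a newick string
#'
#' Branch lengths are written in generations with 12 significant digits so
#' that a write/read round trip preserves node ages to near machine
#' precision.
#'
#' @param x a `local_tree`.
#' @return single newick string terminated by `;`.
#' @export
newick_string <- function(x) {
  n <- n_leaves(x)
  ch <- tree_children(x)
  fmt <- function(v) sprintf("%.12g", v)
  rec2 <- function(v, parent_age) {
    body <- if (v <= n) x$labels[v]
    else paste0("(", paste(vapply(ch[[v]], rec2, character(1),
                                  parent_age = x$age[v]), collapse = ","), ")")
    paste0(body, ":", fmt(parent_age - x$age[v]))
  }
  root <- tree_root(x)
  paste0("(", paste(vapply(ch[[root]], rec2, character(1),
                           parent_age = x$age[root]), collapse = ","), ");")
}

#' Convert a local tree to an `ape::phylo` object
#' @param x a `local_tree`.
#' @return a `phylo`.
#' @export
as_phylo <- function(x) ape::read.tree(text = newick_string(x))

#' Build a local tree from an `ape::phylo` object
#'
#' The phylogeny must be rooted and strictly binary with branch lengths in
#' generations.  Node ages are recovered from root-to-tip path lengths;
#' the tree is required to be ultrametric within `tol` relative to its
#' height (inferred ancestral recombination graphs carry time
#' discretization, hence the tolerance).
#'
#' @param phy a rooted binary `phylo` with edge lengths.
#' @param position 1-based bp coordinate.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return a `local_tree`.
#' @export
local_tree_from_phylo <- function(phy, position = NA_real_, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy))
    stop("tree has polytomies; strictly binary trees are required")
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(n)])
  dev <- max(abs(depth[seq_len(n)] - height))
  if (height <= 0) stop("tree height must be positive")
  if (dev > tol * height)
    stop(sprintf(
      "tree is not ultrametric: max root-to-leaf deviation %.6g exceeds %.3g of height %.6g",
      dev, tol, height))
  m <- n + phy$Nnode
  parent <- integer(m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  age <- height - depth
  age[seq_len(n)] <- 0
  x <- new_local_tree(parent, age, phy$tip.label, position)
  validate_local_tree(x)
  x
}
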