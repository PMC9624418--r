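# Genealogical feature encoding at a focal site: counts of derived and
# ancestral lineages crossing a set of discretized ages, the input
# representation used by genealogy-based selection-inference models.

#' Approximately log-uniform time grid
#'
#' `n_points` ages spaced log-uniformly in `[t_min, t_max]`, prepended
#' with age 0, so recent time scales are discretized more finely.
#'
#' @param t_min youngest positive grid age (generations), default 1.
#' @param t_max oldest grid age; a natural default is 4x the (scaled)
#'   source population size.
#' @param n_points number of positive grid ages (>= 2).
#' @return strictly increasing numeric vector of length `n_points + 1`
#'   starting at 0.
#' @export
make_time_grid <- function(t_min = 1, t_max, n_points = 100) {
  if (t_min <= 0 || t_max <= t_min) stop("need 0 < t_min < t_max")
  if (n_points < 2) stop("n_points must be >= 2")
  c(0, 10^seq(log10(t_min), log10(t_max), length.out = n_points))
}

#' Lineage counts through time, split by allelic state
#'
#' For every grid age t, counts the lineages of the genealogy crossing t
#' (edges with child age <= t < parent age; the root lineage extends
#' beyond the root), split into derived lineages (those ancestral only to
#' the derived leaves; the mutation-carrying branch itself counts as
#' derived up to its parent node) and ancestral lineages (all others).
#'
#' @param tree a `local_tree`.
#' @param derived_leaves non-empty proper subset of the tree's leaves,
#'   required to form a clade (single mutational origin).
#' @param time_grid ages from [make_time_grid].
#' @return a `feature_matrix`: list with `time_grid`, `counts` (length(grid)
#'   x 2 integer matrix, columns `derived`, `ancestral`) and `daf`.
#' @export
lineage_counts <- function(tree, derived_leaves, time_grid) {
  mrca <- carrier_clade_node(tree, derived_leaves)  # errors if not a clade
  n <- n_leaves(tree)
  m <- length(tree$parent)
  ch <- which(tree$parent > 0L)
  lo <- tree$age[ch]
  hi <- tree$age[tree$parent[ch]]
  # derived edges: all edges inside the carrier clade plus the mutation
  # branch above its MRCA
  hit <- tree$labels %in% derived_leaves
  d <- accumulate_clades(tree, as.integer(hit))
  nn <- node_leaf_counts(tree)
  in_clade <- d == nn & d > 0 & nn <= sum(hit)   # MRCA and its descendants
  derived_edge <- in_clade[ch]
  root <- tree_root(tree)
  counts <- matrix(0L, nrow = length(time_grid), ncol = 2,
                   dimnames = list(NULL, c("derived", "ancestral")))
  for (i in seq_along(time_grid)) {
    t <- time_grid[i]
    cross <- lo <= t & t < hi
    counts[i, 1] <- sum(cross & derived_edge)
    counts[i, 2] <- sum(cross & !derived_edge) + (t >= tree$age[root])
  }
  structure(list(time_grid = time_grid, counts = counts,
                 daf = sum(hit) / n),
            class = "feature_matrix")
}

#' Write a feature matrix with its JSON sidecar
#'
#' The matrix is written tab-separated (age, derived, ancestral); the
#' sidecar records the grid parameters and derived allele frequency so
#' feature files are self-describing.
#'
#' @param fm a `feature_matrix`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return invisibly, the two paths.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(age = fm$time_grid, derived = fm$counts[, 1],
                   ancestral = fm$counts[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(n_grid = length(fm$time_grid), daf = fm$daf,
                            t_max = max(fm$time_grid)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(list(features = path, sidecar = side))
}
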