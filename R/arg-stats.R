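# Selection-scan statistics computed on local genealogies: hypergeometric
# species enrichment scores, RTH' (relative TMRCA-half), mutation midpoint
# ages, and their 20-kb windowed averages.

#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing at least `k` population-labelled leaves in a
#' subtree of `n` leaves, when `K` of the `N` sampled leaves carry the
#' label and subtree membership is exchangeable: P(X >= k) for
#' X ~ Hypergeometric(N, K, n).  Evaluated in log space via [stats::phyper].
#'
#' @param N total number of leaves in the sample.
#' @param K leaves carrying the population label.
#' @param n leaves in the subtree.
#' @param k labelled leaves in the subtree.
#' @return P(X >= k), a probability in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(k < 0 | n < k | N < n | K < 0 | N < K))
    stop("hypergeometric domain violated: need 0 <= k <= n <= N and 0 <= K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# -log10 upper-tail probabilities, vectorized over (n, k)
log10_hyper_score <- function(N, K, n, k) {
  -phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# per-node (total leaves, per-population leaves) for one tree
subtree_compositions <- function(tree, map) {
  pops <- attr(map, "populations")
  leaf_pop <- map$population[match(tree$labels, map$leaf_label)]
  if (anyNA(leaf_pop))
    stop("tree leaves absent from sample map: ",
         paste(tree$labels[is.na(leaf_pop)], collapse = ", "))
  ind <- matrix(0L, nrow = n_leaves(tree), ncol = length(pops),
                dimnames = list(NULL, pops))
  ind[cbind(seq_len(n_leaves(tree)), match(leaf_pop, pops))] <- 1L
  k <- accumulate_clades(tree, ind)
  colnames(k) <- pops
  list(n = node_leaf_counts(tree), k = k)
}

#' Species enrichment score of a local tree
#'
#' For every subtree (internal nodes and single leaves alike) the score is
#' the -log10 upper-tail hypergeometric probability of its count of
#' population-labelled leaves; the tree's enrichment score for the
#' population is the maximum over all subtrees.  High scores indicate
#' population-exclusive clades larger than exchangeable sampling would
#' produce.  The statistic depends only on topology, not branch lengths.
#'
#' @param tree a `local_tree`.
#' @param map a `sample_map` covering the tree's leaves.
#' @param pop population name.
#' @return non-negative enrichment score.
#' @export
species_enrichment <- function(tree, map, pop) {
  pops <- attr(map, "populations")
  if (!pop %in% pops) stop("population not in sample map: ", pop)
  comp <- subtree_compositions(tree, map)
  K <- attr(map, "K")[[pop]]
  N <- attr(map, "N")
  max(log10_hyper_score(N, K, comp$n, comp$k[, pop]))
}

#' Age of the youngest subtree covering a fraction of a leaf set
#'
#' Returns the minimum node age among nodes (leaves included) whose
#' subtree contains at least `ceiling(fraction * |leaf_subset|)` members
#' of `leaf_subset`; with the default fraction this is the TMRCA-half
#' (TMRCAH) of the subset.
#'
#' @param tree a `local_tree`.
#' @param leaf_subset character vector of leaf labels.
#' @param fraction required fraction of the subset (default 0.5,
#'   "at least half" via ceiling).
#' @return node age in generations.
#' @export
tmrca_half <- function(tree, leaf_subset, fraction = 0.5) {
  hit <- tree$labels %in% leaf_subset
  if (!any(hit)) stop("leaf_subset is disjoint from the tree's leaves")
  need <- ceiling(fraction * sum(hit))
  cnt <- accumulate_clades(tree, as.integer(hit))
  min(tree$age[cnt >= need])
}

#' RTH': relative TMRCA-half of a population
#'
#' TMRCAH of the population's leaves divided by the age of the youngest
#' subtree containing at least half of all sampled leaves.  The
#' normalization makes the statistic insensitive to genome-wide variation
#' in coalescent depth; values well below 1 flag unusually recent
#' population-specific common ancestry, the footprint of a sweep.
#'
#' @param tree a `local_tree`.
#' @param map a `sample_map`.
#' @param pop population name (needs at least 2 sampled leaves).
#' @return ratio of two node ages of the tree.
#' @export
rth_prime <- function(tree, map, pop) {
  pops <- attr(map, "populations")
  if (!pop %in% pops) stop("population not in sample map: ", pop)
  if (attr(map, "K")[[pop]] < 2L)
    stop("RTH' needs at least 2 haploid leaves for population ", pop)
  num <- tmrca_half(tree, map$leaf_label[map$population == pop])
  den <- tmrca_half(tree, map$leaf_label)
  if (den <= 0)
    stop("global TMRCA-half is zero (sample too small to define RTH')")
  num / den
}

#' Midpoint age of the branch carrying a mutation
#'
#' Locates the edge whose subtree's leaf set equals the carrier
#' (derived-allele) leaves and dates the mutation at the midpoint of that
#' branch.  If the carriers are not a clade (homoplasy or recombination
#' between the site and the tree), an error is raised unless
#' `allow_superset = TRUE`, in which case the smallest clade containing
#' all carriers is used instead.
#'
#' @param tree a `local_tree`.
#' @param derived_leaves non-empty proper subset of the tree's leaf labels.
#' @param allow_superset fall back to the smallest superset clade.
#' @return age in generations: (child age + parent age) / 2 of the edge.
#' @export
mutation_midpoint_age <- function(tree, derived_leaves, allow_superset = FALSE) {
  node <- carrier_clade_node(tree, derived_leaves, allow_superset)
  p <- tree$parent[node]
  if (p == 0L)
    stop("carrier clade is the whole tree's root; no branch to date")
  (tree$age[node] + tree$age[p]) / 2
}

# node whose subtree equals (or minimally contains) the derived leaf set
carrier_clade_node <- function(tree, derived_leaves, allow_superset = FALSE) {
  hit <- tree$labels %in% derived_leaves
  nd <- sum(hit)
  if (nd == 0L) stop("derived_leaves not found in tree")
  if (nd == n_leaves(tree))
    stop("derived_leaves must be a proper subset of the leaves")
  d <- accumulate_clades(tree, as.integer(hit))
  n <- node_leaf_counts(tree)
  exact <- which(d == nd & n == nd)
  if (length(exact)) return(exact[which.min(n[exact])])
  if (!allow_superset)
    stop("derived leaves are not a clade of the tree (set allow_superset = TRUE to use the smallest containing clade)")
  sup <- which(d == nd)
  sup[which.min(n[sup])]
}

#' Windowed averages of a per-tree statistic
#'
#' Tiles the contig into non-overlapping windows from coordinate 1 and
#' averages the per-tree statistic over the trees whose position falls in
#' each window (0-based half-open window coordinates).  Windows containing
#' no trees are omitted.
#'
#' @param series a `tree_series` (edge-discarded for scan use).
#' @param map a `sample_map`.
#' @param statistic `"enrichment"` or `"rth_prime"`.
#' @param window_bp window size in bp (default 20000; with 500-bp tree
#'   sampling a full window averages 40 trees).
#' @param populations populations to evaluate (default: all in the map).
#' @return data frame with columns contig, start, end, population,
#'   statistic, value, n_trees.
#' @export
window_average <- function(series, map, statistic = c("enrichment", "rth_prime"),
                           window_bp = 20000, populations = NULL) {
  statistic <- match.arg(statistic)
  if (window_bp <= 0) stop("window_bp must be positive")
  if (is.null(populations)) populations <- attr(map, "populations")
  fun <- switch(statistic, enrichment = species_enrichment,
                rth_prime = rth_prime)
  out <- vector("list", length(populations))
  if (length(series$trees) == 0L)
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), population = character(),
                      statistic = character(), value = numeric(),
                      n_trees = integer()))
  win <- floor((series$positions - 1) / window_bp)
  for (j in seq_along(populations)) {
    pop <- populations[j]
    vals <- vapply(series$trees, fun, numeric(1), map = map, pop = pop)
    agg_mean <- tapply(vals, win, mean)
    agg_n <- tapply(vals, win, length)
    w <- as.numeric(names(agg_mean))
    out[[j]] <- data.frame(contig = series$contig,
                           start = w * window_bp,
                           end = (w + 1) * window_bp,
                           population = pop,
                           statistic = statistic,
                           value = as.numeric(agg_mean),
                           n_trees = as.integer(agg_n))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
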