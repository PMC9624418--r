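# Enrichment, RTH', TMRCA-half, mutation dating and windowed averages.

test_that("hypergeometric tail matches exhaustive subset enumeration", {
  # frozen spec examples, expected values from the enumeration oracle
  expect_equal(hypergeometric_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeometric_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  # full sweep over small sample sizes
  for (N in c(5, 8, 12)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:n) {
          expect_equal(hypergeometric_tail(N, K, n, k),
                       enumerate_hyper_tail(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  expect_error(hypergeometric_tail(4, 2, 5, 1), "domain")
})

test_that("tail probability is non-increasing in k (score monotone)", {
  for (N in c(6, 10, 12)) {
    K <- floor(N / 2)
    for (n in 1:N) {
      p <- hypergeometric_tail(rep(N, n + 1), K, n, 0:n)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("species enrichment maximizes -log10 tail over all subtrees", {
  map <- toy_map4()
  tr <- balanced_tree4()
  expect_equal(species_enrichment(tr, map, "P"), -log10(1 / 6),
               tolerance = 1e-12)
  # topology-only: doubling branch lengths changes nothing
  expect_equal(species_enrichment(balanced_tree4(scale = 2), map, "P"),
               species_enrichment(tr, map, "P"))
  # saturated case: every subtree has tail probability 1
  map1 <- sample_map(data.frame(leaf_label = c("a1", "a2", "b1", "b2"),
                                individual_id = c("A", "A", "B", "B"),
                                population = rep("P", 4)))
  expect_equal(species_enrichment(tr, map1, "P"), 0)
  expect_error(species_enrichment(tr, map, "Z"), "not in sample map")
})

test_that("TMRCA-half finds the youngest subtree covering half the subset", {
  tr <- eight_leaf_tree()
  # subset {p1..p4}: p1,p2 coalesce at 0.2, the youngest node with >= 2
  expect_equal(tmrca_half(tr, c("p1", "p2", "p3", "p4")), 0.2)
  # singleton subsets are covered by a leaf at age 0
  expect_equal(tmrca_half(tr, "q3"), 0)
  # near-star tree: only internal nodes cover >= half
  star <- near_star_tree(letters[1:6])
  expect_equal(tmrca_half(star, letters[1:6]), 1, tolerance = 1e-6)
  expect_error(tmrca_half(tr, c("zz")), "disjoint")
})

test_that("RTH' is the ratio of population to global TMRCA-half ages", {
  tr <- eight_leaf_tree()
  map <- eight_leaf_map()
  # numerator 0.2 (pair p1,p2); denominator 1.0 (youngest 4-leaf subtree)
  expect_equal(rth_prime(tr, map, "P"), 0.2, tolerance = 1e-12)
  # invariant under global rescaling of ages
  tr10 <- tr
  tr10$age <- tr$age * 10
  expect_equal(rth_prime(tr10, map, "P"), rth_prime(tr, map, "P"),
               tolerance = 1e-12)
  # near-star tree: every population coalesces at the same depth
  star <- near_star_tree(c("p1", "p2", "p3", "p4", "q1", "q2", "q3", "q4"))
  expect_equal(rth_prime(star, map, "P"), 1, tolerance = 1e-5)
  expect_equal(rth_prime(star, map, "Q"), 1, tolerance = 1e-5)
})

test_that("enrichment and RTH' are invariant to population-preserving relabeling", {
  model <- demographic_preset("sasc")
  set.seed(42)
  for (rep in 1:5) {
    g <- simulate_genealogy(model, sweep_config("neutral"), 6, 6)
    tr <- g$tree
    # permute leaf labels within populations
    map <- g$map
    perm <- unlist(lapply(attr(map, "populations"), function(p) {
      l <- map$leaf_label[map$population == p]
      setNames(sample(l), l)
    }))
    tr2 <- tr
    tr2$labels <- unname(perm[tr$labels])
    for (pop in c("satellite", "source")) {
      expect_equal(species_enrichment(tr2, map, pop),
                   species_enrichment(tr, map, pop), tolerance = 1e-12)
      expect_equal(rth_prime(tr2, map, pop), rth_prime(tr, map, pop),
                   tolerance = 1e-12)
    }
    expect_gt(rth_prime(tr, map, "satellite"), 0)
  }
})

test_that("mutation midpoint dating locates the carrier clade's branch", {
  tr <- eight_leaf_tree()
  # clade (p1,p2): node age 0.2, parent age 1.0 -> midpoint 0.6
  expect_equal(mutation_midpoint_age(tr, c("p1", "p2")), 0.6)
  # single leaf: pendant edge 0 -> 0.2 for p1
  expect_equal(mutation_midpoint_age(tr, "p1"), 0.1)
  # non-clade carriers
  tr4 <- balanced_tree4()
  expect_equal(mutation_midpoint_age(tr4, "b1"), 1)  # pendant to age 2
  expect_error(mutation_midpoint_age(tr4, c("a1", "b1")), "not a clade")
  # fallback: smallest superset clade of {a1,b1} is the root -> no branch
  expect_error(mutation_midpoint_age(tr4, c("a1", "b1"),
                                     allow_superset = TRUE), "root")
  expect_equal(mutation_midpoint_age(tr, c("p1", "p2", "p3"),
                                     allow_superset = TRUE),
               (1.0 + 3.0) / 2)  # smallest superset: 4-leaf node at 1.0
})

test_that("window averages tile from the origin and count trees", {
  map <- toy_map4()
  shape <- balanced_tree4()
  positions <- seq(500, 60000, by = 500)
  trees <- lapply(positions, function(p) { t <- shape; t$position <- p; t })
  series <- tree_series("ctg", 60000, trees)
  w <- window_average(series, map, "enrichment", window_bp = 20000,
                      populations = "P")
  expect_equal(nrow(w), 3)
  expect_equal(w$n_trees, rep(40L, 3))       # 500-bp sampling, 20-kb windows
  expect_equal(w$start, c(0, 20000, 40000))
  expect_equal(w$end - w$start, rep(20000, 3))
  # constant per-tree statistic: every window equals it
  expect_equal(w$value, rep(species_enrichment(shape, map, "P"), 3))
  # window = sampling interval reproduces per-tree values
  w1 <- window_average(series, map, "rth_prime", window_bp = 500,
                       populations = "P")
  expect_equal(nrow(w1), length(positions))
  expect_equal(w1$n_trees, rep(1L, length(positions)))
  # empty series gives an empty frame
  empty <- tree_series("ctg", 1000, list())
  expect_equal(nrow(window_average(empty, map, "enrichment")), 0)
})

test_that("windows average heterogeneous per-tree values arithmetically", {
  map <- eight_leaf_map()
  a <- eight_leaf_tree()
  b <- near_star_tree(c("p1", "p2", "p3", "p4", "q1", "q2", "q3", "q4"))
  positions <- seq(500, 20000, by = 500)
  trees <- lapply(seq_along(positions), function(i) {
    t <- if (i %% 2 == 1) a else b
    t$position <- positions[i]
    t
  })
  series <- tree_series("ctg", 20000, trees)
  w <- window_average(series, map, "rth_prime", window_bp = 20000,
                      populations = "P")
  va <- rth_prime(a, map, "P")
  vb <- rth_prime(b, map, "P")
  expect_equal(w$value, (va + vb) / 2, tolerance = 1e-9)
})
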