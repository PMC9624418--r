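# Simulator: parameter sampling, trajectories, structured coalescent,
# SMC tree walk, mutations and unit conversions.

test_that("sweep parameter draws are deterministic and honor the mixture", {
  model <- demographic_preset("sasc")
  a <- sample_sweep_params(model, seed = 7)
  b <- sample_sweep_params(model, seed = 7)
  expect_identical(a, b)
  set.seed(3)
  draws <- replicate(5000, sample_sweep_params(model)$s)
  expect_true(all(draws >= 0.001 & draws <= 0.025))
  # mixture CDF at the geometric midpoint sqrt(0.001 * 0.025):
  # 0.5 * uniform CDF + 0.5 * 0.5 (log-uniform median)
  mid <- sqrt(0.001 * 0.025)
  expected <- 0.5 * (mid - 0.001) / 0.024 + 0.25
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(mean(draws < mid) - expected), 4 * se)
  # onset clamped to the trained regime
  set.seed(4)
  onsets <- replicate(200, sample_sweep_params(model)$onset)
  expect_true(all(onsets >= 250 & onsets <= 20000))
})

test_that("deterministic trajectory matches the per-generation recursion", {
  N <- 1000
  s <- 0.1
  f0 <- 0.01
  traj <- deterministic_trajectory(s, f0, N)
  # independent oracle: literal per-generation recursion
  p <- f0
  gens <- 0
  while (p < 1 - 1 / (4 * N)) {
    p <- p * (1 + s) / (1 + s * p)
    gens <- gens + 1
  }
  expect_equal(traj$fixation_gen, gens)
  expect_equal(traj$freqs[1], f0)
  expect_equal(traj$freqs[10], {
    q <- f0; for (i in 1:9) q <- q * (1 + s) / (1 + s * q); q
  }, tolerance = 1e-12)
  expect_true(all(diff(traj$freqs) >= 0))
  # strong selection fixes within a few generations
  expect_lt(deterministic_trajectory(2, 0.1, 1000)$fixation_gen, 15)
  # degenerate inputs are rejected
  expect_error(deterministic_trajectory(0, 0.5, 1000), "positive")
  expect_error(deterministic_trajectory(0.1, 1, 1000), "f_init")
})

test_that("emitted genealogies are valid and seeds determine output", {
  model <- demographic_preset("sasc")
  cfg <- sweep_config("hard", s = 0.025, onset = 400)
  g1 <- simulate_genealogy(model, cfg, 8, 8, seed = 13)
  g2 <- simulate_genealogy(model, cfg, 8, 8, seed = 13)
  expect_identical(newick_string(g1$tree), newick_string(g2$tree))
  expect_silent(validate_local_tree(g1$tree))
  expect_true(all(g1$derived_leaves %in%
                    g1$map$leaf_label[g1$map$population == "satellite"]))
  expect_gte(g1$daf, cfg$retain_daf_min)
  r1 <- simulate_region(model, sweep_config("neutral", region_bp = 20000),
                        6, 6, seed = 17)
  r2 <- simulate_region(model, sweep_config("neutral", region_bp = 20000),
                        6, 6, seed = 17)
  expect_identical(vapply(r1$series$trees, newick_string, character(1)),
                   vapply(r2$series$trees, newick_string, character(1)))
  expect_identical(r1$haplotypes$positions, r2$haplotypes$positions)
  for (t in r1$series$trees) expect_silent(validate_local_tree(t))
})

test_that("region layout: tree spacing, sweep site at center, mutations", {
  model <- demographic_preset("sasc")
  cfg <- sweep_config("hard", s = 0.025, onset = 300, region_bp = 100000)
  sim <- simulate_region(model, cfg, 6, 6, seed = 23)
  expect_length(sim$series, 200)               # 100 kb / 500 bp
  expect_equal(sim$labels$sweep_pos, 50000)    # sweep site at the center
  expect_equal(diff(sim$series$positions), rep(500, 199))
  # derived leaves form a clade of the sweep-site tree
  ci <- which(sim$series$positions == 50000)
  expect_silent(mutation_midpoint_age(sim$series$trees[[ci]],
                                      sim$derived_leaves))
  # mu = 0 gives zero segregating sites
  m0 <- demographic_preset("sasc", mu = 0)
  s0 <- simulate_region(m0, sweep_config("neutral", region_bp = 10000),
                        4, 4, seed = 29)
  expect_equal(ncol(s0$haplotypes$hap), 0)
})

test_that("neutral coalescent matches analytic expectations (light check)", {
  model <- one_pop_model(N = 500)
  set.seed(37)
  tm <- replicate(400, tree_height(
    simulate_genealogy(model, sweep_config("neutral"), 0, 2)$tree))
  # E[TMRCA] = 2N for a pair
  expect_lt(abs(mean(tm) - 1000), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("soft sweeps retain more derived lineage backgrounds than hard", {
  model <- demographic_preset("sasc")
  set.seed(41)
  count_backgrounds <- function(mode) {
    cfg <- if (mode == "hard") sweep_config("hard", s = 0.02, onset = 1000)
    else sweep_config("soft", s = 0.02, onset = 1000, f_init = 0.08)
    replicate(150, {
      g <- simulate_genealogy(model, cfg, 10, 10)
      fm <- lineage_counts(g$tree, g$derived_leaves,
                           time_grid = c(0, cfg$onset))
      fm$counts[2, "derived"]
    })
  }
  soft <- count_backgrounds("soft")
  hard <- count_backgrounds("hard")
  expect_gt(mean(soft >= 2), mean(hard >= 2))
})

test_that("migrants per generation converts mutation-scaled rates", {
  expect_equal(migrants_per_generation(0, 0.004), 0)
  expect_equal(migrants_per_generation(1.0, 0.004), 0.001)
  expect_equal(migrants_per_generation(0.5, 0.01), 0.00125)
  expect_error(migrants_per_generation(-1, 0.004), "non-negative")
})

test_that("model scaling preserves theta and migrants per generation", {
  m <- demographic_preset("sasc")
  sm <- argscan:::scaled_model(m)
  expect_equal(4 * sm$N_satellite * sm$mu, 4 * m$N_satellite * m$mu)
  expect_equal(2 * sm$N_satellite * sm$m, 2 * m$N_satellite * m$m)
  expect_equal(sm$T_split, m$T_split / m$scale)
})
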