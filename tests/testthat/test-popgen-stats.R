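# Site filtering, diversity, Tajima's D, FST and H statistics.

# small genotype fixture builder: dosages as a sites x individuals matrix
gm_fixture <- function(dosages, depths = NULL, pos = NULL) {
  S <- nrow(dosages)
  if (is.null(depths)) depths <- rep(30, S)
  if (is.null(pos)) pos <- seq_len(S) * 100
  genotype_matrix(
    data.frame(contig = "c1", pos = pos, ref = "A", alt = "T",
               mean_depth = depths),
    dosages)
}

test_that("site filters apply presence, depth and MAC rules", {
  # 10 diploids; hand-designed sites with known (presence, depth, MAC)
  n <- 10
  rows <- rbind(
    pass_common  = c(rep(1, 8), 0, 0),            # called 10/10, MAC 8
    fail_mac7    = c(rep(1, 7), 0, 0, 0),         # MAC 7 -> removed
    fail_presence = c(rep(1, 7), NA, NA, NA),     # called 7/10 -> removed
    fail_depth   = c(rep(1, 8), 0, 0),            # depth 55 -> removed
    pass_hom     = c(rep(2, 4), rep(0, 6)),       # 4 homozygotes, MAC 8
    pass_boundary = c(rep(1, 8), NA, NA))         # called 8/10 = 80%, MAC 8
  colnames(rows) <- paste0("ind", 1:n)
  gm <- gm_fixture(rows, depths = c(30, 30, 30, 55, 2, 50))
  out <- filter_sites(gm)
  expect_equal(nrow(out$sites), 3)
  expect_equal(out$sites$pos, c(100, 500, 600))
  # order invariance: permuting sites and individuals keeps the same survivors
  perm_s <- c(4, 2, 6, 1, 3, 5)
  perm_i <- sample(n)
  gm2 <- gm_fixture(rows[perm_s, perm_i],
                    depths = c(30, 30, 30, 55, 2, 50)[perm_s],
                    pos = sort(c(100, 200, 300, 400, 500, 600)))
  out2 <- filter_sites(gm2)
  expect_equal(nrow(out2$sites), 3)
})

test_that("nucleotide diversity matches hand-computed pairwise differences", {
  # one diploid (2 haplotypes) heterozygous at one site: pi = 1/5000
  gm <- gm_fixture(matrix(1, 1, 1, dimnames = list(NULL, "i1")))
  w <- nucleotide_diversity(gm, window_bp = 5000)
  expect_equal(w$pi_per_site, 2e-4)
  # monomorphic window
  gm0 <- gm_fixture(matrix(0, 2, 3))
  expect_equal(nucleotide_diversity(gm0, window_bp = 5000)$pi_per_site, 0)
  # 4 haplotypes (2 diploids), derived counts {1,1,2}, 1000-bp window:
  # mean pairwise differences (0.5 + 0.5 + 2/3) / 1000
  d <- rbind(c(1, 0), c(0, 1), c(2, 0))
  colnames(d) <- c("i1", "i2")
  w3 <- nucleotide_diversity(gm_fixture(d), window_bp = 1000)
  expect_equal(w3$pi_per_site, (0.5 + 0.5 + 2 / 3) / 1000,
               tolerance = 1e-12)
  expect_equal(w3$n_snps, 3L)
})

# independent implementation of the 1989 statistic (direct transcription
# of the constants), used as the oracle
tajima_oracle <- function(n, derived_counts) {
  S <- sum(derived_counts > 0 & derived_counts < n)
  if (S == 0) return(NA_real_)
  p <- derived_counts / n
  pi <- sum(2 * p * (1 - p) * n / (n - 1))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# derived-count vector -> diploid dosage matrix (haplotypes paired in order)
counts_to_gm <- function(counts, n_hap, pos = NULL) {
  hap <- vapply(counts, function(k) sample(c(rep(1, k), rep(0, n_hap - k))),
                numeric(n_hap))
  dose <- hap[seq(1, n_hap, 2), , drop = FALSE] +
    hap[seq(2, n_hap, 2), , drop = FALSE]
  dose <- t(dose)
  colnames(dose) <- paste0("i", seq_len(ncol(dose)))
  gm_fixture(dose, pos = pos)
}

test_that("Tajima's D agrees with an independent oracle", {
  set.seed(11)
  # spec example: n = 4 haplotypes, derived counts {1,1,2}
  gm <- counts_to_gm(c(1, 1, 2), 4)
  d <- tajimas_d(gm, window_bp = 5000)$tajimas_d
  expect_lt(abs(d - 0.168), 1e-3)
  expect_equal(d, tajima_oracle(4, c(1, 1, 2)), tolerance = 1e-9)
  # S = 0 is undefined, never 0
  gm0 <- gm_fixture(matrix(0, 2, 3))
  expect_true(is.na(tajimas_d(gm0, window_bp = 5000)$tajimas_d))
  # an excess of singletons drives D negative
  gmneg <- counts_to_gm(rep(1, 20), 10)
  expect_lt(tajimas_d(gmneg, window_bp = 5000)$tajimas_d, 0)
  # 100 random fixtures against the oracle at 1e-9
  for (i in 1:100) {
    n_hap <- 2 * sample(2:12, 1)
    S <- sample(1:25, 1)
    counts <- sample(seq_len(n_hap - 1), S, replace = TRUE)
    gm <- counts_to_gm(counts, n_hap)
    expect_equal(tajimas_d(gm, window_bp = 5000)$tajimas_d,
                 tajima_oracle(n_hap, counts), tolerance = 1e-9,
                 label = sprintf("fixture %d (n=%d, S=%d)", i, n_hap, S))
  }
})

test_that("Weir-Cockerham FST handles fixed differences, identity and pooling", {
  pops <- data.frame(individual_id = paste0("i", 1:20),
                     population = rep(c("A", "B"), each = 10))
  # fixed difference, 10 diploids each -> 1.0
  d <- matrix(c(rep(2, 10), rep(0, 10)), nrow = 1)
  colnames(d) <- paste0("i", 1:20)
  f <- weir_cockerham_fst(gm_fixture(d), pops, "A", "B", window_bp = 5000)
  expect_equal(f$fst, 1)
  # unequal sample sizes still give 1 for a fixed difference
  pops2 <- data.frame(individual_id = paste0("i", 1:16),
                      population = rep(c("A", "B"), c(4, 12)))
  d2 <- matrix(c(rep(2, 4), rep(0, 12)), nrow = 1)
  colnames(d2) <- paste0("i", 1:16)
  expect_equal(weir_cockerham_fst(gm_fixture(d2), pops2, "A", "B",
                                  window_bp = 5000)$fst, 1)
  # identical frequency and genotype make-up in both pops -> <= 0
  di <- matrix(rep(c(rep(1, 4), rep(0, 6)), 2), nrow = 1)
  colnames(di) <- paste0("i", 1:20)
  expect_lte(weir_cockerham_fst(gm_fixture(di), pops, "A", "B",
                                window_bp = 5000)$fst, 0)
  # a monomorphic site contributes nothing to the ratio of sums
  dp <- rbind(c(rep(2, 10), rep(0, 10)), rep(0, 20))
  colnames(dp) <- paste0("i", 1:20)
  expect_equal(weir_cockerham_fst(gm_fixture(dp), pops, "A", "B",
                                  window_bp = 5000)$fst, 1)
  # symmetry in the two populations on a random fixture
  set.seed(5)
  dr <- matrix(sample(0:2, 5 * 20, replace = TRUE), nrow = 5)
  colnames(dr) <- paste0("i", 1:20)
  expect_equal(weir_cockerham_fst(gm_fixture(dr), pops, "A", "B",
                                  window_bp = 5000)$fst,
               weir_cockerham_fst(gm_fixture(dr), pops, "B", "A",
                                  window_bp = 5000)$fst, tolerance = 1e-12)
  # window with no usable sites is undefined
  dna <- matrix(NA_integer_, 1, 20)
  colnames(dna) <- paste0("i", 1:20)
  expect_true(is.na(weir_cockerham_fst(gm_fixture(dna), pops, "A", "B",
                                       window_bp = 5000)$fst))
})

test_that("H statistics merge haplotype classes and satisfy identities", {
  # all identical
  hm <- haplotype_matrix(matrix(0L, 6, 4), 1:4)
  h <- h_statistics(hm, window_snps = 4)
  expect_equal(unlist(h[, c("H1", "H2", "H12", "H2_over_H1")]),
               c(H1 = 1, H2 = 0, H12 = 1, H2_over_H1 = 0))
  # 4 equal classes at pairwise distance >= 2
  m4 <- rbind(c(0, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 1, 1))
  h4 <- h_statistics(haplotype_matrix(m4, 1:4), window_snps = 4)
  expect_equal(h4$H1, 0.25)
  expect_equal(h4$H12, 0.375)
  # merge rule: 3 copies of h, 1 at distance 1, 1 at distance 3
  m5 <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0),
              c(1, 0, 0, 0), c(1, 1, 1, 0))
  h5 <- h_statistics(haplotype_matrix(m5, 1:4), window_snps = 4)
  expect_equal(h5$H1, 0.68)
  expect_equal(h5$H2, 0.04, tolerance = 1e-12)
  expect_equal(h5$H12, 1)
  expect_equal(h5$n_classes, 2L)
  # missing alleles are an error
  mna <- m5; mna[1, 1] <- NA
  expect_error(h_statistics(haplotype_matrix(mna, 1:4), window_snps = 4),
               "missing")
  # trailing partial window dropped
  expect_equal(nrow(h_statistics(haplotype_matrix(m5, 1:4),
                                 window_snps = 3)), 1)
})

test_that("H identities hold exactly on random windows", {
  set.seed(9)
  for (i in 1:25) {
    H <- sample(4:16, 1)
    W <- 10
    block <- matrix(sample(0:1, H * W, replace = TRUE, prob = c(0.7, 0.3)),
                    nrow = H)
    p <- hap_class_freqs(block, distance_threshold = 1)
    h <- h_statistics(haplotype_matrix(block, 1:W), window_snps = W)
    p1 <- p[1]; p2 <- if (length(p) > 1) p[2] else 0
    expect_equal(h$H1, sum(p^2))
    expect_equal(h$H2, h$H1 - p1^2)
    expect_equal(h$H12 - h$H1, 2 * p1 * p2, tolerance = 1e-12)
    expect_true(h$H2 <= h$H1 && h$H1 <= h$H12 && h$H12 <= 1)
    expect_true(h$H2_over_H1 >= 0 && h$H2_over_H1 <= 1)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("neutral simulations match Watterson/pairwise expectations", {
  # single-population neutral model: E[pi] = theta*L, E[S] = theta*L*a1
  N <- 500
  model <- demographic_model(N_source = N, N_satellite = N, T_split = 5000,
                             m = 0, mu = 2e-6, r = 1e-9, scale = 1)
  L <- 2000
  n_hap <- 10
  set.seed(101)
  reps <- 500
  S <- numeric(reps)
  pi_sum <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_region(model, sweep_config("neutral", region_bp = L),
                           0, n_hap, interval = L)
    hap <- sim$haplotypes$hap
    S[i] <- ncol(hap)
    if (ncol(hap)) {
      k <- colSums(hap)
      p <- k / n_hap
      pi_sum[i] <- sum(2 * p * (1 - p) * n_hap / (n_hap - 1))
    }
  }
  theta_L <- 4 * N * model$mu * L
  a1 <- sum(1 / seq_len(n_hap - 1))
  expect_lt(abs(mean(pi_sum) - theta_L), 3 * sd(pi_sum) / sqrt(reps))
  expect_lt(abs(mean(S) - theta_L * a1), 3 * sd(S) / sqrt(reps))
})
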