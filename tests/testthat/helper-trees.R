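# Hand-built trees and maps used across test files.

toy_map4 <- function() {
  sample_map(data.frame(
    leaf_label = c("a1", "a2", "b1", "b2"),
    individual_id = c("A", "A", "B", "B"),
    population = c("P", "P", "Q", "Q")))
}

# ((a1,a2)@1,(b1,b2)@2)@3
balanced_tree4 <- function(scale = 1) {
  local_tree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
             age = c(0, 0, 0, 0, 1, 2, 3) * scale,
             labels = c("a1", "a2", "b1", "b2"), position = 500)
}

# eight leaves, pop P = {p1..p4}, pop Q = {q1..q4};
# ((p1,p2)@0.2,(p3,q1)@0.9)@1.0 and ((p4,q2)@1.5,(q3,q4)@1.2)@2.0, root @3
eight_leaf_tree <- function() {
  local_tree(
    parent = c(9L, 9L, 10L, 10L, 12L, 12L, 13L, 13L, 11L, 11L, 15L, 14L,
               14L, 15L, 0L),
    age = c(rep(0, 8), 0.2, 0.9, 1.0, 1.5, 1.2, 2.0, 3.0),
    labels = c("p1", "p2", "p3", "q1", "p4", "q2", "q3", "q4"),
    position = 500)
}

eight_leaf_map <- function() {
  sample_map(data.frame(
    leaf_label = c("p1", "p2", "p3", "p4", "q1", "q2", "q3", "q4"),
    individual_id = c("P1", "P1", "P2", "P2", "Q1", "Q1", "Q2", "Q2"),
    population = rep(c("P", "Q"), each = 4)))
}

# near-star caterpillar: internal ages within [1, 1 + (n-2)*eps]
near_star_tree <- function(labels, eps = 1e-9) {
  n <- length(labels)
  m <- 2L * n - 1L
  parent <- integer(m)
  age <- numeric(m)
  cur <- 1L
  for (i in seq_len(n - 1L)) {
    node <- n + i
    other <- i + 1L
    parent[cur] <- node
    parent[other] <- node
    age[node] <- 1 + (i - 1L) * eps
    cur <- node
  }
  local_tree(parent, age, labels, position = 500)
}

# single-population neutral model for analytic coalescent checks
one_pop_model <- function(N = 500) {
  demographic_model(N_source = N, N_satellite = N, T_split = 10 * N,
                    m = 0, mu = 1e-9, r = 1e-9, scale = 1)
}

# brute-force hypergeometric upper tail by subset enumeration
enumerate_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  sets <- utils::combn(N, n)
  hits <- colSums(matrix(sets <= K, nrow = n))
  mean(hits >= k)
}
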