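# Two-population isolation-with-migration coalescent simulator with
# neutral, hard-sweep and soft-sweep modes.  The sweep-site genealogy is a
# structured coalescent conditioned on a deterministic allele-frequency
# trajectory; trees along the region follow by SMC-style single-
# recombination updates; infinite-sites mutations generate haplotypes.

#' Two-population isolation-with-migration demographic model
#'
#' A large source population and a smaller satellite population that split
#' `T_split` generations ago, with unidirectional migration from source
#' into satellite (backward in time, satellite lineages migrate into the
#' source).  Population sizes are diploid.  `scale` rescales the model for
#' tractable simulation: sizes and times are divided by `scale` while
#' selection and migration (and the per-generation mutation and
#' recombination rates) are multiplied by it, preserving theta = 4*N*mu
#' and the expected number of migrants per generation.
#'
#' @param N_source diploid effective size of the source population.
#' @param N_satellite diploid effective size of the satellite population.
#' @param T_split split time in generations before present.
#' @param m per-generation backward migration probability of a satellite
#'   lineage into the source (default gives ~0.5 migrants/generation).
#' @param mu mutation rate per bp per generation.
#' @param r recombination rate per bp per generation.
#' @param scale population-size scaling divisor (default 10).
#' @return a `demographic_model`.
#' @export
demographic_model <- function(N_source = 500000, N_satellite = 93750,
                              T_split = 68000,
                              m = 0.5 / (2 * N_satellite),
                              mu = 1e-9, r = 1e-9, scale = 10) {
  if (any(c(N_source, N_satellite, T_split, scale) <= 0))
    stop("sizes, times and scale must be positive")
  if (m < 0 || m * scale >= 1)
    stop("migration probability must satisfy 0 <= m*scale < 1")
  structure(list(N_source = N_source, N_satellite = N_satellite,
                 T_split = T_split, m = m, mu = mu, r = r, scale = scale),
            class = "demographic_model")
}

#' Demographic presets for the two satellite-island comparisons
#'
#' `"sasc"`: satellite split ~68k generations ago with N roughly 3/16 of
#' the source.  `"ugi"`: split ~6x earlier with N roughly 1/8 of the
#' source (about two thirds of the other satellite's).  These are
#' ratio-derived presets, not fitted estimates; override any field via
#' `...`.
#'
#' @param name `"sasc"` or `"ugi"`.
#' @param ... overrides passed to [demographic_model].
#' @return a `demographic_model`.
#' @export
demographic_preset <- function(name = c("sasc", "ugi"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    sasc = list(N_source = 500000, N_satellite = 93750, T_split = 68000),
    ugi = list(N_source = 500000, N_satellite = 62500, T_split = 408000))
  args$m <- 0.5 / (2 * args$N_satellite)
  over <- list(...)
  args[names(over)] <- over
  do.call(demographic_model, args)
}

# scaled parameters actually used in simulation
scaled_model <- function(model) {
  list(N_source = model$N_source / model$scale,
       N_satellite = model$N_satellite / model$scale,
       T_split = model$T_split / model$scale,
       m = model$m * model$scale,
       mu = model$mu * model$scale,
       r = model$r * model$scale)
}

#' Sweep / simulation configuration
#'
#' @param mode `"neutral"`, `"hard"` or `"soft"`.
#' @param s selection coefficient on the pre-scaling parameter scale
#'   (multiplied by the model's `scale` in simulation).
#' @param onset selection onset, generations before present.
#' @param f_init initial derived frequency at onset; forced to
#'   1/(2*N_satellite/scale) for hard sweeps, must lie in [0.01, 0.1] for
#'   soft sweeps.
#' @param region_bp simulated region length (default 100000).
#' @param sweep_pos sweep site (default the region center).
#' @param retain_daf_min minimum present-day derived allele frequency for
#'   a sweep replicate to be retained (default 0.2).
#' @return a `sweep_config`.
#' @export
sweep_config <- function(mode = c("neutral", "hard", "soft"), s = NA,
                         onset = NA, f_init = NA, region_bp = 100000,
                         sweep_pos = NULL, retain_daf_min = 0.2) {
  mode <- match.arg(mode)
  if (mode != "neutral") {
    if (!is.finite(s) || s <= 0) stop("sweep modes need s > 0")
    if (!is.finite(onset) || onset < 1) stop("sweep modes need onset >= 1")
    if (mode == "soft" &&
        (!is.finite(f_init) || f_init < 0.01 || f_init > 0.1))
      stop("soft sweeps need f_init in [0.01, 0.1]")
  }
  if (is.null(sweep_pos)) sweep_pos <- region_bp / 2
  structure(list(mode = mode, s = s, onset = round(onset), f_init = f_init,
                 region_bp = region_bp, sweep_pos = sweep_pos,
                 retain_daf_min = retain_daf_min),
            class = "sweep_config")
}

#' Draw sweep parameters for one simulation replicate
#'
#' The selection coefficient is drawn from an equal mixture of a uniform
#' and a log-uniform distribution on [0.001, 0.025] (pre-scaling); the
#' mode is hard or soft with equal probability; for soft sweeps
#' f_init ~ U(0.01, 0.1).  The onset is implied by the parameters: the
#' deterministic fixation time from f_init under the scaled s, clamped to
#' [250, 20000] generations so sweeps are completed or recently fixed.
#'
#' @param model a `demographic_model`.
#' @param seed optional RNG seed (draws are otherwise taken from the
#'   current RNG stream).
#' @param s_range pre-scaling selection coefficient range.
#' @return a `sweep_config`.
#' @export
sample_sweep_params <- function(model, seed = NULL,
                                s_range = c(0.001, 0.025)) {
  if (!is.null(seed)) set.seed(seed)
  sm <- scaled_model(model)
  s <- if (runif(1) < 0.5) runif(1, s_range[1], s_range[2])
       else exp(runif(1, log(s_range[1]), log(s_range[2])))
  mode <- sample(c("hard", "soft"), 1)
  f_init <- if (mode == "soft") runif(1, 0.01, 0.1)
            else 1 / (2 * sm$N_satellite)
  traj <- deterministic_trajectory(s * model$scale, f_init, sm$N_satellite)
  onset <- min(max(traj$fixation_gen, 250), 20000)
  sweep_config(mode, s = s, onset = onset, f_init = f_init)
}

#' Deterministic logistic sweep trajectory
#'
#' Genic selection recursion p' = p(1+s) / (1 + s*p) iterated per
#' generation from `f_init` until the frequency reaches 1 - 1/(4N)
#' (effective fixation) or the generation budget runs out.
#'
#' @param s selection coefficient (on the scale actually simulated).
#' @param f_init initial frequency in (0, 1).
#' @param N diploid population size (sets the fixation boundary).
#' @param max_gen generation budget (default 1e6).
#' @return a `trajectory`: list with `freqs` (frequency at generations
#'   0, 1, ... after onset), `fixation_gen`, `p_end`, and the inputs.
#' @export
deterministic_trajectory <- function(s, f_init, N, max_gen = 1e6) {
  if (f_init <= 0 || f_init >= 1) stop("f_init must lie in (0, 1)")
  if (s <= 0) stop("s must be positive (neutral trajectories are degenerate)")
  cap <- 1 - 1 / (4 * N)
  # closed-form logistic recursion: p_t = p0 (1+s)^t / (1 - p0 + p0 (1+s)^t)
  t_fix <- ceiling(log((cap / (1 - cap)) / (f_init / (1 - f_init))) /
                     log(1 + s))
  if (t_fix > max_gen)
    stop("trajectory did not reach fixation within ", max_gen, " generations")
  tt <- 0:t_fix
  odds <- (f_init / (1 - f_init)) * (1 + s)^tt
  freqs <- pmin(odds / (1 + odds), cap)
  structure(list(s = s, f_init = f_init, N = N, freqs = freqs,
                 fixation_gen = t_fix, p_end = freqs[length(freqs)]),
            class = "trajectory")
}

# frequency at backward generation g (0 = present) for a sweep that
# started `onset` generations ago
traj_backward <- function(traj, onset, g) {
  gf <- onset - 1 - g           # forward generation index during [g, g+1)
  if (gf < 0) gf <- 0
  if (gf >= traj$fixation_gen) traj$p_end else traj$freqs[gf + 1]
}

#' Sample map for simulated data
#'
#' Haploid leaves `sat_i_1/2` and `src_i_1/2` paired into diploid
#' individuals; odd haploid counts leave one single-leaf individual.
#'
#' @param n_source,n_satellite haploid sample sizes.
#' @return a `sample_map` with populations `satellite`, `source`.
#' @export
sim_sample_map <- function(n_source, n_satellite) {
  mk <- function(prefix, pop, k) {
    if (k == 0L) return(NULL)
    ind <- ceiling(seq_len(k) / 2)
    copy <- ifelse(seq_len(k) %% 2 == 1L, 1L, 2L)
    data.frame(leaf_label = paste0(prefix, "_", ind, "_", copy),
               individual_id = paste0(prefix, "_", ind),
               population = pop)
  }
  sample_map(rbind(mk("sat", "satellite", n_satellite),
                   mk("src", "source", n_source)))
}

# Structured-coalescent engine at the sweep site.  Leaves 1..n_satellite
# are satellite (a caller-chosen subset marked derived), the rest source.
# Phase A (backward time 0..onset): derived/ancestral classes in the
# satellite coalesce within-class at rates driven by the trajectory
# x(t); no cross-class coalescence, no migration.  Phase A2 (beyond
# onset, derived class not yet a single lineage): the derived class
# coalesces within a background of constant size N_sat * f_init until its
# MRCA (single mutational origin), while other lineages follow the
# neutral IM process.  Neutral phases: within-deme coalescence, backward
# satellite->source migration at rate m, deme merge at T_split.
sim_engine <- function(sm, mode, onset, f_init, traj,
                       n_source, n_satellite, derived_idx) {
  n <- n_source + n_satellite
  if (n < 2) stop("need at least 2 haploid samples")
  M <- 2L * n - 1L
  parent <- integer(M)
  age <- numeric(M)
  nxt <- n
  lin_node <- seq_len(n)
  lin_deme <- c(rep(1L, n_satellite), rep(2L, n_source))
  lin_cls <- rep(2L, n)
  lin_cls[derived_idx] <- 1L
  mut_node <- NA_integer_
  t <- 0

  coalesce <- function(i, j, when) {
    nxt <<- nxt + 1L
    parent[lin_node[i]] <<- nxt
    parent[lin_node[j]] <<- nxt
    age[nxt] <<- when
    lin_node[i] <<- nxt
    lin_node <<- lin_node[-j]
    lin_deme <<- lin_deme[-j]
    lin_cls <<- lin_cls[-j]
  }
  pick2 <- function(idx) if (length(idx) == 2L) idx else sample(idx, 2L)

  # ---- Phase A: sweep, per-generation trajectory-driven rates ----
  if (mode != "neutral") {
    while (t < onset && length(lin_node) > 1L) {
      g <- floor(t + 1e-9)
      gen_end <- min(g + 1, onset)
      x <- traj_backward(traj, onset, g)
      repeat {
        id_d <- which(lin_deme == 1L & lin_cls == 1L)
        id_a <- which(lin_deme == 1L & lin_cls == 2L)
        id_s <- which(lin_deme == 2L)
        kd <- length(id_d); ka <- length(id_a); ks <- length(id_s)
        Rd <- if (kd >= 2) kd * (kd - 1) / 2 / (2 * sm$N_satellite * x) else 0
        Ra <- if (ka >= 2) ka * (ka - 1) / 2 / (2 * sm$N_satellite * (1 - x)) else 0
        Rs <- if (ks >= 2) ks * (ks - 1) / 2 / (2 * sm$N_source) else 0
        R <- Rd + Ra + Rs
        if (R == 0) { t <- gen_end; break }
        dt <- rexp(1, R)
        if (t + dt >= gen_end) { t <- gen_end; break }
        t <- t + dt
        u <- runif(1) * R
        if (u < Rd) { ij <- pick2(id_d); coalesce(ij[1], ij[2], t) }
        else if (u < Rd + Ra) { ij <- pick2(id_a); coalesce(ij[1], ij[2], t) }
        else { ij <- pick2(id_s); coalesce(ij[1], ij[2], t) }
      }
    }
    t <- max(t, onset)
  }

  # ---- Phases A2 / B / C: continuous-time with epoch at T_split ----
  while (length(lin_node) > 1L) {
    if (t >= sm$T_split) lin_deme[] <- 2L
    id_d <- which(lin_cls == 1L)
    if (mode != "neutral" && length(id_d) == 1L && is.na(mut_node)) {
      mut_node <- lin_node[id_d]     # single origin reached: mark mutation
      lin_cls[id_d] <- 2L
      id_d <- integer(0)
    }
    id_a <- which(lin_deme == 1L & lin_cls == 2L)
    id_s <- which(lin_deme == 2L & lin_cls == 2L)
    kd <- length(id_d); ka <- length(id_a); ks <- length(id_s)
    Rd <- if (kd >= 2) kd * (kd - 1) / 2 / (2 * sm$N_satellite * f_init) else 0
    Ra <- if (ka >= 2) ka * (ka - 1) / 2 / (2 * sm$N_satellite) else 0
    Rs <- if (ks >= 2) ks * (ks - 1) / 2 / (2 * sm$N_source) else 0
    Rm <- if (t < sm$T_split) ka * sm$m else 0
    R <- Rd + Ra + Rs + Rm
    if (R == 0) { t <- sm$T_split; next }   # wait for the deme merge
    dt <- rexp(1, R)
    if (t < sm$T_split && t + dt >= sm$T_split) { t <- sm$T_split; next }
    t <- t + dt
    u <- runif(1) * R
    if (u < Rd) { ij <- pick2(id_d); coalesce(ij[1], ij[2], t) }
    else if (u < Rd + Ra) { ij <- pick2(id_a); coalesce(ij[1], ij[2], t) }
    else if (u < Rd + Ra + Rs) { ij <- pick2(id_s); coalesce(ij[1], ij[2], t) }
    else { lin_deme[sample(id_a, 1L)] <- 2L }  # backward migration sat->src
  }
  list(parent = parent, age = age, mut_node = mut_node)
}

#' Simulate the genealogy at a sweep site
#'
#' Draws the number of sampled derived satellite leaves from the
#' present-day frequency of the deterministic trajectory, then runs the
#' structured coalescent (see the package vignette for the phase
#' structure).  Sweep replicates whose sampled derived allele frequency
#' falls below `retain_daf_min` are redrawn.
#'
#' @param model a `demographic_model`.
#' @param cfg a `sweep_config`.
#' @param n_source,n_satellite haploid sample sizes per population.
#' @param seed optional RNG seed.
#' @param max_retries redraws allowed for the retention rule.
#' @return list with `tree` (a `local_tree`), `derived_leaves` (character,
#'   empty for neutral mode), `trajectory` (or NULL), `daf` (sampled
#'   derived allele frequency) and `map` (the matching `sample_map`).
#' @export
simulate_genealogy <- function(model, cfg, n_source, n_satellite,
                               seed = NULL, max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (n_satellite < 1 && cfg$mode != "neutral")
    stop("sweeps need satellite samples")
  sm <- scaled_model(model)
  map <- sim_sample_map(n_source, n_satellite)
  labels <- c(if (n_satellite) paste0("sat_", ceiling(seq_len(n_satellite) / 2),
                                      "_", ifelse(seq_len(n_satellite) %% 2, 1, 2)),
              if (n_source) paste0("src_", ceiling(seq_len(n_source) / 2),
                                   "_", ifelse(seq_len(n_source) %% 2, 1, 2)))
  traj <- NULL
  derived_idx <- integer(0)
  if (cfg$mode == "neutral") {
    eng <- sim_engine(sm, "neutral", 0, NA, NULL, n_source, n_satellite,
                      integer(0))
    daf <- 0
  } else {
    f_init <- if (cfg$mode == "hard") 1 / (2 * sm$N_satellite) else cfg$f_init
    traj <- deterministic_trajectory(cfg$s * model$scale, f_init,
                                     sm$N_satellite)
    p0 <- traj_backward(traj, cfg$onset, 0)
    nd <- NA_integer_
    for (try in seq_len(max_retries)) {
      nd <- rbinom(1, n_satellite, p0)
      if (nd >= 1 && nd / n_satellite >= cfg$retain_daf_min) break
      nd <- NA_integer_
    }
    if (is.na(nd))
      stop(sprintf(
        "no replicate reached derived allele frequency >= %g in %d draws (present-day frequency %.3g); increase onset or s",
        cfg$retain_daf_min, max_retries, p0))
    derived_idx <- sort(sample(n_satellite, nd))
    daf <- nd / n_satellite
    eng <- sim_engine(sm, cfg$mode, cfg$onset, f_init, traj,
                      n_source, n_satellite, derived_idx)
  }
  tree <- new_local_tree(eng$parent, eng$age, labels,
                         position = cfg$sweep_pos)
  validate_local_tree(tree)
  list(tree = tree, derived_leaves = labels[derived_idx],
       trajectory = traj, daf = daf, map = map)
}

# One SMC-style update: detach a uniformly chosen point of the tree and
# re-coalesce the dangling lineage against the remaining tree, with
# effective size N_satellite below T_split and N_source above (population
# labels are ignored during re-coalescence; see the vignette).
smc_recoalesce <- function(tree, sm) {
  parent <- tree$parent
  age <- tree$age
  m <- length(parent)
  ch_nodes <- which(parent > 0L)
  len <- age[parent[ch_nodes]] - age[ch_nodes]
  c_node <- ch_nodes[sample.int(length(ch_nodes), 1L, prob = len)]
  p_node <- parent[c_node]
  u <- runif(1, age[c_node], age[p_node])
  sib <- setdiff(which(parent == p_node), c_node)
  # splice p_node out of the remaining tree
  parent[sib] <- parent[p_node]
  root <- if (parent[p_node] == 0L) sib else {
    r <- which(parent == 0L)
    if (r == p_node) sib else r
  }
  parent[p_node] <- -1L  # freed id, reused for the new coalescence node
  # lineages of the remaining tree crossing age t:
  rem <- setdiff(which(parent > 0L), c_node)
  lo <- age[rem]
  hi <- age[parent[rem]]
  root_age <- age[root]
  n_cross <- function(t) sum(lo <= t & t < hi) + (t >= root_age)
  # piecewise-constant rate inversion for the re-coalescence time
  brk <- sort(unique(c(u, lo[lo > u], hi[hi > u], root_age[root_age > u],
                       if (sm$T_split > u) sm$T_split)))
  E <- rexp(1)
  t_star <- NA_real_
  for (i in seq_along(brk)) {
    t0 <- brk[i]
    t1 <- if (i < length(brk)) brk[i + 1] else Inf
    L <- n_cross((t0 + min(t1, t0 + 1)) / 2)
    rate <- L / (2 * (if (t0 < sm$T_split) sm$N_satellite else sm$N_source))
    if (is.finite(t1) && E > rate * (t1 - t0)) {
      E <- E - rate * (t1 - t0)
    } else {
      t_star <- t0 + E / rate
      break
    }
  }
  # choose the partner lineage uniformly among those crossing t_star
  cand <- rem[lo <= t_star & t_star < hi]
  if (t_star >= root_age) cand <- c(cand, root)
  q <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  w <- p_node
  if (q == root && t_star >= root_age) {
    parent[w] <- 0L
  } else {
    parent[w] <- parent[q]
  }
  parent[q] <- w
  parent[c_node] <- w
  age[w] <- t_star
  new_local_tree(parent, age, tree$labels, tree$position)
}

#' Simulate a region: tree series, haplotypes and truth labels
#'
#' Simulates the sweep-site genealogy at the region center (or a neutral
#' genealogy), extends it to a series of local trees every `interval` bp
#' by SMC-style single-recombination updates (Poisson number per step with
#' mean r * interval * total branch length), and drops infinite-sites
#' mutations (Poisson with mean mu * interval * total branch length per
#' tree) to produce phased haplotypes.
#'
#' @param model a `demographic_model`.
#' @param cfg a `sweep_config`.
#' @param n_source,n_satellite haploid sample sizes.
#' @param interval tree sampling interval in bp (default 500).
#' @param seed optional RNG seed.
#' @param mutations drop mutations and build haplotypes (default TRUE;
#'   disable when only the tree series is needed).
#' @return list with `series` (a `tree_series`), `haplotypes` (a
#'   `haplotype_matrix`, rows in sample-map leaf order), `map`,
#'   `derived_leaves`, `labels` (truth record: mode, s, onset, f_init,
#'   daf, sweep position) and `trajectory`.
#' @export
simulate_region <- function(model, cfg, n_source, n_satellite,
                            interval = 500, seed = NULL, mutations = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$region_bp < interval) stop("region_bp must be >= interval")
  sm <- scaled_model(model)
  positions <- seq(interval, cfg$region_bp, by = interval)
  ci <- which.min(abs(positions - cfg$sweep_pos))
  site <- simulate_genealogy(model, cfg, n_source, n_satellite)
  trees <- vector("list", length(positions))
  center <- site$tree
  center$position <- positions[ci]
  trees[[ci]] <- center
  walk <- function(from, idx_seq) {
    cur <- trees[[from]]
    for (i in idx_seq) {
      tl <- sum(cur$age[cur$parent[cur$parent > 0L]] -
                  cur$age[cur$parent > 0L])
      n_rec <- rpois(1, sm$r * interval * tl)
      for (k in seq_len(n_rec)) cur <- smc_recoalesce(cur, sm)
      cur$position <- positions[i]
      trees[[i]] <<- cur
    }
  }
  if (ci < length(positions)) walk(ci, (ci + 1):length(positions))
  if (ci > 1) walk(ci, (ci - 1):1)
  series <- tree_series(contig = "sim", contig_length = cfg$region_bp,
                        trees = trees, sampling_interval = interval,
                        block_bounds = matrix(c(0, cfg$region_bp), 1))
  hap <- if (mutations) drop_mutations(series, sm$mu, interval) else NULL
  list(series = series, haplotypes = hap, map = site$map,
       derived_leaves = site$derived_leaves,
       labels = list(mode = cfg$mode, s = cfg$s, onset = cfg$onset,
                     f_init = cfg$f_init, daf = site$daf,
                     sweep_pos = positions[ci]),
       trajectory = site$trajectory)
}

# infinite-sites mutations: tree i covers ((i-1)*interval, i*interval];
# mutation count ~ Poisson(mu * interval * total branch length), placed on
# branches proportionally to length; carriers are the leaves under the
# mutated branch
drop_mutations <- function(series, mu, interval) {
  n <- n_leaves(series$trees[[1]])
  labels <- series$trees[[1]]$labels
  pos_list <- list()
  hap_list <- list()
  used <- new.env(hash = TRUE)
  for (i in seq_along(series$trees)) {
    tr <- series$trees[[i]]
    ch <- which(tr$parent > 0L)
    len <- tr$age[tr$parent[ch]] - tr$age[ch]
    tl <- sum(len)
    k <- rpois(1, mu * interval * tl)
    if (k == 0) next
    below <- accumulate_clades(tr, diag(1L, n))  # node x leaf membership
    span_lo <- (i - 1) * interval
    for (j in seq_len(k)) {
      v <- ch[sample.int(length(ch), 1L, prob = len)]
      carriers <- below[v, ]
      if (all(carriers == 1L)) next           # mutation above the root path
      p <- span_lo + sample.int(interval, 1L)
      key <- as.character(p)
      tries <- 0
      while (!is.null(used[[key]]) && tries < 25) {
        p <- span_lo + sample.int(interval, 1L)
        key <- as.character(p)
        tries <- tries + 1
      }
      if (!is.null(used[[key]])) next          # span saturated, drop
      used[[key]] <- TRUE
      pos_list[[length(pos_list) + 1L]] <- p
      hap_list[[length(hap_list) + 1L]] <- as.integer(carriers)
    }
  }
  if (!length(pos_list)) {
    hm <- haplotype_matrix(matrix(integer(0), nrow = n, ncol = 0), numeric(0))
    rownames(hm$hap) <- labels
    return(hm)
  }
  pos <- unlist(pos_list)
  ord <- order(pos)
  hap <- do.call(cbind, hap_list)[, ord, drop = FALSE]
  rownames(hap) <- labels
  haplotype_matrix(hap, pos[ord])
}

#' Write simulated haplotypes as a phased VCF
#'
#' Minimal VCF 4.2 with REF=A/ALT=T placeholder alleles, phased GT and a
#' constant DP so that depth-based site filters are well defined on
#' simulated data.
#'
#' @param hm a `haplotype_matrix` with row names matching the sample map
#'   leaf labels.
#' @param map a `sample_map`.
#' @param path output path.
#' @param contig contig name.
#' @param contig_length contig length for the VCF header.
#' @param depth constant per-genotype DP value (default 30).
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(hm, map, path, contig = "sim",
                          contig_length = NULL, depth = 30) {
  inds <- unique(map$individual_id)
  header <- c("##fileformat=VCFv4.2",
              "##source=argscan-simulator",
              if (!is.null(contig_length))
                sprintf("##contig=<ID=%s,length=%d>", contig,
                        as.integer(contig_length)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", inds), collapse = "\t"))
  S <- ncol(hm$hap)
  rows <- character(S)
  gt_cols <- lapply(inds, function(id) {
    leaves <- map$leaf_label[map$individual_id == id]
    idx <- match(leaves, rownames(hm$hap))
    if (anyNA(idx)) stop("sample map leaf missing from haplotypes: ", id)
    if (length(idx) == 2L)
      paste0(hm$hap[idx[1], ], "|", hm$hap[idx[2], ], ":", depth)
    else paste0(hm$hap[idx[1], ], ":", depth)
  })
  for (s in seq_len(S)) {
    rows[s] <- paste(c(contig, format(hm$positions[s], scientific = FALSE),
                       ".", "A", "T", ".", "PASS", ".", "GT:DP",
                       vapply(gt_cols, `[[`, character(1), s)),
                     collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Migrants per generation from mutation-scaled parameters
#'
#' Converts a mutation-scaled per-generation migration rate and the
#' receiving population's theta into the expected number of migrants per
#' generation: m * theta / 4.
#'
#' @param m mutation-scaled migration rate (>= 0).
#' @param theta mutation-scaled size of the receiving population (>= 0).
#' @return migrants per generation.
#' @export
migrants_per_generation <- function(m, theta) {
  if (m < 0 || theta < 0) stop("m and theta must be non-negative")
  m * theta / 4
}
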