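# End-to-end scan orchestration: validate -> edge-discard -> per-tree
# statistics -> windowed averages -> empirical thresholds from control
# contigs -> flagged focal windows.  Also builds the deterministic
# simulated fixture bundle used by the tests and the analysis scripts.

#' Scan configuration
#'
#' @param window_bp window size for tree-statistic averages (default
#'   20000).
#' @param interval_bp tree sampling interval (default 500; a full window
#'   then averages 40 trees).
#' @param edge_discard_bp trim at ARG block edges (default 50000).
#' @param levels empirical outlier levels (default 0.01, 0.005, 0.001).
#' @param statistics which tree statistics to scan.
#' @param populations populations to scan (default: all in the map).
#' @param seed stored for provenance.
#' @return a `scan_config`.
#' @export
scan_config <- function(window_bp = 20000, interval_bp = 500,
                        edge_discard_bp = 50000,
                        levels = c(0.01, 0.005, 0.001),
                        statistics = c("enrichment", "rth_prime"),
                        populations = NULL, seed = NULL) {
  if (any(levels <= 0 | levels >= 0.5))
    stop("levels must lie in (0, 0.5)")
  if (window_bp %% interval_bp != 0)
    warning("window_bp is not a multiple of interval_bp; windows will average unequal tree counts")
  structure(list(window_bp = window_bp, interval_bp = interval_bp,
                 edge_discard_bp = edge_discard_bp, levels = levels,
                 statistics = statistics, populations = populations,
                 seed = seed),
            class = "scan_config")
}

series_windows <- function(series, map, config) {
  trimmed <- tryCatch(
    discard_block_edges(series, config$edge_discard_bp),
    error = function(e) stop(sprintf("contig %s: %s", series$contig,
                                     conditionMessage(e)), call. = FALSE))
  do.call(rbind, lapply(config$statistics, function(st)
    window_average(trimmed, map, st, window_bp = config$window_bp,
                   populations = config$populations)))
}

#' Run the sweep scan end to end
#'
#' Computes windowed enrichment and RTH' for every population on all
#' focal and control contigs, derives empirical thresholds from the
#' control windows only, and flags the focal windows.
#'
#' @param config a `scan_config`.
#' @param focal_series list of `tree_series` to scan (may be empty).
#' @param control_series non-empty list of `tree_series` providing the
#'   control distribution.
#' @param map a `sample_map`.
#' @return list with `focal` (flagged window table), `control` (control
#'   window table), `thresholds` (a `threshold_set`) and `config`.
#' @export
run_scan <- function(config, focal_series, control_series, map) {
  if (!length(control_series)) stop("control series must be non-empty")
  control <- do.call(rbind, lapply(control_series, series_windows,
                                   map = map, config = config))
  thresholds <- empirical_thresholds(control, levels = config$levels)
  focal <- if (length(focal_series))
    do.call(rbind, lapply(focal_series, series_windows,
                          map = map, config = config))
  else control[0, ]
  focal <- flag_windows(focal, thresholds)
  list(focal = focal, control = control, thresholds = thresholds,
       config = config)
}

#' Simulate neutral control windows for threshold calibration
#'
#' Generates neutral contigs under the model, computes windowed tree
#' statistics and returns the first `n_windows` windows per population.
#' Used to calibrate empirical thresholds and to check that the flagged
#' fraction on the control set matches the nominal level.
#'
#' @param model a `demographic_model`.
#' @param n_windows number of control windows to return.
#' @param n_source,n_satellite haploid sample sizes (desk-scale defaults).
#' @param window_bp window size (default 20000).
#' @param interval tree sampling interval (default 500).
#' @param windows_per_contig windows simulated per neutral contig.
#' @param statistic tree statistic to window.
#' @param populations populations to evaluate (default satellite only).
#' @param seed optional RNG seed.
#' @return data frame of control `WindowStat` rows.
#' @export
simulate_control_windows <- function(model, n_windows, n_source = 12,
                                     n_satellite = 10, window_bp = 20000,
                                     interval = 500, windows_per_contig = 10,
                                     statistic = "enrichment",
                                     populations = "satellite",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_contig <- ceiling(n_windows / windows_per_contig)
  out <- vector("list", n_contig)
  cfg <- sweep_config("neutral",
                      region_bp = windows_per_contig * window_bp)
  for (i in seq_len(n_contig)) {
    sim <- simulate_region(model, cfg, n_source, n_satellite,
                           interval = interval, mutations = FALSE)
    sim$series$contig <- paste0("ctl_", i)
    out[[i]] <- window_average(sim$series, sim$map, statistic,
                               window_bp = window_bp,
                               populations = populations)
  }
  res <- do.call(rbind, out)
  res[unlist(lapply(populations, function(p)
    head(which(res$population == p), n_windows))), , drop = FALSE]
}

#' Build the deterministic simulated fixture bundle
#'
#' Simulates two focal contigs (one hard sweep at the center, one
#' neutral) and three neutral control contigs under the scaled
#' two-population model, at desk scale.  With `dir` given, writes the
#' newick/BED/sample-map/VCF/JSON artifacts of every contig.
#'
#' @param seed RNG seed; the bundle is fully determined by it.
#' @param dir optional output directory.
#' @param model a `demographic_model` (default: `"sasc"` preset).
#' @param n_source,n_satellite haploid sample sizes (desk-scale defaults).
#' @param s selection coefficient (pre-scaling) of the sweep contig.
#' @param focal_bp,control_bp contig lengths; controls are long enough
#'   that three of them give >= 100 windows after edge discard.
#' @param edge_discard_bp trim used to size the contigs.
#' @return list with `focal` (list of 2 `tree_series`), `control` (list
#'   of 3), `map`, `truth` (per-contig labels) and `vcf_paths` (when
#'   written).
#' @export
make_fixtures <- function(seed, dir = NULL,
                          model = demographic_preset("sasc"),
                          n_source = 12, n_satellite = 10, s = 0.025,
                          focal_bp = 300000, control_bp = 840000,
                          edge_discard_bp = 50000) {
  set.seed(seed)
  sm <- scaled_model(model)
  sweep_cfg <- sweep_config("hard", s = s,
                            onset = min(max(deterministic_trajectory(
                              s * model$scale, 1 / (2 * sm$N_satellite),
                              sm$N_satellite)$fixation_gen, 250), 20000),
                            region_bp = focal_bp)
  neutral_focal <- sweep_config("neutral", region_bp = focal_bp)
  neutral_ctl <- sweep_config("neutral", region_bp = control_bp)
  sims <- list(
    sweep = simulate_region(model, sweep_cfg, n_source, n_satellite),
    focal_neutral = simulate_region(model, neutral_focal,
                                    n_source, n_satellite),
    control_1 = simulate_region(model, neutral_ctl, n_source, n_satellite),
    control_2 = simulate_region(model, neutral_ctl, n_source, n_satellite),
    control_3 = simulate_region(model, neutral_ctl, n_source, n_satellite))
  for (nm in names(sims)) sims[[nm]]$series$contig <- nm
  map <- sims$sweep$map
  truth <- lapply(sims, `[[`, "labels")
  vcf_paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sample_map(map, file.path(dir, "samples.tsv"))
    vcf_paths <- character(0)
    for (nm in names(sims)) {
      x <- sims[[nm]]
      write_tree_series(x$series, file.path(dir, paste0(nm, ".nwk")),
                        file.path(dir, paste0(nm, ".bed")))
      vp <- file.path(dir, paste0(nm, ".vcf"))
      write_sim_vcf(x$haplotypes, map, vp, contig = nm,
                    contig_length = x$series$contig_length)
      vcf_paths[nm] <- vp
    }
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(focal = list(sims$sweep$series, sims$focal_neutral$series),
       control = list(sims$control_1$series, sims$control_2$series,
                      sims$control_3$series),
       map = map, truth = truth, vcf_paths = vcf_paths)
}
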