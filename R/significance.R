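# Empirical outlier thresholds from control windows, window flagging, and
# Bonferroni arithmetic.  Enrichment outliers sit in the upper tail of the
# control distribution, RTH' outliers in the lower tail.

default_tails <- c(enrichment = "upper", rth_prime = "lower")

#' Empirical outlier thresholds from control windows
#'
#' For each (population, statistic) pair the cutoff at level q is the
#' control value at ascending rank `ceiling((1 - q) * M)` among the M
#' control values (upper tail; the lower tail mirrors the rank), so at
#' most a fraction q of control values lie strictly beyond their own
#' cutoff, with equality when (1 - q) * M is an integer.  Windows
#' are later flagged only when strictly beyond a cutoff, which guarantees
#' a flagged fraction <= q on the control set itself.
#'
#' @param control data frame of control window statistics with columns
#'   population, statistic, value (as produced by [window_average]).
#' @param levels outlier quantile levels (default 0.01, 0.005, 0.001).
#' @param tails named character vector mapping statistic to
#'   `"upper"`/`"lower"`; defaults cover enrichment and rth_prime.
#' @return a `threshold_set`: data frame population, statistic, level,
#'   tail, cutoff, n_control.
#' @export
empirical_thresholds <- function(control, levels = c(0.01, 0.005, 0.001),
                                 tails = default_tails) {
  if (any(levels <= 0 | levels >= 0.5))
    stop("quantile levels must lie in (0, 0.5)")
  need_m <- ceiling(1 / min(levels))
  groups <- unique(control[, c("population", "statistic")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    pop <- groups$population[g]
    st <- groups$statistic[g]
    tail <- tails[[st]]
    if (is.null(tail)) stop("no tail direction known for statistic ", st)
    vals <- control$value[control$population == pop &
                            control$statistic == st]
    vals <- vals[is.finite(vals)]
    M <- length(vals)
    if (M < need_m)
      stop(sprintf(
        "too few control windows for %s/%s: %d given, at least %d needed for level %g",
        pop, st, M, need_m, min(levels)))
    s <- sort(vals)
    for (q in levels) {
      rank_up <- ceiling((1 - q) * M)
      cutoff <- if (tail == "upper") s[rank_up] else s[M + 1L - rank_up]
      out[[length(out) + 1L]] <- data.frame(
        population = pop, statistic = st, level = q, tail = tail,
        cutoff = cutoff, n_control = M)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("threshold_set", "data.frame")
  res
}

#' Flag windows against empirical thresholds
#'
#' Annotates each window with the smallest level q at which it is an
#' outlier (strictly above an upper-tail cutoff, strictly below a
#' lower-tail one), or `"ns"` when it is beyond no cutoff.
#'
#' @param stats data frame of window statistics (population, statistic,
#'   value).
#' @param thresholds a `threshold_set` covering every (population,
#'   statistic) present in `stats`.
#' @return `stats` with added columns `flag` (character: the level or
#'   "ns") and `flag_level` (numeric, NA when not significant).
#' @export
flag_windows <- function(stats, thresholds) {
  if (nrow(stats) == 0L) {
    stats$flag <- character(0)
    stats$flag_level <- numeric(0)
    return(stats)
  }
  flag_level <- rep(NA_real_, nrow(stats))
  for (i in seq_len(nrow(stats))) {
    th <- thresholds[thresholds$population == stats$population[i] &
                       thresholds$statistic == stats$statistic[i], ]
    if (nrow(th) == 0L)
      stop(sprintf("no thresholds for population %s, statistic %s",
                   stats$population[i], stats$statistic[i]))
    beyond <- if (th$tail[1] == "upper") stats$value[i] > th$cutoff
              else stats$value[i] < th$cutoff
    if (any(beyond)) flag_level[i] <- min(th$level[beyond])
  }
  stats$flag <- ifelse(is.na(flag_level), "ns",
                       paste0("p<", as.character(flag_level)))
  stats$flag_level <- flag_level
  stats
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}
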