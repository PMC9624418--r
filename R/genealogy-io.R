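# Readers/writers for the artifacts an ARG scan consumes: a sample map
# assigning haploid leaves to diploid individuals and populations, and a
# series of local trees (one newick per line) with a BED position table.

#' Build a sample map from a data frame
#'
#' @param df data frame with columns `leaf_label`, `individual_id`,
#'   `population`.
#' @return a `sample_map`: the data frame with attributes `populations`
#'   (first-appearance order), `K` (named haploid counts per population)
#'   and `N` (total haploid sample size).
#' @export
sample_map <- function(df) {
  need <- c("leaf_label", "individual_id", "population")
  if (!all(need %in% names(df)))
    stop("sample map requires columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (nrow(df) == 0L) stop("sample map is empty (no samples)")
  dup <- df$leaf_label[duplicated(df$leaf_label)]
  if (length(dup))
    stop("duplicate leaf label(s) in sample map: ",
         paste(unique(dup), collapse = ", "))
  per_ind <- table(df$individual_id)
  if (any(per_ind > 2L))
    stop("individual(s) with more than 2 haploid leaves: ",
         paste(names(per_ind)[per_ind > 2L], collapse = ", "))
  pops <- unique(df$population)
  K <- vapply(pops, function(p) sum(df$population == p), integer(1))
  structure(df, class = c("sample_map", "data.frame"),
            populations = pops, K = K, N = nrow(df))
}

#' Read a sample map from a tab-separated file
#'
#' @param path tab-separated file with header columns `leaf_label`,
#'   `individual_id`, `population`.
#' @return a `sample_map`.
#' @export
read_sample_map <- function(path) {
  df <- tryCatch(read.delim(path, colClasses = "character"),
                 error = function(e) stop("cannot read sample map ", path,
                                          ": ", conditionMessage(e)))
  sample_map(df)
}

#' Write a sample map
#' @param map a `sample_map`.
#' @param path output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_sample_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Population haploid sample sizes of a sample map
#' @param map a `sample_map`.
#' @return named integer vector `K` per population.
#' @export
pop_sizes <- function(map) attr(map, "K")

#' Construct a tree series
#'
#' An ordered series of local genealogies along one contig.  Block bounds
#' delimit the independently inferred ARG blocks (0-based, half-open, BED
#' convention); tree positions are 1-based bp.
#'
#' @param contig contig name.
#' @param contig_length contig length in bp.
#' @param trees list of `local_tree` with strictly increasing positions.
#' @param sampling_interval bp between consecutive trees (inferred from
#'   positions when `NULL`).
#' @param block_bounds two-column matrix of block `(start, end)`,
#'   0-based half-open; default one block spanning the contig.
#' @return a `tree_series`.
#' @export
tree_series <- function(contig, contig_length, trees,
                        sampling_interval = NULL, block_bounds = NULL) {
  pos <- vapply(trees, function(t) t$position, numeric(1))
  if (anyNA(pos)) stop("all trees in a series need a position")
  if (any(diff(pos) <= 0)) stop("tree positions must be strictly increasing")
  if (any(pos < 1 | pos > contig_length))
    stop("tree positions outside [1, contig_length] on ", contig)
  if (is.null(block_bounds))
    block_bounds <- matrix(c(0, contig_length), nrow = 1)
  block_bounds <- matrix(as.numeric(block_bounds), ncol = 2)
  if (any(block_bounds[, 2] <= block_bounds[, 1]))
    stop("block bounds must satisfy start < end")
  if (is.null(sampling_interval))
    sampling_interval <- if (length(pos) > 1) median(diff(pos)) else NA_real_
  structure(list(contig = as.character(contig),
                 contig_length = as.numeric(contig_length),
                 trees = trees, positions = pos,
                 sampling_interval = sampling_interval,
                 block_bounds = block_bounds),
            class = "tree_series")
}

#' @export
print.tree_series <- function(x, ...) {
  cat(sprintf("<tree_series> contig %s (%.0f bp): %d trees, interval %s bp, %d block(s)\n",
              x$contig, x$contig_length, length(x$trees),
              format(x$sampling_interval), nrow(x$block_bounds)))
  invisible(x)
}

#' @export
length.tree_series <- function(x) length(x$trees)

#' Read a series of local trees
#'
#' Reads one newick tree per line (branch lengths in generations) and a
#' BED position table (0-based half-open; one record per tree, same
#' order).  Every tree must carry exactly the sample map's leaf set and be
#' ultrametric within `tol`.
#'
#' @param newick_path file with one newick tree per line.
#' @param positions_path BED file: contig, start, end (one row per tree).
#' @param map a `sample_map`.
#' @param contig_length contig length in bp; defaults to the largest block
#'   end (or the last tree position when no blocks file is given).
#' @param block_bounds optional two-column matrix of ARG block bounds
#'   (0-based half-open).
#' @param tol relative ultrametricity tolerance.
#' @return a `tree_series`.
#' @export
read_tree_series <- function(newick_path, positions_path, map,
                             contig_length = NULL, block_bounds = NULL,
                             tol = 1e-6) {
  phys <- ape::read.tree(newick_path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  bed <- read.delim(positions_path, header = FALSE,
                    colClasses = c("character", "numeric", "numeric"))
  names(bed) <- c("contig", "start", "end")
  if (length(phys) != nrow(bed))
    stop(sprintf("tree count (%d) and position records (%d) differ",
                 length(phys), nrow(bed)))
  contig <- unique(bed$contig)
  if (length(contig) != 1L)
    stop("position table spans multiple contigs: ",
         paste(contig, collapse = ", "))
  want <- sort(map$leaf_label)
  trees <- vector("list", length(phys))
  for (i in seq_along(phys)) {
    got <- sort(phys[[i]]$tip.label)
    if (!identical(got, want)) {
      extra <- setdiff(got, want)
      miss <- setdiff(want, got)
      stop(sprintf(
        "tree %d leaf set does not match sample map%s%s", i,
        if (length(extra)) paste0("; unknown leaves: ",
                                  paste(extra, collapse = ", ")) else "",
        if (length(miss)) paste0("; missing leaves: ",
                                 paste(miss, collapse = ", ")) else ""))
    }
    pos <- bed$start[i] + 1  # BED 0-based start -> 1-based bp
    trees[[i]] <- tryCatch(
      local_tree_from_phylo(phys[[i]], position = pos, tol = tol),
      error = function(e) stop(sprintf("tree %d (position %.0f): %s",
                                       i, pos, conditionMessage(e)),
                               call. = FALSE))
  }
  if (is.null(contig_length))
    contig_length <- if (!is.null(block_bounds)) max(block_bounds[, 2])
                     else max(bed$end)
  tree_series(contig, contig_length, trees, block_bounds = block_bounds)
}

#' Write a tree series (newick + BED positions)
#'
#' @param series a `tree_series`.
#' @param newick_path output newick file (one tree per line).
#' @param positions_path output BED file.
#' @return invisibly, a list of the two paths.
#' @export
write_tree_series <- function(series, newick_path, positions_path) {
  writeLines(vapply(series$trees, newick_string, character(1)), newick_path)
  bed <- data.frame(contig = series$contig,
                    start = series$positions - 1,
                    end = series$positions)
  write.table(format(bed, scientific = FALSE, trim = TRUE), positions_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(newick = newick_path, positions = positions_path))
}

#' Discard trees near ARG block boundaries
#'
#' Local-tree topologies near the edges of independently inferred ARG
#' blocks are unreliable; trees whose position lies within `edge_discard`
#' bp of a block start or end are removed.
#'
#' @param series a `tree_series` with block bounds.
#' @param edge_discard bp to trim at each block edge (default 50000).
#' @return the trimmed `tree_series` (block bounds unchanged, so the
#'   operation is idempotent).
#' @export
discard_block_edges <- function(series, edge_discard = 50000) {
  if (edge_discard < 0) stop("edge_discard must be >= 0")
  if (edge_discard == 0) return(series)
  bb <- series$block_bounds
  short <- which(bb[, 2] - bb[, 1] <= 2 * edge_discard)
  if (length(short))
    warning(sprintf("%d block(s) on %s shorter than 2 x edge_discard are fully discarded",
                    length(short), series$contig))
  keep <- rep(FALSE, length(series$positions))
  for (b in seq_len(nrow(bb))) {
    keep <- keep |
      (series$positions >= bb[b, 1] + edge_discard + 1 &
       series$positions <= bb[b, 2] - edge_discard)
  }
  structure(list(contig = series$contig,
                 contig_length = series$contig_length,
                 trees = series$trees[keep],
                 positions = series$positions[keep],
                 sampling_interval = series$sampling_interval,
                 block_bounds = bb),
            class = "tree_series")
}
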