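# Windowed summary statistics on genotype/haplotype matrices: site
# filtering for resequencing panels, nucleotide diversity, Tajima's D,
# Weir-Cockerham FST and Garud's haplotype homozygosity statistics.

#' Construct a genotype matrix
#'
#' @param sites data frame with columns contig, pos (1-based), ref, alt
#'   and optionally mean_depth (per-site mean sequencing depth).
#' @param geno integer matrix (sites x individuals) of alt-allele dosages
#'   in \{0, 1, 2\}, `NA` for missing genotypes.
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno) {
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  if (is.null(sites$mean_depth)) sites$mean_depth <- NA_real_
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites))
    stop("geno must have one row per site")
  if (any(!geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA (biallelic SNPs)")
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ctg)
  }
  structure(list(sites = sites, geno = geno,
                 individuals = colnames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d individuals (%d contig(s))\n",
              nrow(x$sites), ncol(x$geno), length(unique(x$sites$contig))))
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses GT into alt-allele dosages and, when a per-sample DP FORMAT
#' field is present, records per-site mean depth over called genotypes.
#' Multiallelic or non-SNP records are dropped.
#'
#' @param path VCF 4.x file.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  alleles <- gsub("[|/]", "", gt)
  dose[alleles == "00"] <- 0L
  dose[alleles %in% c("01", "10")] <- 1L
  dose[alleles == "11"] <- 2L
  md <- rep(NA_real_, nrow(gt))
  fmt <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                  error = function(e) NULL)
  if (!is.null(fmt))
    md <- rowMeans(fmt[keep, , drop = FALSE], na.rm = TRUE)
  sites <- data.frame(contig = fix[keep, "CHROM"],
                      pos = as.numeric(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      mean_depth = md)
  genotype_matrix(sites, dose)
}

#' Filter SNP sites by presence, depth and minor allele count
#'
#' Retains sites genotyped in at least `min_presence` of individuals,
#' with mean depth inside `depth_range` (inclusive; sites with unknown
#' depth are not filtered on depth), and with a minor allele count of at
#' least `min_mac` over called alleles.  With the default `min_mac = 8`,
#' the rarer allele must be carried by at least 4 diploid individuals
#' even if all carriers are homozygous.
#'
#' @param gm a `genotype_matrix`.
#' @param min_presence minimum called fraction (default 0.8).
#' @param depth_range inclusive mean-depth bounds (default c(2, 50)).
#' @param min_mac minimum minor allele count (default 8).
#' @return the filtered `genotype_matrix` (possibly 0 sites).
#' @export
filter_sites <- function(gm, min_presence = 0.8, depth_range = c(2, 50),
                         min_mac = 8) {
  if (min_presence < 0 || min_presence > 1)
    stop("min_presence must be in [0, 1]")
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2])
    stop("depth_range must be c(lo, hi) with lo <= hi")
  if (min_mac < 0) stop("min_mac must be >= 0")
  called <- !is.na(gm$geno)
  n_ind <- ncol(gm$geno)
  presence_ok <- rowSums(called) / n_ind >= min_presence
  md <- gm$sites$mean_depth
  depth_ok <- is.na(md) | (md >= depth_range[1] & md <= depth_range[2])
  ac <- rowSums(gm$geno, na.rm = TRUE)
  an <- 2L * rowSums(called)
  mac <- pmin(ac, an - ac)
  keep <- presence_ok & depth_ok & mac >= min_mac
  genotype_matrix(gm$sites[keep, , drop = FALSE],
                  gm$geno[keep, , drop = FALSE])
}

# per-site alt counts and called allele numbers for a subset of columns
site_freqs <- function(gm, individuals = NULL) {
  g <- gm$geno
  if (!is.null(individuals)) g <- g[, individuals, drop = FALSE]
  list(ac = rowSums(g, na.rm = TRUE),
       an = 2L * rowSums(!is.na(g)),
       het = rowSums(g == 1L, na.rm = TRUE),
       n_called = rowSums(!is.na(g)))
}

# 0-based half-open window tiling covering all sites on a contig
tile_windows <- function(pos, window_bp, contig_length = NULL) {
  hi <- if (is.null(contig_length)) max(pos) else contig_length
  n_win <- ceiling(hi / window_bp)
  data.frame(start = (seq_len(n_win) - 1) * window_bp,
             end = seq_len(n_win) * window_bp)
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity 2*p*q*n/(n-1) (n = called alleles at
#' the site) summed over the sites of each non-overlapping window and
#' divided by the window length in bp.
#'
#' @param gm a `genotype_matrix` (single contig).
#' @param individuals individuals to include (default all).
#' @param window_bp window size in bp (default 5000).
#' @param contig_length optional, extends the tiling beyond the last SNP.
#' @return data frame: contig, start, end, pi_per_site, n_snps.
#' @export
nucleotide_diversity <- function(gm, individuals = NULL, window_bp = 5000,
                                 contig_length = NULL) {
  ctg <- unique(gm$sites$contig)
  if (length(ctg) != 1L) stop("one contig at a time")
  f <- site_freqs(gm, individuals)
  usable <- f$an >= 2L
  p <- ifelse(usable, f$ac / f$an, 0)
  contrib <- ifelse(usable, 2 * p * (1 - p) * f$an / (f$an - 1L), 0)
  win <- tile_windows(gm$sites$pos, window_bp, contig_length)
  idx <- findInterval(gm$sites$pos - 1, win$start)
  pi_sum <- vapply(seq_len(nrow(win)),
                   function(w) sum(contrib[idx == w]), numeric(1))
  n_seg <- vapply(seq_len(nrow(win)),
                  function(w) sum(idx == w & usable & f$ac > 0 & f$ac < f$an),
                  numeric(1))
  data.frame(contig = ctg, start = win$start, end = win$end,
             pi_per_site = pi_sum / window_bp, n_snps = as.integer(n_seg))
}

# Tajima (1989) normalizing constants for sample size n (called haplotypes)
tajima_constants <- function(n) {
  if (n < 2) stop("Tajima's D needs n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' The 1989 statistic D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1)) per
#' non-overlapping window, where pi is the window sum of per-site
#' unbiased heterozygosity (in count units), S the number of segregating
#' sites, and the constants use the window-median number of called
#' haplotypes (missingness makes per-site sample sizes vary).  Windows
#' with S = 0 yield `NA` (the statistic is undefined there, never 0).
#'
#' @inheritParams nucleotide_diversity
#' @return data frame: contig, start, end, tajimas_d, n_snps.
#' @export
tajimas_d <- function(gm, individuals = NULL, window_bp = 5000,
                      contig_length = NULL) {
  ctg <- unique(gm$sites$contig)
  if (length(ctg) != 1L) stop("one contig at a time")
  f <- site_freqs(gm, individuals)
  seg <- f$an >= 2L & f$ac > 0 & f$ac < f$an
  p <- ifelse(seg, f$ac / pmax(f$an, 1L), 0)
  contrib <- ifelse(seg, 2 * p * (1 - p) * f$an / pmax(f$an - 1L, 1L), 0)
  win <- tile_windows(gm$sites$pos, window_bp, contig_length)
  idx <- findInterval(gm$sites$pos - 1, win$start)
  d <- rep(NA_real_, nrow(win))
  n_seg <- integer(nrow(win))
  for (w in seq_len(nrow(win))) {
    sel <- idx == w & seg
    S <- sum(sel)
    n_seg[w] <- S
    if (S == 0) next
    n_hap <- median(f$an[sel])
    if (n_hap < 2) next
    k <- tajima_constants(n_hap)
    pi_w <- sum(contrib[sel])
    d[w] <- (pi_w - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  data.frame(contig = ctg, start = win$start, end = win$end,
             tajimas_d = d, n_snps = n_seg)
}

# Weir & Cockerham (1984) two-population variance components per site
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Per-site 1984 variance components (a, b, c) combined per window as the
#' ratio of sums sum(a) / sum(a+b+c) (the "weighted" windowed estimator).
#' Sites need at least one called diploid per population and both
#' populations jointly polymorphic sites contribute; windows with a zero
#' denominator yield `NA`.
#'
#' @param gm a `genotype_matrix` (single contig).
#' @param pops data frame with columns `individual_id`, `population`.
#' @param popA,popB the two population names.
#' @param window_bp window size in bp (default 5000; 25000 also reported
#'   in practice).
#' @inheritParams nucleotide_diversity
#' @return data frame: contig, start, end, fst, n_snps.
#' @export
weir_cockerham_fst <- function(gm, pops, popA, popB, window_bp = 5000,
                               contig_length = NULL) {
  ctg <- unique(gm$sites$contig)
  if (length(ctg) != 1L) stop("one contig at a time")
  idsA <- pops$individual_id[pops$population == popA]
  idsB <- pops$individual_id[pops$population == popB]
  if (!length(idsA) || !length(idsB))
    stop("both populations need members in `pops`")
  fA <- site_freqs(gm, intersect(gm$individuals, idsA))
  fB <- site_freqs(gm, intersect(gm$individuals, idsB))
  ok <- fA$n_called >= 1L & fB$n_called >= 1L
  comp <- wc_components(fA$n_called, fA$ac / pmax(fA$an, 1L),
                        fA$het / pmax(fA$n_called, 1L),
                        fB$n_called, fB$ac / pmax(fB$an, 1L),
                        fB$het / pmax(fB$n_called, 1L))
  a <- ifelse(ok, comp$a, 0)
  abc <- ifelse(ok, comp$a + comp$b + comp$c, 0)
  win <- tile_windows(gm$sites$pos, window_bp, contig_length)
  idx <- findInterval(gm$sites$pos - 1, win$start)
  num <- vapply(seq_len(nrow(win)), function(w) sum(a[idx == w]), numeric(1))
  den <- vapply(seq_len(nrow(win)), function(w) sum(abc[idx == w]), numeric(1))
  nsnp <- vapply(seq_len(nrow(win)),
                 function(w) sum(idx == w & ok & abc != 0), numeric(1))
  data.frame(contig = ctg, start = win$start, end = win$end,
             fst = ifelse(den == 0, NA_real_, num / den),
             n_snps = as.integer(nsnp))
}

#' Construct a haplotype matrix
#'
#' @param haplotypes binary matrix (haploid sequences x SNP sites),
#'   entries 0/1.
#' @param positions 1-based bp positions of the SNP columns.
#' @return a `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haplotypes, positions) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != length(positions))
    stop("one position per SNP column required")
  if (any(!haplotypes %in% c(0L, 1L, NA)))
    stop("haplotype entries must be 0/1 (NA only outside H-statistic windows)")
  structure(list(hap = haplotypes, positions = as.numeric(positions)),
            class = "haplotype_matrix")
}

#' Read phased haplotypes from a VCF
#'
#' Requires phased GT (`|` separator); each diploid individual
#' contributes two haploid rows named `<id>_1`, `<id>_2`.
#'
#' @param path VCF with phased genotypes.
#' @return a `haplotype_matrix`.
#' @export
read_haplotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt[!is.na(gt)], fixed = TRUE)))
    stop("haplotype statistics need phased genotypes ('|' separator)")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  hap <- rbind(matrix(a1, nrow = ncol(gt), byrow = TRUE),
               matrix(a2, nrow = ncol(gt), byrow = TRUE))
  ids <- colnames(gt)
  rownames(hap) <- c(paste0(ids, "_1"), paste0(ids, "_2"))
  ord <- as.vector(rbind(seq_along(ids), seq_along(ids) + length(ids)))
  hap <- hap[ord, , drop = FALSE]
  haplotype_matrix(hap, as.numeric(vcfR::getFIX(v)[, "POS"]))
}

# greedy merge of haplotype classes: descending frequency, absorb into the
# most frequent retained class within the distance threshold
merge_hap_classes <- function(block, distance_threshold) {
  key <- apply(block, 1, paste, collapse = "")
  first <- !duplicated(key)
  classes <- block[first, , drop = FALSE]
  freq <- as.integer(table(factor(key, levels = key[first])))
  ord <- order(-freq, seq_along(freq))  # ties by first occurrence
  classes <- classes[ord, , drop = FALSE]
  freq <- freq[ord]
  kept <- integer(0)
  kept_freq <- numeric(0)
  for (i in seq_along(freq)) {
    absorbed <- FALSE
    for (j in seq_along(kept)) {
      if (sum(classes[i, ] != classes[kept[j], ]) <= distance_threshold) {
        kept_freq[j] <- kept_freq[j] + freq[i]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      kept <- c(kept, i)
      kept_freq <- c(kept_freq, freq[i])
    }
  }
  sort(kept_freq / nrow(block), decreasing = TRUE)
}

#' Merged haplotype class frequencies of one SNP window
#'
#' Exposes the class-merging step of [h_statistics]: classes formed by
#' exact identity, then absorbed greedily (descending frequency, ties by
#' first occurrence) into the most frequent retained class within the
#' Hamming distance threshold.
#'
#' @param block binary matrix, haplotypes x SNPs (no missing values).
#' @param distance_threshold Hamming distance merged as one class.
#' @return decreasing numeric vector of merged class frequencies
#'   (sums to 1).
#' @export
hap_class_freqs <- function(block, distance_threshold = 1) {
  block <- as.matrix(block)
  if (anyNA(block)) stop("missing alleles in haplotype block")
  merge_hap_classes(block, distance_threshold)
}

#' Garud's haplotype homozygosity statistics
#'
#' In non-overlapping windows of exactly `window_snps` SNPs (a trailing
#' partial window is dropped), haplotype classes are formed by exact
#' identity and then merged greedily in descending frequency: a class is
#' absorbed by the most frequent retained class within Hamming distance
#' `distance_threshold`.  With merged class frequencies p1 >= p2 >= ...:
#' H1 = sum(p_i^2), H2 = H1 - p1^2, H12 = (p1 + p2)^2 + sum_\{i>=3\} p_i^2.
#' H12 is sensitive to both hard and soft sweeps; H2/H1 helps tell them
#' apart.
#'
#' @param hm a `haplotype_matrix` (no missing alleles).
#' @param window_snps SNPs per window (default 100).
#' @param distance_threshold Hamming distance merged as one class
#'   (default 1).
#' @return data frame: start_pos, end_pos, H1, H2, H12, H2_over_H1,
#'   n_classes (one row per complete window).
#' @export
h_statistics <- function(hm, window_snps = 100, distance_threshold = 1) {
  S <- ncol(hm$hap)
  n_win <- floor(S / window_snps)
  if (n_win == 0L)
    return(data.frame(start_pos = numeric(), end_pos = numeric(),
                      H1 = numeric(), H2 = numeric(), H12 = numeric(),
                      H2_over_H1 = numeric(), n_classes = integer()))
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    cols <- ((w - 1) * window_snps + 1):(w * window_snps)
    block <- hm$hap[, cols, drop = FALSE]
    if (anyNA(block))
      stop("missing alleles in H-statistic window ", w,
           "; filter incomplete haplotypes first")
    p <- merge_hap_classes(block, distance_threshold)
    H1 <- sum(p^2)
    p1 <- p[1]
    p2 <- if (length(p) >= 2) p[2] else 0
    H2 <- H1 - p1^2
    H12 <- (p1 + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
    out[[w]] <- data.frame(start_pos = hm$positions[cols[1]],
                           end_pos = hm$positions[cols[length(cols)]],
                           H1 = H1, H2 = H2, H12 = H12,
                           H2_over_H1 = if (H1 > 0) H2 / H1 else 0,
                           n_classes = length(p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
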