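#!/usr/bin/env Rscript
# Classic windowed summary statistics on the simulated sweep contig's
# phased VCF: site filtering, nucleotide diversity, Tajima's D,
# Weir-Cockerham FST between satellite and source, and Garud's
# H1/H2/H12/H2-H1 for the satellite haplotypes.

suppressPackageStartupMessages(library(argscan))

vcf <- "results/fixtures/sweep.vcf"
if (!file.exists(vcf))
  stop("run analysis/01_simulate_fixtures.R first (missing ", vcf, ")")
map <- read_sample_map("results/fixtures/samples.tsv")
dir.create("results", showWarnings = FALSE)

gm <- read_genotypes(vcf)
message(nrow(gm$sites), " biallelic SNPs on the sweep contig")
kept <- filter_sites(gm)
message(nrow(kept$sites), " SNPs pass the 80% presence / depth 2-50 / MAC>=8 filter")

pops <- data.frame(individual_id = unique(map$individual_id))
pops$population <- map$population[match(pops$individual_id,
                                        map$individual_id)]
sat_ids <- pops$individual_id[pops$population == "satellite"]

pi_d <- merge(
  nucleotide_diversity(gm, individuals = sat_ids, window_bp = 5000,
                       contig_length = 300000),
  tajimas_d(gm, individuals = sat_ids, window_bp = 5000,
            contig_length = 300000))
write.table(pi_d, "results/popgen_pi_tajima.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fst <- weir_cockerham_fst(gm, pops, "satellite", "source",
                          window_bp = 5000, contig_length = 300000)
write.table(fst, "results/popgen_fst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hm <- read_haplotypes(vcf)
sat_rows <- rownames(hm$hap) %in% map$leaf_label[map$population == "satellite"]
hm_sat <- haplotype_matrix(hm$hap[sat_rows, , drop = FALSE], hm$positions)
hstats <- h_statistics(hm_sat, window_snps = 100)
write.table(hstats, "results/popgen_hstats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

near <- function(df, a, b) df[df$start < b & df$end > a, , drop = FALSE]
sweep_win <- near(pi_d, 140000, 160000)
message("satellite diversity around the sweep site (145-155 kb): pi = ",
        signif(mean(sweep_win$pi_per_site), 3), ", Tajima's D = ",
        signif(mean(sweep_win$tajimas_d, na.rm = TRUE), 3))
message("genome-window mean pi = ", signif(mean(pi_d$pi_per_site), 3))
message("mean satellite-source FST = ", signif(mean(fst$fst, na.rm = TRUE), 3))
message("tables written under results/")
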