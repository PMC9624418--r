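#!/usr/bin/env Rscript
# Simulates the study-shaped data bundle: two focal contigs (one carrying
# a completed hard sweep at its center, one neutral) and three neutral
# control contigs under the scaled two-population isolation-with-migration
# model, writing newick tree series, BED positions, sample map, phased
# VCFs and truth labels under results/fixtures/.

suppressPackageStartupMessages(library(argscan))

seed <- 1
out_dir <- "results/fixtures"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating fixture bundle (seed ", seed, ") ...")
fx <- make_fixtures(seed = seed, dir = out_dir)

sizes <- vapply(c(fx$focal, fx$control), length, integer(1))
message("contigs simulated: ",
        paste(vapply(c(fx$focal, fx$control), `[[`, "", "contig"),
              collapse = ", "))
message("trees per contig: ", paste(sizes, collapse = ", "))
message("sweep truth: mode=", fx$truth$sweep$mode,
        " s=", fx$truth$sweep$s,
        " onset=", fx$truth$sweep$onset,
        " sampled DAF=", fx$truth$sweep$daf)
message("bundle written under ", out_dir)
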