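#!/usr/bin/env Rscript

# Stage 1 — simulate the study scenario.
#
# Generates the default synthetic cohort: a 27-individual labelled reference
# panel from three diverged populations (B/S/T analogues, Balding-Nichols
# fst = 0.1), ten query samples whose reported metadata carry a planted
# 9-of-10 label permutation, eight pedigree relatives covering seven of the
# queries, and per-chromosome mapped-read counts for every sequenced sample.
# All downstream stages read the files written here.

suppressPackageStartupMessages(library(trifold))

seed <- 20260920L
out <- "results/scenario"

scn <- make_scenario(scenario_config(), seed = seed)
write_scenario(scn, out)

cat(sprintf("scenario seed %d written to %s/\n", seed, out))
cat(sprintf("  %d panel, %d queries, %d relatives, %d raw SNPs\n",
            length(scn$panel$ids), length(scn$query_samples),
            length(scn$relative_ids), ncol(scn$genotypes$geno)))
cat(sprintf("  planted permutation moves %d of %d query samples\n",
            length(scn$truth$moved), length(scn$query_samples)))
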