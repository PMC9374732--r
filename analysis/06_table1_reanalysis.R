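#!/usr/bin/env Rscript

# Stage 6 — the packaged worked example.
#
# Runs the identity resolution on the ten published orang-utan genomes
# shipped with the package: printed X:Y ratios classified with bands
# calibrated from the published known-male (0.369-0.569) and known-female
# (4.114-5.827) ranges, the corrected species column standing in for the
# supervised-admixture calls, and the published kinship block as hits.
# Reproduces the corrected identity block and the headline discrepancy
# counts (9 samples relabelled, 8 attributed to the wrong individual, 5
# named individuals with contradicted sex).

suppressPackageStartupMessages(library(trifold))

fx <- load_table1()
res <- run_table1(fx)

dir.create("results", showWarnings = FALSE)
out <- cbind(res$corrected,
             flag = res$assignment$flag,
             reported_name = fx$samples$rep_name)
write.table(out, "results/table1_corrected.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out, row.names = FALSE)
print(res$summary)
match_ok <- identical(res$corrected$name, fx$samples$cor_name) &&
  identical(res$corrected$sex, unname(fx$samples$cor_sex)) &&
  identical(res$corrected$species, fx$samples$cor_species)
cat(sprintf("corrected block reproduced for all 10 rows: %s\n", match_ok))
cat("table -> results/table1_corrected.tsv\n")
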