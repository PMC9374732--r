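#!/usr/bin/env Rscript

# Stage 2 — infer genetic sex from X:Y mapped-read ratios.
#
# Reads the idxstats-style tables written by stage 1, calibrates male and
# female ratio bands on the known-sex panel (multiplicative margin 0.25),
# and classifies the ten query samples.  With the default scenario's 1x
# depth and 1% Y mismapping, male ratios sit near 1 and female ratios near
# 100, so the bands are unambiguous.

suppressPackageStartupMessages(library(trifold))

scen_dir <- "results/scenario"
panel <- read.delim(file.path(scen_dir, "panel_labels.tsv"))

ratio_of <- function(id) {
  as.numeric(xy_ratio(read_idxstats(file.path(scen_dir, "idxstats",
                                              paste0(id, ".tsv")))))
}
panel$ratio <- vapply(panel$sample, ratio_of, 0)
thr <- calibrate_thresholds(panel[c("ratio", "sex")], margin = 0.25)
cat(sprintf("calibrated bands: male <= %.3f, female >= %.3f\n",
            thr$male_upper, thr$female_lower))

queries <- sprintf("SAMQ%02d", 1:10)
calls <- classify_sex(vapply(queries, ratio_of, 0), thr, queries)
write.table(calls, "results/sex_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(calls, row.names = FALSE)
cat(sprintf("%d male, %d female, %d undetermined -> results/sex_calls.tsv\n",
            sum(calls$call == "male"), sum(calls$call == "female"),
            sum(calls$call == "undetermined")))
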