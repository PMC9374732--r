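#!/usr/bin/env Rscript

# Stage 5 — tri-fold identity resolution.
#
# Combines the sex calls (stage 2), species calls (stage 3) and kinship
# hits (stage 4): candidate sets by sex/species exclusion, confirmation
# where an observed kinship coefficient resembles the pedigree expectation
# for a known relative (|phi_hat - phi_exp| <= 0.1, phi_hat > 0.02), then
# globally unique assignment by singleton propagation plus forced
# bipartite matching.  The result is compared with the scenario's planted
# permutation and summarized.

suppressPackageStartupMessages(library(trifold))

scen_dir <- "results/scenario"
sex <- read.delim("results/sex_calls.tsv")
anc <- read.delim("results/ancestry_q.tsv")
kin <- read.delim("results/kinship.tsv")
registry <- read.delim(file.path(scen_dir, "registry.tsv"))
links <- read.delim(file.path(scen_dir, "pedigree_links.tsv"))
reported <- read.delim(file.path(scen_dir, "reported_metadata.tsv"))
records <- read.delim(file.path(scen_dir, "records_lab_ids.tsv"))
truth <- unlist(jsonlite::read_json(
  file.path(scen_dir, "truth.json"))$planted_permutation)

evidence <- data.frame(
  biosample = sex$sample,
  sex_call = sex$call,
  species_call = anc$species_call[match(sex$sample, anc$sample)])
cands <- candidate_sets(evidence, registry)
hits <- data.frame(biosample = kin$id1, relative = kin$id2,
                   phi_hat = kin$phi_hat)
confs <- kinship_confirm(cands, hits, links, tau = 0.1, floor = 0.02)
assignment <- assign_identities(cands, confs)
summary <- summarize_discrepancies(assignment, reported, registry, records)

write.table(assignment, "results/assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(summary = unclass(summary),
       recovered = all(!is.na(assignment$assigned)) &&
         all(assignment$assigned == truth[assignment$biosample])),
  "results/resolution_report.json", auto_unbox = TRUE, pretty = TRUE)

print(assignment[c("biosample", "assigned", "flag", "kinship_confirmed")],
      row.names = FALSE)
print(summary)
ok <- all(!is.na(assignment$assigned)) &&
  all(assignment$assigned == truth[assignment$biosample])
cat(sprintf("planted permutation %s recovered -> results/assignment.tsv\n",
            if (ok) "fully" else "NOT"))
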