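#' Scenario configuration
#'
#' Defaults mirror the study design the package was built to re-analyse:
#' a labelled reference panel of 27 individuals (9 per population, three
#' diverged populations "B"/"S"/"T" under Balding-Nichols divergence
#' fst = 0.1), 10 query samples (5 B, 4 S, 1 T), 8 genotyped relatives
#' covering 7 of the queries at first/second/third degree (one relative is
#' a child of two different queries), a planted permutation mislabelling 9
#' of the 10 query samples, and ~10^4 post-filter SNPs.
#'
#' @param n_panel_per_pop Panel samples per population.
#' @param pop_names Population labels (length 3 for the default templates).
#' @param n_snps Target post-filter SNP count.
#' @param n_snps_raw SNPs simulated before MAF filtering.
#' @param freq_lo,freq_hi Ancestral frequency bounds.
#' @param fst Balding-Nichols divergence per population.
#' @param n_swapped Queries whose reported label is moved by the planted
#'   permutation (0 <= n_swapped <= 10; 1 is infeasible, a single sample
#'   cannot be "swapped" with nobody).
#' @param mean_depth,mismap_rate Read-count simulation parameters.
#' @param chrom_lengths Chromosome length table.
#' @param maf_min,window_snps,step_snps,r2_max Variant filter / LD pruning.
#' @param prune Whether the pipeline LD-prunes the scenario genotypes.
#'   Off by default: scenario SNPs are unlinked by construction, and with a
#'   45-sample cohort an r-squared ceiling of 0.1 sits inside the sampling
#'   noise of independent markers (E[r^2] ~ 1/(n-1) ~ 0.023), so pruning
#'   would discard mostly-independent, ancestry-informative SNPs.  Use
#'   \code{\link{add_ld_blocks}} + \code{prune = TRUE} to exercise pruning.
#' @param tau,floor,major_min,margin Resolution thresholds (kinship
#'   tolerance, kinship floor, species majority, sex-band margin).
#' @param em_tol,em_max_iter Stopping rule for the supervised-admixture EM
#'   (log-likelihood units; the ancestry estimates stabilise well before
#'   the likelihood tail flattens).
#' @return List of class \code{scenario_config}.
#' @export
scenario_config <- function(n_panel_per_pop = 9L,
                            pop_names = c("B", "S", "T"),
                            n_snps = 10000L,
                            n_snps_raw = 14000L,
                            freq_lo = 0.05, freq_hi = 0.95,
                            fst = 0.1,
                            n_swapped = 9L,
                            mean_depth = 5, mismap_rate = 0.01,
                            chrom_lengths = default_chrom_lengths(),
                            maf_min = 0.05, window_snps = 50L,
                            step_snps = 10L, r2_max = 0.1,
                            tau = 0.1, floor = 0.02,
                            major_min = 0.85, margin = 0.25,
                            prune = FALSE,
                            em_tol = 0.05, em_max_iter = 400L) {
  stopifnot(length(pop_names) == 3L, n_panel_per_pop >= 1L,
            n_snps_raw >= n_snps)
  structure(as.list(environment()), class = "scenario_config")
}

# fixed query template mirroring the study: name, sex, species index (1=B,
# 2=S, 3=T), and which pedigree template supplies relatives
scenario_query_table <- function(pop_names) {
  data.frame(
    name = sprintf("IND%02d", 1:10),
    sex = c("male", "male", "female", "male", "male",
            "female", "female", "male", "female", "female"),
    species = pop_names[c(1, 1, 1, 2, 2, 2, 3, 1, 1, 2)],
    stringsAsFactors = FALSE)
}

# pedigree templates: 8 relatives over 7 queries; degrees 1,1,1(x2-link),
# 2,2,3 plus a three-relative family (two children and a grandchild)
scenario_pedigrees <- function() {
  list(
    pedigree(c("IND01", "MATE1A", "REL1"),
             c(NA, NA, "IND01"), c(NA, NA, "MATE1A"),
             c("male", "female", "female")),
    pedigree(c("IND02", "IND03", "REL2"),
             c(NA, NA, "IND02"), c(NA, NA, "IND03"),
             c("male", "female", "female")),
    pedigree(c("IND04", "MATE3A", "MID3", "MATE3B", "REL3"),
             c(NA, NA, "IND04", NA, "MATE3B"),
             c(NA, NA, "MATE3A", NA, "MID3"),
             c("male", "female", "female", "male", "male")),
    pedigree(c("IND05", "MATE4A", "MID4", "MATE4B", "REL4"),
             c(NA, NA, "IND05", NA, "MATE4B"),
             c(NA, NA, "MATE4A", NA, "MID4"),
             c("male", "female", "female", "male", "female")),
    pedigree(c("IND06", "MATE5A", "MID5A", "MATE5B", "MID5B", "MATE5C", "REL5"),
             c(NA, NA, "MATE5A", NA, "MATE5B", NA, "MATE5C"),
             c(NA, NA, "IND06", NA, "MID5A", NA, "MID5B"),
             c("female", "male", "female", "male", "female", "male", "male")),
    pedigree(c("IND07", "MATE6A", "REL6", "REL7", "MATE6B", "REL8"),
             c(NA, NA, "MATE6A", "MATE6A", NA, "REL6"),
             c(NA, NA, "IND07", "IND07", NA, "MATE6B"),
             c("female", "male", "male", "female", "female", "female")))
}

# population of every pedigree member = population of its query founder
scenario_ped_pops <- function(pop_names) {
  c(MATE1A = pop_names[1], REL1 = pop_names[1],
    REL2 = pop_names[1],
    MATE3A = pop_names[2], MID3 = pop_names[2], MATE3B = pop_names[2],
    REL3 = pop_names[2],
    MATE4A = pop_names[2], MID4 = pop_names[2], MATE4B = pop_names[2],
    REL4 = pop_names[2],
    MATE5A = pop_names[2], MID5A = pop_names[2], MATE5B = pop_names[2],
    MID5B = pop_names[2], MATE5C = pop_names[2], REL5 = pop_names[2],
    MATE6A = pop_names[3], REL6 = pop_names[3], REL7 = pop_names[3],
    MATE6B = pop_names[3], REL8 = pop_names[3])
}

#' Generate a complete synthetic sample-swap scenario
#'
#' Simulates the reference panel, query individuals, pedigreed relatives,
#' per-chromosome read counts and reported metadata with a planted label
#' permutation, all from one base seed via named substreams.  Reported
#' metadata differ from the truth by exactly the planted permutation: the
#' reported block of a swapped sample is the full identity (lab id,
#' studbook, name, species, sex) of the wrong individual.
#'
#' @param config A \code{\link{scenario_config}}.
#' @param seed Integer base seed.
#' @return List of class \code{swap_scenario}; see elements
#'   \code{genotypes} (combined raw \code{geno_matrix}: panel, query
#'   samples, relatives), \code{panel} (ids, labels, sexes),
#'   \code{query_samples}, \code{relative_ids}, \code{pedigrees},
#'   \code{registry}, \code{links}, \code{chrom_counts}, \code{reported},
#'   \code{records_lab_ids}, \code{truth}.
#' @export
make_scenario <- function(config = scenario_config(), seed = 1L) {
  cf <- config
  pops <- cf$pop_names
  qt <- scenario_query_table(pops)
  if (cf$n_swapped > nrow(qt) || cf$n_swapped == 1L) {
    stop("infeasible n_swapped: need 0 or 2..", nrow(qt))
  }
  anc <- sample_ancestral_freqs(cf$n_snps_raw, cf$freq_lo, cf$freq_hi,
                                substream_seed(seed, "ancestral"))
  F <- balding_nichols_freqs(anc, cf$fst, 3L, substream_seed(seed, "bn"))
  rownames(F) <- pops

  panel_ids <- sprintf("PAN%02d", seq_len(3L * cf$n_panel_per_pop))
  panel_pops <- rep(pops, each = cf$n_panel_per_pop)
  panel_sex <- rep_len(c("male", "female"), length(panel_ids))

  ped_pops <- scenario_ped_pops(pops)
  founder_pop <- c(stats::setNames(panel_pops, panel_ids),
                   stats::setNames(qt$species, qt$name),
                   ped_pops[grep("^MATE", names(ped_pops))])
  Q <- matrix(0, nrow = length(founder_pop), ncol = 3L,
              dimnames = list(names(founder_pop), pops))
  Q[cbind(seq_along(founder_pop), match(founder_pop, pops))] <- 1
  founders <- simulate_genotypes(F, Q, substream_seed(seed, "genotypes"))

  peds <- scenario_pedigrees()
  rel_ids <- sprintf("REL%d", 1:8)
  rel_rows <- list()
  for (i in seq_along(peds)) {
    dropped <- drop_genes(peds[[i]], founders,
                          substream_seed(seed, paste0("drop", i)))
    keep <- intersect(rownames(dropped$geno), rel_ids)
    rel_rows[[i]] <- dropped$geno[keep, , drop = FALSE]
  }
  rel_geno <- do.call(rbind, rel_rows)[rel_ids, , drop = FALSE]

  query_samples <- sprintf("SAMQ%02d", 1:10)
  qg <- founders$geno[qt$name, , drop = FALSE]
  rownames(qg) <- query_samples
  pg <- founders$geno[panel_ids, , drop = FALSE]
  genotypes <- geno_matrix(rbind(pg, qg, rel_geno), founders$variants)

  registry <- data.frame(
    name = qt$name,
    studbook = 100L + seq_len(nrow(qt)),
    lab_id = sprintf("KB%04d", 5000L + seq_len(nrow(qt))),
    sex = qt$sex, species = qt$species, stringsAsFactors = FALSE)

  links <- do.call(rbind, lapply(peds, function(pd) {
    qs <- intersect(pd$members$id, qt$name)
    rl <- intersect(pd$members$id, rel_ids)
    expand.grid(candidate = qs, relative = rl, stringsAsFactors = FALSE)
  }))
  links$phi_exp <- mapply(function(cc, rr) {
    for (pd in peds) {
      if (all(c(cc, rr) %in% pd$members$id)) return(pedigree_phi(pd, cc, rr))
    }
    0
  }, links$candidate, links$relative)
  links <- links[links$phi_exp > 0, , drop = FALSE]
  rownames(links) <- NULL

  counts <- list()
  for (i in seq_along(panel_ids)) {
    counts[[panel_ids[i]]] <- simulate_chrom_counts(
      panel_sex[i], cf$mean_depth, cf$mismap_rate, cf$chrom_lengths,
      substream_seed(seed, paste0("counts_", panel_ids[i])), panel_ids[i])
  }
  for (i in seq_along(query_samples)) {
    counts[[query_samples[i]]] <- simulate_chrom_counts(
      qt$sex[i], cf$mean_depth, cf$mismap_rate, cf$chrom_lengths,
      substream_seed(seed, paste0("counts_", query_samples[i])),
      query_samples[i])
  }

  # planted permutation: a single cycle over n_swapped randomly chosen
  # queries, so every chosen sample's reported label is wrong
  perm <- seq_len(nrow(qt))
  if (cf$n_swapped >= 2L) {
    perm <- with_seed(substream_seed(seed, "permutation"), {
      moved <- sort(sample.int(nrow(qt), cf$n_swapped))
      cyc <- sample(moved)
      p <- perm
      p[cyc] <- cyc[c(seq_along(cyc)[-1L], 1L)]
      p
    })
  }
  rep_idx <- perm
  reported <- data.frame(
    biosample = query_samples,
    lab_id = registry$lab_id[rep_idx],
    studbook = registry$studbook[rep_idx],
    name = registry$name[rep_idx],
    species = registry$species[rep_idx],
    sex = c(male = "M", female = "F")[registry$sex[rep_idx]],
    stringsAsFactors = FALSE)

  rel_q <- matrix(0, nrow = 8L, ncol = 3L,
                  dimnames = list(rel_ids, pops))
  rel_q[cbind(rel_ids, ped_pops[rel_ids])] <- 1
  true_q <- rbind(Q[panel_ids, , drop = FALSE],
                  `rownames<-`(Q[qt$name, , drop = FALSE], query_samples),
                  rel_q)

  truth <- list(
    planted_permutation = stats::setNames(qt$name, query_samples),
    true_sex = stats::setNames(c(qt$sex, panel_sex),
                               c(qt$name, panel_ids)),
    true_species = stats::setNames(qt$species, qt$name),
    true_q = true_q,
    true_freqs = F,
    moved = query_samples[perm != seq_len(nrow(qt))])

  structure(list(
    config = cf, seed = seed,
    genotypes = genotypes,
    panel = list(ids = panel_ids, labels = panel_pops, sexes = panel_sex),
    query_samples = query_samples,
    relative_ids = rel_ids,
    pedigrees = peds,
    registry = registry,
    links = links,
    chrom_counts = counts,
    reported = reported,
    records_lab_ids = data.frame(biosample = query_samples,
                                 lab_id = registry$lab_id,
                                 stringsAsFactors = FALSE),
    truth = truth), class = "swap_scenario")
}

#' @exportS3Method base::print
print.swap_scenario <- function(x, ...) {
  cat(sprintf(paste0("<swap_scenario> %d panel, %d queries (%d mislabelled), ",
                     "%d relatives, %d raw SNPs, seed %d\n"),
              length(x$panel$ids), length(x$query_samples),
              length(x$truth$moved), length(x$relative_ids),
              n_variants(x$genotypes), x$seed))
  invisible(x)
}

#' Write a scenario's inputs to disk in standard formats
#'
#' Genotypes as a minimal VCF, read counts as idxstats-style TSVs,
#' pedigrees as PED-style files, reported metadata and registry as TSV, and
#' the scenario truth as JSON.
#'
#' @param scn A \code{swap_scenario}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(scn$genotypes, file.path(dir, "genotypes.vcf"))
  cdir <- file.path(dir, "idxstats")
  dir.create(cdir, showWarnings = FALSE)
  for (id in names(scn$chrom_counts)) {
    write_idxstats(scn$chrom_counts[[id]], file.path(cdir, paste0(id, ".tsv")))
  }
  for (i in seq_along(scn$pedigrees)) {
    write_pedigree(scn$pedigrees[[i]],
                   file.path(dir, sprintf("pedigree%d.ped", i)),
                   family = sprintf("FAM%d", i))
  }
  utils::write.table(scn$reported, file.path(dir, "reported_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scn$registry, file.path(dir, "registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scn$links, file.path(dir, "pedigree_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scn$records_lab_ids, file.path(dir, "records_lab_ids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = scn$panel$ids,
                                population = scn$panel$labels,
                                sex = scn$panel$sexes),
                     file.path(dir, "panel_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_permutation = as.list(scn$truth$planted_permutation),
         moved = scn$truth$moved,
         true_species = as.list(scn$truth$true_species),
         seed = scn$seed,
         provenance = scenario_provenance(scn)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# machine-readable record of every threshold and seed a run depends on
scenario_provenance <- function(scn) {
  cf <- scn$config
  fields <- c("n_panel_per_pop", "n_snps", "n_snps_raw", "fst", "n_swapped",
              "mean_depth", "mismap_rate", "maf_min", "window_snps",
              "step_snps", "r2_max", "tau", "floor", "major_min", "margin",
              "prune", "em_tol", "em_max_iter")
  c(list(seed = scn$seed), cf[fields])
}
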