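#' Run the full identity-verification pipeline on a synthetic scenario
#'
#' Sexing (X:Y ratios calibrated on the known-sex panel), variant filtering
#' and LD pruning, supervised admixture of queries and relatives against
#' the labelled panel, ancestry-adjusted kinship of every query-relative
#' pair (with the finite-panel covariance correction), and tri-fold
#' identity resolution against the scenario registry.
#'
#' @param scn A \code{\link{make_scenario}} result.
#' @return List with \code{sex_calls}, \code{species_calls}, \code{Q}
#'   (estimated ancestry of queries and relatives), \code{kinship} (the
#'   query x relative estimate table), \code{assignment}, \code{summary},
#'   \code{recovered} (TRUE iff every query sample was assigned its true
#'   individual), and \code{n_snps_used}.
#' @export
run_scenario_pipeline <- function(scn) {
  stopifnot(inherits(scn, "swap_scenario"))
  cf <- scn$config

  # --- sex channel -------------------------------------------------------
  panel_ratios <- vapply(scn$panel$ids, function(id) {
    as.numeric(xy_ratio(scn$chrom_counts[[id]]))
  }, 0)
  thr <- calibrate_thresholds(
    data.frame(ratio = panel_ratios, sex = scn$panel$sexes),
    margin = cf$margin)
  query_ratios <- vapply(scn$query_samples, function(id) {
    as.numeric(xy_ratio(scn$chrom_counts[[id]]))
  }, 0)
  sex_calls <- classify_sex(query_ratios, thr, scn$query_samples)

  # --- genotype preparation ---------------------------------------------
  gm <- filter_variants(scn$genotypes, maf_min = cf$maf_min,
                        require_complete = TRUE, autosomes_only = TRUE)
  if (isTRUE(cf$prune)) {
    gm <- ld_prune(gm, cf$window_snps, cf$step_snps, cf$r2_max)
  }
  if (n_variants(gm) > cf$n_snps) {
    gm <- sample_variants(gm, cf$n_snps, substream_seed(scn$seed, "subset"))
  }

  # --- ancestry channel --------------------------------------------------
  panel_gm <- gm_subset(gm, samples = scn$panel$ids)
  Fhat <- panel_freqs(panel_gm, scn$panel$labels)
  others <- c(scn$query_samples, scn$relative_ids)
  labels <- stats::setNames(rep(NA_character_, n_samples(gm)),
                            rownames(gm$geno))
  labels[scn$panel$ids] <- scn$panel$labels
  fit <- supervised_admixture(gm, labels, tol = cf$em_tol,
                              max_iter = cf$em_max_iter)
  Qhat <- fit$Q[others, , drop = FALSE]
  species_calls <- data.frame(
    sample = others,
    species = vapply(others, function(s) {
      classify_species(Qhat[s, ], fit$pop_names, cf$major_min)
    }, ""), stringsAsFactors = FALSE)

  # --- kinship channel ---------------------------------------------------
  panel_n <- table(scn$panel$labels)[rownames(Fhat)]
  pairs <- expand.grid(id1 = scn$query_samples, id2 = scn$relative_ids,
                       stringsAsFactors = FALSE)
  kin <- kinship_pairs(gm$geno[others, , drop = FALSE], Qhat, Fhat, pairs,
                       panel_n = as.numeric(panel_n))

  # --- resolution --------------------------------------------------------
  evidence <- data.frame(
    biosample = scn$query_samples,
    sex_call = sex_calls$call,
    species_call = species_calls$species[match(scn$query_samples,
                                               species_calls$sample)],
    stringsAsFactors = FALSE)
  cands <- candidate_sets(evidence, scn$registry)
  hits <- data.frame(biosample = kin$id1, relative = kin$id2,
                     phi_hat = kin$phi_hat, stringsAsFactors = FALSE)
  confs <- kinship_confirm(cands, hits, scn$links,
                           tau = cf$tau, floor = cf$floor)
  assignment <- assign_identities(cands, confs)
  summary <- summarize_discrepancies(
    assignment, scn$reported, scn$registry, scn$records_lab_ids)
  recovered <- !anyNA(assignment$assigned) &&
    all(assignment$assigned ==
          scn$truth$planted_permutation[assignment$biosample])

  list(sex_calls = sex_calls, thresholds = thr,
       species_calls = species_calls, Q = Qhat, F = Fhat,
       admixture_fit = fit,
       kinship = kin, evidence = evidence, assignment = assignment,
       summary = summary, recovered = recovered,
       n_snps_used = n_variants(gm),
       provenance = scenario_provenance(scn))
}

#' Re-run the identity resolution on the packaged worked example
#'
#' Uses the fixture's printed X:Y ratios (classified with thresholds
#' calibrated from the printed known-male and known-female ranges), the
#' corrected species column as the ancestry channel's species call, and the
#' printed kinship block as the hit table, then resolves identities against
#' the fixture registry and summarizes discrepancies.
#'
#' @param fixture Output of \code{\link{load_table1}} (loaded if missing).
#' @return List with \code{sex_calls}, \code{assignment}, \code{corrected}
#'   (the reproduced corrected-metadata table), \code{summary} and
#'   \code{thresholds}.
#' @export
run_table1 <- function(fixture = load_table1()) {
  thr <- calibrate_thresholds(fixture$sex_calibration, margin = 0.25)
  sex_calls <- classify_sex(fixture$samples$xy_ratio, thr,
                            fixture$samples$biosample)
  evidence <- data.frame(
    biosample = fixture$samples$biosample,
    sex_call = sex_calls$call,
    species_call = fixture$samples$cor_species,
    stringsAsFactors = FALSE)
  cands <- candidate_sets(evidence, fixture$registry)
  hits <- data.frame(biosample = fixture$kinship$biosample,
                     relative = as.character(fixture$kinship$relative_isb),
                     phi_hat = fixture$kinship$phi_hat,
                     stringsAsFactors = FALSE)
  links <- data.frame(candidate = fixture$links$candidate,
                      relative = as.character(fixture$links$relative),
                      phi_exp = fixture$links$phi_exp,
                      stringsAsFactors = FALSE)
  confs <- kinship_confirm(cands, hits, links, tau = 0.1, floor = 0.02)
  assignment <- assign_identities(cands, confs)
  reg <- fixture$registry
  idx <- match(assignment$assigned, reg$name)
  corrected <- data.frame(
    biosample = assignment$biosample,
    lab_id = fixture$records_lab_ids$lab_id[
      match(assignment$biosample, fixture$records_lab_ids$biosample)],
    isb = reg$isb[idx],
    name = reg$name[idx],
    species = reg$species[idx],
    sex = c(male = "M", female = "F")[reg$sex[idx]],
    stringsAsFactors = FALSE)
  reported <- data.frame(biosample = fixture$samples$biosample,
                         lab_id = fixture$samples$rep_lab_id,
                         name = fixture$samples$rep_name,
                         sex = fixture$samples$rep_sex,
                         stringsAsFactors = FALSE)
  summary <- summarize_discrepancies(assignment, reported, fixture$registry,
                                     fixture$records_lab_ids)
  list(sex_calls = sex_calls, thresholds = thr, assignment = assignment,
       corrected = corrected, summary = summary)
}

#' Kinship estimator calibration study
#'
#' Repeatedly simulates a four-member chain pedigree (founder A, child B,
#' grandchild C) plus an unrelated individual U from one population under
#' Balding-Nichols divergence, and estimates kinship and IBD-state
#' proportions with the generator's true individual-specific frequencies,
#' isolating the estimator from panel-estimation error.
#'
#' @param n_rep Replicates.
#' @param n_snps SNPs per replicate.
#' @param fst Balding-Nichols divergence.
#' @param seed Integer base seed.
#' @return Data frame with one row per replicate: \code{phi_po},
#'   \code{phi_gp}, \code{phi_un} (parent-offspring, grandparent,
#'   unrelated) and \code{d0_po}, \code{d1_po}, \code{d2_po}.
#' @export
kinship_calibration_study <- function(n_rep = 20L, n_snps = 10000L,
                                      fst = 0.1, seed = 1L) {
  ped <- pedigree(c("A", "MB", "B", "MC", "C"),
                  c(NA, NA, "A", NA, "MC"),
                  c(NA, NA, "MB", NA, "B"),
                  c("male", "female", "female", "male", "male"))
  out <- data.frame(phi_po = numeric(n_rep), phi_gp = numeric(n_rep),
                    phi_un = numeric(n_rep), d0_po = numeric(n_rep),
                    d1_po = numeric(n_rep), d2_po = numeric(n_rep))
  for (r in seq_len(n_rep)) {
    rs <- substream_seed(seed, paste0("calib", r))
    anc <- sample_ancestral_freqs(n_snps, 0.05, 0.95,
                                  substream_seed(rs, "anc"))
    F <- balding_nichols_freqs(anc, fst, 3L, substream_seed(rs, "bn"))
    Q <- matrix(0, 4L, 3L, dimnames = list(c("A", "MB", "MC", "U"), NULL))
    Q[, 1L] <- 1
    founders <- simulate_genotypes(F, Q, substream_seed(rs, "geno"))
    dropped <- drop_genes(ped, founders, substream_seed(rs, "drop"))
    mu <- clamp_freq(F[1L, ])          # true pop-1 frequencies for everyone
    g <- function(id) if (id == "U") founders$geno["U", ] else dropped$geno[id, ]
    out$phi_po[r] <- kinship_phi(g("A"), g("B"), mu, mu)
    out$phi_gp[r] <- kinship_phi(g("A"), g("C"), mu, mu)
    out$phi_un[r] <- kinship_phi(g("A"), g("U"), mu, mu)
    d <- ibd_deltas(g("A"), g("B"), mu, mu)
    out[r, c("d0_po", "d1_po", "d2_po")] <- as.list(unname(d))
  }
  out
}
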