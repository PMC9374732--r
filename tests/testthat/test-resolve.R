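toy_registry <- function() {
  data.frame(
    name = c("Ann", "Bea", "Cal", "Dov"),
    sex = c("female", "female", "male", "male"),
    species = c("S", "T", "S", "S"),
    stringsAsFactors = FALSE)
}

test_that("sex/species exclusion builds the right candidate sets", {
  ev <- data.frame(
    biosample = c("s1", "s2", "s3", "s4"),
    sex_call = c("female", "male", "undetermined", "female"),
    species_call = c("T", "B", "S", "admixed"),
    stringsAsFactors = FALSE)
  cs <- candidate_sets(ev, toy_registry())
  expect_identical(cs$s1, "Bea")                 # singleton
  expect_identical(cs$s2, character(0))          # exclusion empties the set
  expect_identical(cs$s3, c("Ann", "Cal", "Dov"))  # undetermined matches both
  expect_identical(cs$s4, character(0))          # admixed matches none
})

test_that("kinship confirmation applies floor, tolerance and ambiguity rules", {
  cands <- list(s1 = c("Ann", "Cal"), s2 = c("Ann", "Cal"))
  links <- data.frame(candidate = c("Ann", "Cal"),
                      relative = c("r1", "r2"),
                      phi_exp = c(0.25, 0.125), stringsAsFactors = FALSE)
  hits <- data.frame(biosample = "s1", relative = "r1", phi_hat = 0.246,
                     stringsAsFactors = FALSE)
  cf <- kinship_confirm(cands, hits, links)
  expect_identical(cf$s1$confirmed, "Ann")       # 0.246 vs 0.25 within tau
  expect_identical(cf$s2$confirmed, NA_character_)

  # below the background floor nothing confirms
  low <- data.frame(biosample = "s1", relative = "r1", phi_hat = 0.01)
  expect_identical(kinship_confirm(cands, low, links)$s1$confirmed,
                   NA_character_)
  # too far from expectation does not confirm
  off <- data.frame(biosample = "s1", relative = "r1", phi_hat = 0.55)
  expect_identical(kinship_confirm(cands, off, links)$s1$confirmed,
                   NA_character_)
  # hits supporting two different candidates cancel out
  both <- data.frame(biosample = c("s1", "s1"), relative = c("r1", "r2"),
                     phi_hat = c(0.24, 0.12))
  amb <- kinship_confirm(cands, both, links)$s1
  expect_identical(amb$confirmed, NA_character_)
  expect_true(amb$ambiguous)
  expect_setequal(amb$supported, c("Ann", "Cal"))

  bad <- data.frame(biosample = "s1", relative = "ghost", phi_hat = 0.2)
  expect_error(kinship_confirm(cands, bad, links), "unknown relative")
})

test_that("identity assignment enforces uniqueness and flags failures", {
  # s1 confirmed; s2's only survivor is forced once Ann is taken
  cands <- list(s1 = c("Ann", "Bea"), s2 = c("Ann", "Bea"))
  confs <- list(s1 = list(confirmed = "Ann", supported = "Ann",
                          ambiguous = FALSE),
                s2 = list(confirmed = NA_character_, supported = character(0),
                          ambiguous = FALSE))
  out <- assign_identities(cands, confs)
  expect_identical(out$assigned, c("Ann", "Bea"))
  expect_false(anyDuplicated(na.omit(out$assigned)) > 0)

  # genuinely ambiguous pair stays unresolved
  amb <- assign_identities(list(s1 = c("Ann", "Bea"), s2 = c("Ann", "Bea")))
  expect_true(all(is.na(amb$assigned)))
  expect_identical(amb$flag, c("unresolved", "unresolved"))

  # records channel contradicting the exclusion set is a conflict
  rec <- data.frame(biosample = "s1", records_candidate = "Cal")
  con <- assign_identities(list(s1 = c("Ann", "Bea")), records = rec)
  expect_identical(con$flag, "conflict")
  expect_true(is.na(con$assigned))

  # matching still covers structured multi-sample cases
  cands3 <- list(a = c("Ann", "Bea"), b = "Bea", c = c("Cal", "Dov"))
  out3 <- assign_identities(cands3)
  expect_identical(out3$assigned[out3$biosample == "a"], "Ann")
  expect_identical(out3$assigned[out3$biosample == "b"], "Bea")
  expect_true(is.na(out3$assigned[out3$biosample == "c"]))
})

test_that("discrepancy summary counts relabels, misattributions and sexes", {
  reg <- toy_registry()
  reported <- data.frame(
    biosample = c("s1", "s2"),
    lab_id = c("L1", "L2"),
    name = c("Ann", "Bea"),
    sex = c("female", "male"),      # Bea is female in the registry
    stringsAsFactors = FALSE)
  ident <- data.frame(biosample = c("s1", "s2"),
                      assigned = c("Ann", "Bea"),
                      flag = "partial", stringsAsFactors = FALSE)
  rec <- data.frame(biosample = c("s1", "s2"), lab_id = c("L1", "L2"))
  s0 <- summarize_discrepancies(ident, reported, reg, rec)
  expect_identical(s0$n_relabelled, 0L)
  expect_identical(s0$n_misattributed, 0L)
  expect_identical(s0$n_sex_contradicted, 1L)   # Bea reported male

  # a planted two-sample swap relabels and misattributes both
  swapped <- data.frame(biosample = c("s1", "s2"),
                        assigned = c("Bea", "Ann"),
                        flag = "partial", stringsAsFactors = FALSE)
  s2 <- summarize_discrepancies(swapped, reported, reg, rec)
  expect_identical(s2$n_relabelled, 2L)
  expect_identical(s2$n_misattributed, 2L)

  # an unverifiable lab id counts as a relabel without misattribution
  rec_na <- data.frame(biosample = c("s1", "s2"), lab_id = c(NA, "L2"))
  s1 <- summarize_discrepancies(ident, reported, reg, rec_na)
  expect_identical(s1$n_relabelled, 1L)
  expect_identical(s1$n_misattributed, 0L)
})

test_that("adding the kinship channel never removes a correct assignment", {
  cfg <- scenario_config(n_snps = 4000L, n_snps_raw = 6000L,
                         em_tol = 0.05, em_max_iter = 300L)
  for (seed in 1:5) {
    scn <- make_scenario(cfg, seed = 1000L + seed)
    res <- run_scenario_pipeline(scn)
    cands <- candidate_sets(res$evidence, scn$registry)
    base <- assign_identities(cands)                 # sex/species only
    full <- res$assignment
    truth <- scn$truth$planted_permutation
    for (i in seq_len(nrow(base))) {
      s <- base$biosample[i]
      if (!is.na(base$assigned[i]) && base$assigned[i] == truth[[s]]) {
        expect_identical(full$assigned[full$biosample == s], base$assigned[i])
      }
    }
    expect_false(anyDuplicated(na.omit(full$assigned)) > 0)
  }
})
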