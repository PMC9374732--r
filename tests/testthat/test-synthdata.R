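test_that("ancestral frequency sampling honours bounds, seeds and edge cases", {
  expect_identical(sample_ancestral_freqs(0, 0.1, 0.9, 1), numeric(0))
  expect_error(sample_ancestral_freqs(-1), "non-negative")
  expect_equal(sample_ancestral_freqs(5, 0.5, 0.5, 1), rep(0.5, 5))
  p <- sample_ancestral_freqs(1e4, 0.05, 0.95, 7)
  expect_true(all(p >= 0.05 & p <= 0.95))
  # LLN: mean of U(0.05, 0.95) is 0.5, SE = 0.9/sqrt(12 * n)
  se <- 0.9 / sqrt(12 * 1e4)
  expect_lt(abs(mean(p) - 0.5), 3 * se)
  expect_identical(p, sample_ancestral_freqs(1e4, 0.05, 0.95, 7))
})

test_that("Balding-Nichols frequencies have the right centre and divergence", {
  expect_error(balding_nichols_freqs(0.5, 0, 2), "fst")
  expect_error(balding_nichols_freqs(0.5, 1, 2), "fst")
  p <- sample_ancestral_freqs(2000, 0.2, 0.8, 3)
  # near-zero divergence collapses every population onto the ancestral freq
  f0 <- balding_nichols_freqs(p, 1e-6, 3, 4)
  expect_lt(max(abs(sweep(f0, 2, p))), 0.01)
  # Beta mean equals the ancestral frequency
  f <- balding_nichols_freqs(rep(0.4, 1e4), 0.1, 2, 5)
  expect_lt(abs(mean(f[1, ]) - 0.4), 0.01)
  # Hudson-estimator oracle recovers the target Fst
  p2 <- sample_ancestral_freqs(1e4, 0.1, 0.9, 6)
  f2 <- balding_nichols_freqs(p2, 0.1, 2, 7)
  expect_lt(abs(hudson_fst(f2[1, ], f2[2, ]) - 0.1), 0.02)
})

test_that("genotype simulation follows the admixture model", {
  F1 <- matrix(1, 1, 50)
  g <- simulate_genotypes(F1, matrix(1, 1, 1), 1)
  expect_true(all(g$geno == 2L))
  expect_error(simulate_genotypes(matrix(0.5, 2, 10), matrix(1, 1, 1)),
               "populations")
  expect_error(simulate_genotypes(matrix(0.5, 1, 10), matrix(2, 1, 1)),
               "simplex")
  p <- sample_ancestral_freqs(1e4, 0.1, 0.9, 8)
  F <- balding_nichols_freqs(p, 0.1, 2, 9)
  q <- c(0.3, 0.7)
  gm <- simulate_genotypes(F, rbind(q), 10)
  expect_equal(mean(gm$geno), 2 * sum(q * rowMeans(F)), tolerance = 0.01)
  expect_identical(simulate_genotypes(F, rbind(q), 10)$geno, gm$geno)
})

test_that("gene dropping transmits alleles with the right relatedness", {
  ped <- chain_pedigree()
  v <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "C")
  hom <- geno_matrix(matrix(2L, 4, 3, dimnames = list(c("A", "MB", "MC", "MD"),
                                                      NULL)), v)
  dropped <- drop_genes(ped, hom, 1)
  expect_true(all(dropped$geno == 2L))

  p <- sample_ancestral_freqs(1e5, 0.1, 0.9, 11)
  F <- rbind(p)
  founders <- simulate_genotypes(
    F, matrix(1, 4, 1, dimnames = list(c("A", "MB", "MC", "MD"), NULL)), 12)
  d <- drop_genes(ped, founders, 13)
  expect_equal(empirical_kinship(d$geno["A", ], d$geno["B", ], p), 0.25,
               tolerance = 0.02)
  expect_equal(empirical_kinship(d$geno["A", ], d$geno["C", ], p), 0.125,
               tolerance = 0.02)
  expect_equal(empirical_kinship(d$geno["A", ], d$geno["D", ], p), 0.0625,
               tolerance = 0.02)

  expect_error(drop_genes(ped, gm_subset(founders, samples = "A"), 1),
               "missing founder")
  expect_error(pedigree("X", "onlydad", NA), "both parents")
})

test_that("chromosome count simulation separates the sexes", {
  expect_error(simulate_chrom_counts("other", 5), "unknown sex")
  cf <- simulate_chrom_counts("female", 5, mismap_rate = 0, seed = 1)
  expect_identical(cf$mapped[cf$chrom == "Y"], 0L)
  cm <- simulate_chrom_counts("male", 30, seed = 2)
  expect_equal(as.numeric(xy_ratio(cm)), 1, tolerance = 0.02)
  rf <- replicate(20, {
    s <- sample.int(1e6, 1)
    as.numeric(xy_ratio(simulate_chrom_counts("female", 1, 0.01, seed = s)))
  })
  rm_ <- replicate(20, {
    s <- sample.int(1e6, 1)
    as.numeric(xy_ratio(simulate_chrom_counts("male", 1, 0.01, seed = s)))
  })
  expect_gt(min(rf) / max(rm_), 5)
})

test_that("scenario generation plants exactly the configured permutation", {
  cfg <- small_config(n_swapped = 0L)
  scn <- make_scenario(cfg, seed = 3)
  # identity permutation: reported metadata equal the truth
  expect_identical(scn$reported$name, scn$registry$name)
  expect_identical(scn$reported$lab_id, scn$registry$lab_id)
  expect_length(scn$truth$moved, 0)

  scn9 <- make_scenario(small_config(), seed = 3)
  expect_length(scn9$panel$ids, 27)
  expect_length(scn9$query_samples, 10)
  expect_length(scn9$relative_ids, 8)
  expect_length(scn9$truth$moved, 9)
  # round trip: reported block is the registry row of the permuted identity
  perm <- match(scn9$reported$name, scn9$registry$name)
  expect_identical(scn9$reported$studbook, scn9$registry$studbook[perm])
  expect_identical(scn9$reported$species, scn9$registry$species[perm])
  # the unmoved sample reports its own individual
  truth <- scn9$truth$planted_permutation
  moved <- scn9$reported$name != truth[scn9$reported$biosample]
  expect_identical(sum(moved), 9L)

  expect_error(make_scenario(small_config(n_swapped = 11L)), "infeasible")
  expect_error(make_scenario(small_config(n_swapped = 1L)), "infeasible")
})

test_that("scenario generation is byte-identical under one seed", {
  a <- make_scenario(small_config(), seed = 5)
  b <- make_scenario(small_config(), seed = 5)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$reported, b$reported)
  expect_identical(lapply(a$chrom_counts, `[[`, "mapped"),
                   lapply(b$chrom_counts, `[[`, "mapped"))
})

test_that("gene-dropped scenario relatives match pedigree kinship", {
  # pedigree-phi agreement of empirical kinship for every query-relative
  # link in one scenario at elevated SNP count
  cfg <- scenario_config(n_snps = 5000L, n_snps_raw = 7000L)
  scn <- make_scenario(cfg, seed = 11)
  F <- scn$truth$true_freqs
  truth_name <- scn$truth$planted_permutation
  for (r in seq_len(nrow(scn$links))) {
    cand <- scn$links$candidate[r]
    rel <- scn$links$relative[r]
    samp <- names(truth_name)[truth_name == cand]
    pop <- scn$registry$species[scn$registry$name == cand]
    p <- F[pop, ]
    phi <- empirical_kinship(scn$genotypes$geno[samp, ],
                             scn$genotypes$geno[rel, ], p)
    expect_lt(abs(phi - scn$links$phi_exp[r]), 0.035)
  }
})
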