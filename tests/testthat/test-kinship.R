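test_that("individual-specific frequencies are the q-weighted mixture", {
  expect_equal(individual_freqs(c(1, 0), rbind(c(0.3, 0.9), c(0.7, 0.1))),
               c(0.3, 0.9))
  expect_equal(individual_freqs(c(0.5, 0.5), rbind(0.2, 0.6)), 0.4)
  F5 <- matrix(0.5, 2, 4)
  expect_equal(individual_freqs(c(0.3, 0.7), F5), rep(0.5, 4))
  expect_error(individual_freqs(c(1, 0, 0), F5), "populations")
})

test_that("kinship estimator hits the closed-form limits", {
  p <- sample_ancestral_freqs(1e4, 0.1, 0.9, 51)
  F <- rbind(p)
  ids <- c("A", "MB", "MC", "U")
  founders <- simulate_genotypes(F, matrix(1, 4, 1, dimnames = list(ids, NULL)), 52)
  ped <- pedigree(c("A", "MB", "B", "MC", "C"),
                  c(NA, NA, "A", NA, "MC"), c(NA, NA, "MB", NA, "B"))
  d <- drop_genes(ped, founders, 53)
  mu <- clamp_freq(p)
  g <- function(id) if (id == "U") founders$geno["U", ] else d$geno[id, ]
  expect_equal(kinship_phi(g("A"), g("A"), mu, mu), 0.5, tolerance = 0.02)
  expect_lt(abs(kinship_phi(g("A"), g("U"), mu, mu)), 0.02)
  expect_equal(kinship_phi(g("A"), g("B"), mu, mu), 0.25, tolerance = 0.02)
  expect_error(kinship_phi(c(1, NA), c(1, 1), c(0.5, 0.5), c(0.5, 0.5)),
               "complete")
})

test_that("IBD-state least squares recovers canonical relationships", {
  p <- sample_ancestral_freqs(1e4, 0.1, 0.9, 61)
  F <- rbind(p)
  ids <- c("A", "MB", "U")
  founders <- simulate_genotypes(F, matrix(1, 3, 1, dimnames = list(ids, NULL)), 62)
  ped <- pedigree(c("A", "MB", "B"), c(NA, NA, "A"), c(NA, NA, "MB"))
  d <- drop_genes(ped, founders, 63)
  mu <- clamp_freq(p)

  dup <- ibd_deltas(d$geno["A", ], d$geno["A", ], mu, mu)
  expect_gt(dup[["delta2"]], 0.95)
  po <- ibd_deltas(d$geno["A", ], d$geno["B", ], mu, mu)
  expect_equal(unname(po), c(0, 1, 0), tolerance = 0.05)
  un <- ibd_deltas(d$geno["A", ], founders$geno["U", ], mu, mu)
  expect_gt(un[["delta0"]], 0.9)
  for (dd in list(dup, po, un)) {
    expect_true(all(dd >= 0))
    expect_equal(sum(dd), 1, tolerance = 1e-9)
  }
  mu0 <- rep(1e-6, 100)
  expect_error(ibd_deltas(rep(0L, 100), rep(0L, 100), mu0, mu0),
               "degenerate|collinear")
})

test_that("recursive pedigree kinship matches the classical values", {
  ped <- chain_pedigree()
  expect_identical(pedigree_phi(ped, "A", "B"), 0.25)
  expect_identical(pedigree_phi(ped, "A", "C"), 0.125)
  expect_identical(pedigree_phi(ped, "A", "D"), 0.0625)
  expect_identical(pedigree_phi(ped, "A", "A"), 0.5)
  expect_identical(pedigree_phi(ped, "A", "MC"), 0)
  sib <- full_sib_pedigree()
  expect_identical(pedigree_phi(sib, "S1", "S2"), 0.25)
  expect_error(pedigree_phi(ped, "A", "nobody"), "unknown")
})

test_that("inheritance-vector enumeration yields exact IBD probabilities", {
  ped <- chain_pedigree()
  expect_equal(unname(pedigree_deltas(ped, "A", "B")), c(0, 1, 0))
  expect_equal(unname(pedigree_deltas(ped, "A", "C")), c(0.5, 0.5, 0))
  expect_equal(unname(pedigree_deltas(ped, "A", "D")), c(0.75, 0.25, 0))
  sib <- full_sib_pedigree()
  expect_equal(unname(pedigree_deltas(sib, "S1", "S2")), c(0.25, 0.5, 0.25))

  # consistency with the kinship recursion for every pair in both pedigrees
  for (pd in list(ped, sib)) {
    ids <- pd$members$id
    prs <- t(combn(ids, 2))
    for (r in seq_len(nrow(prs))) {
      dd <- pedigree_deltas(pd, prs[r, 1], prs[r, 2])
      expect_identical(pedigree_phi(pd, prs[r, 1], prs[r, 2]),
                       dd[["delta1"]] / 4 + dd[["delta2"]] / 2)
    }
  }

  # the seeded Monte Carlo fallback agrees with exact enumeration
  mc <- pedigree_deltas(ped, "A", "C", method = "monte_carlo",
                        n_draws = 2e5, seed = 4)
  expect_lt(max(abs(mc - pedigree_deltas(ped, "A", "C"))), 0.003)

  # inbred pairs are out of scope
  inb <- pedigree(c("A", "B", "C", "D"),
                  c(NA, NA, "A", "A"), c(NA, NA, "B", "C"))
  expect_error(pedigree_deltas(inb, "A", "D"), "inbred")
})

test_that("expected tables carry kinship, IBD states and degree bands", {
  ped <- chain_pedigree()
  tab <- expected_table(ped, rbind(c("A", "B"), c("A", "C"), c("A", "MD")))
  expect_equal(tab$phi_exp, c(0.25, 0.125, 0))
  expect_identical(tab$degree, c("1", "2", "unrelated"))
  expect_equal(tab$delta1, c(1, 0.5, 0))
})
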