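# Independent oracles and shared fixtures for the test suite.

# Hudson's Fst estimator (ratio of averages) from two populations' allele
# frequencies; used as an external check on the Balding-Nichols generator.
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Plain moment kinship with known true frequencies (no ancestry adjustment
# needed for a single population); oracle for gene-dropped pedigrees.
empirical_kinship <- function(g_i, g_j, p) {
  sum((g_i - 2 * p) * (g_j - 2 * p)) / (4 * sum(p * (1 - p)))
}

# small, fast scenario for structural (non-accuracy) tests
small_config <- function(...) {
  scenario_config(n_snps = 800L, n_snps_raw = 1200L,
                  em_tol = 0.1, em_max_iter = 150L, ...)
}

# three-generation chain A -> B -> C -> D with unrelated mates
chain_pedigree <- function() {
  pedigree(c("A", "MB", "B", "MC", "C", "MD", "D"),
           c(NA, NA, "A", NA, "MC", NA, "MD"),
           c(NA, NA, "MB", NA, "B", NA, "C"),
           c("male", "female", "female", "male", "male", "male", "female"))
}

full_sib_pedigree <- function() {
  pedigree(c("F", "M", "S1", "S2"),
           c(NA, NA, "F", "F"), c(NA, NA, "M", "M"),
           c("male", "female", "male", "female"))
}
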