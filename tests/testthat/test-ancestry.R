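mk_gm <- function(geno, chrom = "1") {
  geno <- as.matrix(geno)
  geno_matrix(geno, data.frame(chrom = rep_len(chrom, ncol(geno)),
                               pos = seq_len(ncol(geno)) * 100L,
                               ref = "A", alt = "C"))
}

test_that("variant filtering applies MAF, completeness and autosome rules", {
  g <- matrix(0L, nrow = 10, ncol = 4)
  g[, 2] <- c(rep(2L, 9), 1L)          # alt count 19/20 -> MAF exactly 0.05
  g[, 3] <- rep(1L, 10)                # MAF 0.5
  g[, 4] <- rep(1L, 10); g[1, 4] <- NA # one missing call
  gm <- mk_gm(g)
  out <- filter_variants(gm, maf_min = 0.05)
  expect_identical(out$variants$pos, c(200L, 300L))   # monomorphic + missing dropped
  out2 <- filter_variants(gm, maf_min = 0.05, require_complete = FALSE)
  expect_identical(out2$variants$pos, c(200L, 300L, 400L))

  gx <- mk_gm(matrix(1L, 4, 3), chrom = c("1", "chrX", "MT"))
  expect_identical(filter_variants(gx)$variants$chrom, "1")
  expect_identical(nrow(filter_variants(gx, autosomes_only = FALSE)$variants), 3L)

  gmulti <- mk_gm(matrix(1L, 4, 2))
  gmulti$variants$alt[2] <- "C,T"
  expect_identical(filter_variants(gmulti)$variants$alt, "C")
  expect_warning(filter_variants(mk_gm(matrix(0L, 4, 2))), "no variants")
})

test_that("variant sampling is uniform, ordered and reproducible", {
  gm <- mk_gm(matrix(rbinom(20 * 50, 2, 0.5), nrow = 20))
  expect_identical(sample_variants(gm, 50), gm)
  expect_identical(n_variants(sample_variants(gm, 0)), 0L)
  expect_error(sample_variants(gm, 51), "cannot sample")
  a <- sample_variants(gm, 10, seed = 2)
  expect_identical(a$variants$pos, sort(a$variants$pos))
  expect_identical(a$geno, sample_variants(gm, 10, seed = 2)$geno)
})

test_that("LD pruning removes exactly the correlated members", {
  set.seed(1)
  base <- rbinom(60, 2, 0.5)
  # three SNPs with pairwise r2 = (1, 0, 0): duplicate + independent
  g3 <- cbind(base, base, rbinom(60, 2, 0.5))
  pruned <- ld_prune(mk_gm(g3), window_snps = 3, step_snps = 1, r2_max = 0.1)
  expect_identical(n_variants(pruned), 2L)

  # independent SNPs survive untouched once no pair breaches the ceiling
  set.seed(2)
  gi <- matrix(rbinom(200 * 30, 2, 0.5), nrow = 200)
  r2 <- cor(gi)^2; diag(r2) <- 0
  gi <- gi[, colSums(r2 > 0.5) == 0, drop = FALSE]  # keep comfortably-independent set
  kept <- ld_prune(mk_gm(gi), window_snps = 10, step_snps = 5, r2_max = 0.5)
  expect_identical(n_variants(kept), ncol(gi))

  # rescan property on deliberately correlated blocks
  p <- sample_ancestral_freqs(300, 0.2, 0.8, 3)
  gm <- simulate_genotypes(rbind(p), matrix(1, 40, 1), 4)
  gmb <- add_ld_blocks(gm, block_every = 5L, copies = 2L, noise = 0.05, seed = 5)
  pr <- ld_prune(gmb, window_snps = 20, step_snps = 5, r2_max = 0.2)
  g <- pr$geno
  for (s in seq(1, n_variants(pr), by = 5)) {
    win <- s:min(s + 19, n_variants(pr))
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(g[, win])^2)
    diag(r2) <- 0
    r2[!is.finite(r2)] <- 0
    expect_lte(max(r2), 0.2)
  }
})

test_that("panel frequencies use the half-count pseudocount", {
  gm <- mk_gm(rbind(c(2L, 0L), c(2L, 0L)))
  f <- panel_freqs(gm, c("p1", "p1"))
  expect_equal(unname(f[1, 1]), 4.5 / 5)
  expect_equal(unname(f[1, 2]), 0.5 / 5)
  f1 <- panel_freqs(mk_gm(matrix(1L, 1, 1)), "p1")
  expect_equal(unname(f1[1, 1]), 1.5 / 3)
  big <- panel_freqs(mk_gm(matrix(0L, 50, 1)), rep("p1", 50))
  expect_gt(big[1, 1], 0)          # clamped, never exactly zero
  expect_lt(big[1, 1], 0.01)
  expect_error(panel_freqs(gm, c("p1", NA)), "label")
})

test_that("probe QC treats each published threshold as an exclusion", {
  base <- data.frame(probe_id = "p", meanR_AA = 0.5, meanR_AB = 0.5,
                     meanR_BB = 0.5, Cluster_Sep = 0.5, meanTHETA_AA = 0.05,
                     meanTHETA_AB = 0.5, meanTHETA_BB = 0.95,
                     devTHETA_AA = 0.01, devTHETA_AB = 0.05,
                     devTHETA_BB = 0.01, GenTrain_Score = 0.8)
  expect_identical(as.character(filter_probes(base)), "p")  # violates nothing
  bad <- function(field, value) {
    d <- base; d[[field]] <- value; d$probe_id <- "q"
    as.character(filter_probes(rbind(base, d)))
  }
  expect_identical(bad("meanR_AB", 0.1), "p")
  expect_identical(bad("GenTrain_Score", 0.69), "p")  # boundary of "< 0.7"
  expect_identical(bad("meanTHETA_AB", 0.25), "p")    # outside [0.3, 0.7]
  expect_identical(bad("meanTHETA_AB", 0.75), "p")
  expect_identical(bad("devTHETA_AB", 0.07), "p")     # ">= 0.07" is inclusive
  miss <- base; miss$Cluster_Sep <- NA; miss$probe_id <- "m"
  res <- filter_probes(rbind(base, miss))
  expect_identical(as.character(res), "p")
  expect_identical(attr(res, "excluded")$reason, "incomplete")
})
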