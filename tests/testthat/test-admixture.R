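sim_panel_and_queries <- function(n_snps, seed, q_queries,
                                  n_per_pop = 9L, fst = 0.1) {
  p <- sample_ancestral_freqs(n_snps, 0.05, 0.95, substream_seed(seed, "p"))
  F <- balding_nichols_freqs(p, fst, 3L, substream_seed(seed, "f"))
  rownames(F) <- c("A", "B", "C")
  Qp <- diag(3)[rep(1:3, each = n_per_pop), ]
  panel <- simulate_genotypes(F, Qp, substream_seed(seed, "gp"))
  queries <- simulate_genotypes(F, q_queries, substream_seed(seed, "gq"))
  list(F = F, panel = panel, queries = queries,
       labels = rep(c("A", "B", "C"), each = n_per_pop))
}

test_that("supervised EM with fixed frequencies maximizes monotonically", {
  # K = 1 is the degenerate simplex
  f1 <- matrix(0.4, 1, 100)
  g <- rbinom(100, 2, 0.4)
  expect_identical(supervised_q(g, f1)$q, c(pop1 = 1))

  sim <- sim_panel_and_queries(5000, 21, rbind(c(1, 0, 0)))
  fit <- supervised_q(sim$queries$geno[1, ], sim$F)
  expect_gt(fit$q[["A"]], 0.95)
  expect_true(all(diff(fit$trace) >= -1e-6))

  sim2 <- sim_panel_and_queries(10000, 22, rbind(c(0.5, 0.5, 0)))
  fit2 <- supervised_q(sim2$queries$geno[1, ], sim2$F)
  expect_lt(max(abs(fit2$q - c(0.5, 0.5, 0))), 0.05)
  expect_true(all(fit2$q >= 0))
  expect_equal(sum(fit2$q), 1, tolerance = 1e-9)

  expect_error(supervised_q(c(0, NA, 1), matrix(0.5, 1, 3)), "complete")
  expect_error(supervised_q(c(0, 1), matrix(c(0, 0.5), 1, 2)), "clamped")
})

test_that("joint supervised admixture pins the panel and frees the queries", {
  qtrue <- rbind(c(1, 0, 0), c(0, 0, 1), c(0.5, 0.5, 0))
  sim <- sim_panel_and_queries(4000, 23, qtrue)
  G <- rbind(sim$panel$geno, sim$queries$geno)
  labels <- c(sim$labels, rep(NA, 3))
  fit <- supervised_admixture(G, labels, tol = 1e-3, max_iter = 800)
  expect_true(all(diff(fit$trace) >= -1e-6))
  n <- length(sim$labels)
  expect_equal(unname(fit$Q[seq_len(n), ]),
               unname(diag(3)[rep(1:3, each = 9), ]))   # panel rows untouched
  expect_lt(max(abs(fit$Q[n + 1:3, ] - qtrue)), 0.08)
  expect_error(supervised_admixture(G, rep(NA, nrow(G))), "labelled")
})

test_that("unsupervised block EM is monotone and recovers separated pops", {
  p <- sample_ancestral_freqs(1500, 0.1, 0.9, 31)
  F <- balding_nichols_freqs(p, 0.15, 2L, 32)
  Q <- diag(2)[rep(1:2, each = 10), ]
  gm <- simulate_genotypes(F, Q, 33)

  # K = 1 closed form: F converges to the pooled frequency
  f1 <- unsupervised_admixture(gm, K = 1, seed = 1)
  expect_true(all(f1$Q == 1))
  expect_equal(as.vector(f1$F), colMeans(gm$geno) / 2, tolerance = 1e-6)
  expect_true(all(diff(f1$trace) >= -1e-6))

  fit <- unsupervised_admixture(gm, K = 2, seed = 2, tol = 1e-4,
                                max_iter = 400)
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_gte(fit$loglik, fit$trace[1])
  # membership recovered up to label swap
  err_id <- max(abs(fit$Q - Q))
  err_sw <- max(abs(fit$Q - Q[, 2:1]))
  expect_lt(min(err_id, err_sw), 0.05)
  expect_error(unsupervised_admixture(gm, K = 25), "exceed")
})

test_that("cross-validation is seeded, guarded and degenerate-safe", {
  p <- sample_ancestral_freqs(300, 0.2, 0.8, 41)
  F <- balding_nichols_freqs(p, 0.15, 2L, 42)
  gm <- simulate_genotypes(F, diag(2)[rep(1:2, each = 6), ], 43)
  a <- cv_error(gm, K = 2, n_folds = 3, n_boot = 1, seed = 9,
                max_iter = 50)
  b <- cv_error(gm, K = 2, n_folds = 3, n_boot = 1, seed = 9,
                max_iter = 50)
  expect_identical(a$mean, b$mean)
  expect_true(is.na(a$sd))
  expect_error(cv_error(gm, K = 2, n_folds = 1), "n_folds")
})

test_that("species classification needs a clear majority", {
  expect_identical(classify_species(c(1, 0, 0), c("B", "S", "T")), "B")
  expect_identical(classify_species(c(0.5, 0.5, 0), c("B", "S", "T")),
                   "admixed")
  expect_identical(classify_species(c(0.86, 0.14, 0), c("B", "S", "T")), "B")
  expect_error(classify_species(c(1, 0), c("a", "b"), major_min = 0.4))
})
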