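# Binomial admixture log-likelihood over unmasked cells.
# G: n x M dosages; P = Q %*% F; W: NULL or 0/1 mask (1 = observed).
admix_loglik <- function(G, P, W = NULL) {
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  ll <- G * log(P) + (2 - G) * log1p(-P)
  if (!is.null(W)) ll <- ll * W
  sum(ll)
}

# one EM step for Q with F fixed; returns updated n x K matrix
em_step_q <- function(G, Q, F, W = NULL) {
  P <- Q %*% F
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  A <- G / P
  B <- (2 - G) / (1 - P)
  if (!is.null(W)) { A <- A * W; B <- B * W }
  num <- (A %*% t(F) + B %*% t(1 - F)) * Q
  denom <- if (is.null(W)) 2 * ncol(G) else 2 * rowSums(W)
  Qn <- num / denom
  Qn / rowSums(Qn)                       # guard tiny drift off the simplex
}

# one EM step for F with Q fixed
em_step_f <- function(G, Q, F, W = NULL) {
  P <- Q %*% F
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  A <- G / P
  B <- (2 - G) / (1 - P)
  if (!is.null(W)) { A <- A * W; B <- B * W }
  a <- (t(Q) %*% A) * F                  # expected alt-allele counts from pop k
  b <- (t(Q) %*% B) * (1 - F)
  clamp_freq(a / (a + b))
}

#' Supervised ancestry proportions by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' \code{sum_m [g_m log p_m + (2 - g_m) log(1 - p_m)]}, with
#' \code{p_m = sum_k q_k f_km}, over the simplex, holding the population
#' allele frequencies \code{F} fixed (the supervised-analysis setting: F
#' comes from a labelled reference panel).  The EM update is monotone in the
#' log-likelihood; the trace is returned so callers can assert it.
#'
#' @param g Dosage vector (no missing entries) or an n x M matrix to fit all
#'   rows jointly (rows are independent).
#' @param F \code{K x M} frequency matrix with entries strictly inside (0,1).
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap.
#' @return List with \code{q} (vector, or matrix for matrix input),
#'   \code{loglik}, \code{trace} (per-iteration log-likelihood) and
#'   \code{iterations}.
#' @export
supervised_q <- function(g, F, tol = 1e-6, max_iter = 2000L) {
  single <- is.null(dim(g))
  G <- rbind(g)
  if (ncol(G) != ncol(F)) stop("genotypes and F disagree on SNP count")
  if (anyNA(G)) stop("supervised_q requires complete genotypes")
  if (any(F <= 0) || any(F >= 1)) {
    stop("F must be clamped strictly inside (0, 1)")
  }
  K <- nrow(F)
  Q <- matrix(1 / K, nrow = nrow(G), ncol = K)
  ll <- admix_loglik(G, Q %*% F)
  if (!is.finite(ll)) stop("non-finite likelihood at initialization")
  trace <- ll
  iter <- 0L
  while (iter < max_iter && K > 1L) {
    iter <- iter + 1L
    Q <- em_step_q(G, Q, F)
    ll_new <- admix_loglik(G, Q %*% F)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  rownames(Q) <- rownames(G)
  colnames(Q) <- rownames(F) %||% paste0("pop", seq_len(K))
  list(q = if (single) stats::setNames(Q[1L, ], colnames(Q)) else Q,
       loglik = ll, trace = trace, iterations = iter)
}

#' Unsupervised admixture by block EM
#'
#' Alternates the EM update for all ancestry vectors (F fixed) with the EM
#' update for the population frequencies (Q fixed); each half-step is itself
#' an EM step on the full likelihood, so the log-likelihood never decreases.
#' Population labels are unidentifiable (any column permutation of Q with
#' the matching row permutation of F is an equivalent optimum).
#'
#' @param gm \code{\link{geno_matrix}} or a dosage matrix (no missing calls;
#'   use the \code{mask} argument, not NAs, to hold out entries).
#' @param K Number of populations (1 <= K <= n samples).
#' @param seed Seed for the random initialization.
#' @param tol,max_iter Convergence controls on the log-likelihood.
#' @param mask Optional 0/1 matrix; 0-cells are excluded from the likelihood
#'   and every update (used by cross-validation).
#' @return List with \code{Q} (n x K), \code{F} (K x M), \code{loglik},
#'   \code{trace}, \code{iterations}.
#' @export
unsupervised_admixture <- function(gm, K, seed = 1L, tol = 1e-4,
                                   max_iter = 500L, mask = NULL) {
  G <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  if (anyNA(G)) stop("missing genotypes: pass holdout cells via `mask`")
  n <- nrow(G); m <- ncol(G)
  if (K > n) stop("K cannot exceed the number of samples")
  W <- mask
  init <- with_seed(seed, {
    Q0 <- matrix(stats::rgamma(n * K, shape = 1), nrow = n)
    Q0 <- Q0 / rowSums(Q0)
    pool <- if (is.null(W)) colMeans(G) / 2 else colSums(G * W) / (2 * colSums(W))
    F0 <- matrix(rep(pool, each = K), nrow = K) +
      matrix(stats::runif(K * m, -0.1, 0.1), nrow = K)
    list(Q = Q0, F = clamp_freq(F0))
  })
  Q <- init$Q; F <- init$F
  if (K == 1L) Q[] <- 1
  ll <- admix_loglik(G, Q %*% F, W)
  trace <- ll
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (K > 1L) Q <- em_step_q(G, Q, F, W)
    F <- em_step_f(G, Q, F, W)
    ll_new <- admix_loglik(G, Q %*% F, W)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  rownames(Q) <- rownames(G)
  list(Q = Q, F = F, loglik = ll, trace = trace, iterations = iter)
}

#' Supervised admixture: fixed panel labels, jointly estimated frequencies
#'
#' The supervised analysis mode: reference-panel samples have their
#' ancestry vectors pinned to their population labels while the remaining
#' samples' vectors are free, and the population allele frequencies are
#' re-estimated from \emph{all} samples by block EM.  (Holding F fixed at
#' plug-in panel frequencies instead shrinks pure samples' estimates
#' noticeably when the panel is small — errors-in-variables attenuation —
#' which joint estimation avoids.)  The log-likelihood is non-decreasing at
#' every iteration.
#'
#' @param gm \code{\link{geno_matrix}} or dosage matrix, no missing calls.
#' @param labels Character vector, one per sample: a population name for
#'   panel samples, \code{NA} for samples whose ancestry is to be estimated.
#' @param tol,max_iter Convergence controls on the log-likelihood.
#' @return List with \code{Q} (all samples; panel rows are their labels),
#'   \code{F}, \code{loglik}, \code{trace}, \code{iterations},
#'   \code{pop_names}.
#' @export
supervised_admixture <- function(gm, labels, tol = 1e-2, max_iter = 600L) {
  G <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(G))
  if (anyNA(G)) stop("supervised_admixture requires complete genotypes")
  fixed <- !is.na(labels)
  if (!any(fixed)) stop("no labelled panel samples")
  pops <- sort(unique(labels[fixed]))
  K <- length(pops)
  Q <- matrix(1 / K, nrow = nrow(G), ncol = K,
              dimnames = list(rownames(G), pops))
  Q[fixed, ] <- 0
  Q[cbind(which(fixed), match(labels[fixed], pops))] <- 1
  F <- panel_freqs(geno_matrix(G[fixed, , drop = FALSE],
                               data.frame(chrom = "1",
                                          pos = seq_len(ncol(G)),
                                          ref = "A", alt = "C")),
                   labels[fixed])
  ll <- admix_loglik(G, Q %*% F)
  trace <- ll
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Qn <- em_step_q(G, Q, F)
    Q[!fixed, ] <- Qn[!fixed, , drop = FALSE]
    F <- em_step_f(G, Q, F)
    ll_new <- admix_loglik(G, Q %*% F)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(Q = Q, F = F, loglik = ll, trace = trace, iterations = iter,
       pop_names = pops)
}

#' Held-out cross-validation error over K
#'
#' Genotype cells (sample x SNP entries, not whole samples) are partitioned
#' into \code{n_folds} random folds; each fold in turn is masked, the
#' unsupervised model is fitted on the remaining cells, and the masked cells
#' are scored by mean squared error between observed dosage and its fitted
#' expectation \code{2 sum_k q f}.  The whole procedure is repeated over
#' \code{n_boot} re-randomized fold assignments ("bootstrapped" CV) and the
#' mean and SD of the per-assignment CV errors are returned.
#'
#' @param gm \code{\link{geno_matrix}} or dosage matrix, no missing calls.
#' @param K Number of populations.
#' @param n_folds Folds (>= 2).
#' @param n_boot Fold re-randomizations (>= 1).
#' @param seed Integer seed.
#' @param tol,max_iter Passed to the unsupervised fits.
#' @return List with \code{mean}, \code{sd} (NA when \code{n_boot} = 1) and
#'   \code{per_boot}.
#' @export
cv_error <- function(gm, K, n_folds = 5L, n_boot = 1L, seed = 1L,
                     tol = 1e-3, max_iter = 200L) {
  G <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  if (n_folds < 2L) stop("n_folds must be at least 2 (a 0-fraction mask leaves nothing to score)")
  n <- nrow(G); m <- ncol(G)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bseed <- substream_seed(seed, paste0("cvfold", b))
    folds <- with_seed(bseed, {
      repeat {
        fl <- matrix(sample.int(n_folds, n * m, replace = TRUE), nrow = n)
        # a fold must never swallow an entire SNP column
        full <- FALSE
        for (f in seq_len(n_folds)) {
          if (any(colSums(fl == f) == n)) { full <- TRUE; break }
        }
        if (!full) break
        warning("redrawing folds: a fold masked an entire SNP column")
      }
      fl
    })
    err <- 0; nheld <- 0
    for (f in seq_len(n_folds)) {
      W <- (folds != f) * 1
      fit <- unsupervised_admixture(G, K,
                                    seed = substream_seed(bseed, paste0("fit", f)),
                                    tol = tol, max_iter = max_iter, mask = W)
      pred <- 2 * fit$Q %*% fit$F
      held <- folds == f
      err <- err + sum((G[held] - pred[held])^2)
      nheld <- nheld + sum(held)
    }
    boots[b] <- err / nheld
  }
  list(mean = mean(boots),
       sd = if (n_boot > 1L) stats::sd(boots) else NA_real_,
       per_boot = boots)
}

#' Classify species/population from an ancestry vector
#'
#' @param q Ancestry vector (sums to 1).
#' @param pop_names Population labels, one per component (defaults to
#'   \code{names(q)}).
#' @param major_min Minimum majority proportion in (0.5, 1]; below it the
#'   call is \code{"admixed"}.
#' @return A single label.
#' @export
classify_species <- function(q, pop_names = names(q), major_min = 0.85) {
  stopifnot(major_min > 0.5, major_min <= 1)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_along(q))
  k <- which.max(q)
  if (q[k] >= major_min) pop_names[k] else "admixed"
}
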