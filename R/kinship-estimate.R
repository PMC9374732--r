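#' Individual-specific allele frequencies
#'
#' The per-SNP frequency implied by a sample's ancestry vector,
#' \code{mu_m = sum_k q_k f_km}, clamped away from 0 and 1.  Conditioning
#' kinship moments on these individual-specific frequencies is what keeps
#' the estimator unbiased under population structure.
#'
#' @param q Ancestry vector on the simplex (length K).
#' @param F \code{K x M} population frequency matrix.
#' @return Numeric vector of length M.
#' @export
individual_freqs <- function(q, F) {
  if (length(q) != nrow(F)) stop("q and F disagree on the number of populations")
  clamp_freq(as.vector(q %*% F))
}

#' Ancestry-adjusted kinship coefficient for one pair
#'
#' Moment estimator on individual-specific frequencies:
#' \deqn{\hat\Phi = \frac{\sum_m (g_{im} - 2\mu_{im})(g_{jm} - 2\mu_{jm})}
#'   {4 \sum_m \sqrt{\mu_{im}(1-\mu_{im})\,\mu_{jm}(1-\mu_{jm})}}}
#' Self-pairs estimate (1 + inbreeding)/2, ~0.5 for outbred individuals;
#' unrelated pairs with correct \code{mu} estimate 0.
#'
#' @param g_i,g_j Dosage vectors (aligned, no missing entries).
#' @param mu_i,mu_j Individual-specific frequency vectors.
#' @param correction Optional scalar subtracted from the numerator (see
#'   \code{\link{panel_bias_correction}}); default 0 leaves the plain
#'   estimator.
#' @return Kinship estimate.
#' @export
kinship_phi <- function(g_i, g_j, mu_i, mu_j, correction = 0) {
  stopifnot(length(g_i) == length(g_j), length(mu_i) == length(g_i),
            length(mu_j) == length(g_j))
  if (anyNA(g_i) || anyNA(g_j)) stop("kinship_phi requires complete genotypes")
  denom <- 4 * sum(sqrt(mu_i * (1 - mu_i) * mu_j * (1 - mu_j)))
  if (denom <= 0) stop("degenerate denominator: all frequencies at bounds")
  (sum((g_i - 2 * mu_i) * (g_j - 2 * mu_j)) - correction) / denom
}

#' Finite-panel covariance correction for kinship numerators
#'
#' When both samples' individual-specific frequencies are built from the
#' same finite reference panel, the shared estimation error of
#' \code{f_km-hat} inflates the kinship numerator by approximately
#' \code{4 sum_m sum_k q_ik q_jk Var(f_km-hat)} (about \code{1/(2 n_k)} on
#' the kinship scale for a same-population pair — far above the confirmation
#' floor for a small panel).  This returns that term, with
#' \code{Var(f-hat)} evaluated by plug-in for the half-count pseudocount
#' estimator, for subtraction from the numerator.
#'
#' @param q_i,q_j Ancestry vectors.
#' @param F \code{K x M} panel frequency matrix.
#' @param panel_n Named or positional vector of panel sample counts per
#'   population (diploids).
#' @return Scalar correction for the numerator of \code{\link{kinship_phi}}.
#' @export
panel_bias_correction <- function(q_i, q_j, F, panel_n) {
  stopifnot(length(panel_n) == nrow(F))
  vf <- F * (1 - F) * (2 * panel_n) / (2 * panel_n + 1)^2   # K x M plug-in Var
  4 * sum((q_i * q_j) %*% vf)
}

#' IBD-sharing proportions for one pair by constrained least squares
#'
#' Builds the observed 3 x 3 joint-genotype count table, computes the
#' expected table under each IBD state (0, 1 or 2 alleles shared identical
#' by descent) using the pair-averaged frequency
#' \code{mu_bar = (mu_i + mu_j)/2} for the shared allele, and solves the
#' simplex-constrained least-squares problem for the state weights.  The
#' three-variable QP is solved exactly by enumerating the active sets of
#' the simplex (interior, three edges, three vertices).
#'
#' @param g_i,g_j Dosage vectors (no missing entries).
#' @param mu_i,mu_j Individual-specific frequency vectors.
#' @return Numeric \code{c(delta0, delta1, delta2)} summing to 1.
#' @export
ibd_deltas <- function(g_i, g_j, mu_i, mu_j) {
  stopifnot(length(g_i) == length(g_j))
  p <- clamp_freq((mu_i + mu_j) / 2)
  hw <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)        # M x 3, genotype 0/1/2
  obs <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) obs[a + 1, b + 1] <- sum(g_i == a & g_j == b)
  E0 <- crossprod(hw)                                  # sum_m hw_a hw_b
  E2 <- diag(colSums(hw))
  # one shared allele z ~ Bern(p); free alleles x_i, x_j ~ Bern(p)
  q0 <- cbind(1 - p, p)                                # P(free allele = 0/1)
  E1 <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) {
    acc <- 0
    for (z in 0:1) {
      if (a - z < 0 || a - z > 1 || b - z < 0 || b - z > 1) next
      pz <- if (z == 1) p else 1 - p
      acc <- acc + sum(pz * q0[, a - z + 1] * q0[, b - z + 1])
    }
    E1[a + 1, b + 1] <- acc
  }
  X <- cbind(as.vector(E0), as.vector(E1), as.vector(E2))
  if (kappa(X) > 1e10) {
    stop("degenerate expected-genotype matrix: IBD states are collinear")
  }
  y <- as.vector(obs)
  d <- simplex_lsq(X, y)
  stats::setNames(d, c("delta0", "delta1", "delta2"))
}

# exact min ||y - X d||^2 s.t. d >= 0, sum d = 1, for 3 columns:
# enumerate all non-empty support sets, solve the equality-constrained
# problem on each, keep the best feasible solution
simplex_lsq <- function(X, y) {
  k <- ncol(X)
  best <- NULL; best_obj <- Inf
  supports <- unlist(lapply(seq_len(k), function(s) {
    utils::combn(k, s, simplify = FALSE)
  }), recursive = FALSE)
  for (sup in supports) {
    Xi <- X[, sup, drop = FALSE]
    # minimize ||y - Xi d||^2 with sum d = 1 via a Lagrange multiplier
    A <- crossprod(Xi)
    o <- rep(1, length(sup))
    M <- rbind(cbind(2 * A, o), c(o, 0))
    rhs <- c(2 * crossprod(Xi, y), 1)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    d_sub <- sol[seq_along(sup)]
    if (any(d_sub < -1e-10)) next
    d <- numeric(k); d[sup] <- pmax(d_sub, 0)
    d <- d / sum(d)
    obj <- sum((y - X %*% d)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- d }
  }
  best
}

#' Kinship and IBD estimates for a set of pairs
#'
#' Convenience wrapper applying \code{\link{kinship_phi}} and
#' \code{\link{ibd_deltas}} across pairs, with the finite-panel correction
#' applied when \code{panel_n} is supplied.
#'
#' @param G Dosage matrix with rownames (no missing calls).
#' @param Q Ancestry matrix aligned to \code{G}'s rows.
#' @param F \code{K x M} frequency matrix.
#' @param pairs Two-column matrix/data frame of sample ids.
#' @param panel_n Optional per-population panel sizes enabling the
#'   finite-panel numerator correction.
#' @param deltas Whether to estimate IBD-state proportions too.
#' @return Data frame: id1, id2, phi_hat, delta0..2, n_snps.
#' @export
kinship_pairs <- function(G, Q, F, pairs, panel_n = NULL, deltas = TRUE) {
  pairs <- as.matrix(pairs)
  Mu <- clamp_freq(Q %*% F)
  rownames(Mu) <- rownames(Q) %||% rownames(G)
  out <- data.frame(id1 = pairs[, 1L], id2 = pairs[, 2L],
                    phi_hat = NA_real_, delta0 = NA_real_,
                    delta1 = NA_real_, delta2 = NA_real_,
                    n_snps = ncol(G), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    i <- out$id1[r]; j <- out$id2[r]
    corr <- if (is.null(panel_n)) 0 else {
      panel_bias_correction(Q[i, ], Q[j, ], F, panel_n)
    }
    out$phi_hat[r] <- kinship_phi(G[i, ], G[j, ], Mu[i, ], Mu[j, ],
                                  correction = corr)
    if (deltas) {
      out[r, c("delta0", "delta1", "delta2")] <-
        as.list(unname(ibd_deltas(G[i, ], G[j, ], Mu[i, ], Mu[j, ])))
    }
  }
  out
}
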