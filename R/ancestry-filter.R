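SEX_CHROMS <- c("X", "Y", "MT")

#' Filter variants for ancestry analysis
#'
#' Retains biallelic SNPs, optionally restricted to autosomes and to
#' complete (no missing call) columns, with minor allele frequency at or
#' above \code{maf_min} (inclusive) computed over all samples.
#'
#' @param gm \code{\link{geno_matrix}}.
#' @param maf_min Minimum minor allele frequency in [0, 0.5].
#' @param require_complete Drop any SNP with a missing call.
#' @param autosomes_only Drop X/Y/MT (chromosome aliases resolved).
#' @return Filtered \code{geno_matrix} (a warning, not an error, if empty).
#' @export
filter_variants <- function(gm, maf_min = 0.05, require_complete = TRUE,
                            autosomes_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  keep <- !grepl(",", gm$variants$alt, fixed = TRUE)
  if (autosomes_only) {
    keep <- keep & !(normalize_chrom(gm$variants$chrom) %in% SEX_CHROMS)
  }
  if (require_complete) {
    keep <- keep & colSums(is.na(gm$geno)) == 0L
  }
  nn <- colSums(!is.na(gm$geno))
  ac <- colSums(gm$geno, na.rm = TRUE)
  maf <- ifelse(nn > 0, pmin(ac, 2 * nn - ac) / (2 * nn), 0)
  keep <- keep & maf >= maf_min
  if (!any(keep)) warning("no variants survive filtering")
  gm_subset(gm, variants = which(keep))
}

#' Randomly sample variants without replacement
#'
#' @param gm \code{\link{geno_matrix}}.
#' @param n Number of SNPs to keep (\code{n <=} available).
#' @param seed Integer seed.
#' @return \code{geno_matrix} with genomic coordinate order preserved.
#' @export
sample_variants <- function(gm, n, seed = 1L) {
  m <- n_variants(gm)
  if (n > m) stop(sprintf("cannot sample %d of %d variants", n, m))
  if (n == m) return(gm)
  idx <- sort(with_seed(seed, sample.int(m, n)))
  gm_subset(gm, variants = idx)
}

#' PLINK-style sliding-window LD pruning
#'
#' Windows of \code{window_snps} SNPs advance by \code{step_snps} over the
#' variant list.  Within a window, while any retained pair has squared
#' dosage correlation above \code{r2_max}, the member of the worst offending
#' pair with the lower minor allele frequency is removed (ties: the later
#' genomic coordinate).  r-squared is computed on mean-centered dosage
#' vectors (composite LD, the PLINK default for unphased data).
#'
#' @param gm \code{\link{geno_matrix}} (no missing calls expected; pairwise
#'   complete observations are used if present).
#' @param window_snps Window size in SNPs (>= 2).
#' @param step_snps Step in SNPs (>= 1).
#' @param r2_max Pruning threshold in (0, 1].
#' @return Pruned \code{geno_matrix}.
#' @export
ld_prune <- function(gm, window_snps = 50L, step_snps = 10L, r2_max = 0.1) {
  stopifnot(window_snps >= 2L, step_snps >= 1L, r2_max > 0, r2_max <= 1)
  m <- n_variants(gm)
  if (m < 2L) return(gm)
  nn <- colSums(!is.na(gm$geno))
  ac <- colSums(gm$geno, na.rm = TRUE)
  maf <- pmin(ac, 2 * nn - ac) / pmax(2 * nn, 1L)
  keep <- rep(TRUE, m)
  # sweep windows over the retained list until a full pass removes nothing,
  # so the pruned output re-scanned with the same windows is always clean
  repeat {
    removed <- FALSE
    act_all <- which(keep)
    if (length(act_all) < 2L) break
    for (s in seq(1L, length(act_all), by = step_snps)) {
      win <- act_all[s:min(s + window_snps - 1L, length(act_all))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        cc <- suppressWarnings(
          stats::cor(gm$geno[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r2 <- cc^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1L, ]
        i <- act[hit[1L]]; j <- act[hit[2L]]
        drop <- if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else max(i, j)               # tie: later coordinate
        keep[drop] <- FALSE
        removed <- TRUE
      }
      if (s + window_snps - 1L >= length(act_all)) break
    }
    if (!removed) break
  }
  gm_subset(gm, variants = which(keep))
}

#' Panel allele frequencies per labelled population
#'
#' Alternate-allele frequency per population with a half-count pseudocount,
#' \code{f = (alt_count + 0.5) / (2 n + 1)}, clamped away from 0 and 1, so a
#' monomorphic panel never yields a degenerate likelihood.
#'
#' @param gm \code{\link{geno_matrix}} of panel samples.
#' @param labels Population label per sample (character; every population
#'   must have at least one sample).
#' @return Matrix \code{K x M} with populations as rownames.
#' @export
panel_freqs <- function(gm, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == n_samples(gm))
  pops <- sort(unique(labels))
  if (any(!nzchar(pops)) || anyNA(labels)) {
    stop("every panel sample needs a population label")
  }
  F <- matrix(NA_real_, nrow = length(pops), ncol = n_variants(gm),
              dimnames = list(pops, NULL))
  for (k in seq_along(pops)) {
    g <- gm$geno[labels == pops[k], , drop = FALSE]
    nn <- colSums(!is.na(g))
    if (all(nn == 0L)) stop("population has no samples: ", pops[k])
    F[k, ] <- (colSums(g, na.rm = TRUE) + 0.5) / (2 * nn + 1)
  }
  clamp_freq(F)
}

#' Microarray probe QC filter
#'
#' Each condition below describes pathological cluster geometry and is an
#' exclusion criterion; a probe is retained iff it triggers none and has all
#' statistics present:
#' meanR_AA/AB/BB < 0.2; Cluster_Sep < 0.35; meanTHETA_AA > 0.3;
#' meanTHETA_BB < 0.7; meanTHETA_AB outside [0.3, 0.7]; devTHETA_AA > 0.025;
#' devTHETA_AB >= 0.07; devTHETA_BB > 0.025; GenTrain_Score < 0.7.
#'
#' @param stats Data frame with a \code{probe_id} column and the statistics
#'   named above.
#' @return Character vector of retained probe ids, with a data frame of
#'   exclusions (probe_id, reason) as attribute \code{"excluded"}.
#' @export
filter_probes <- function(stats) {
  need <- c("meanR_AA", "meanR_AB", "meanR_BB", "Cluster_Sep",
            "meanTHETA_AA", "meanTHETA_AB", "meanTHETA_BB",
            "devTHETA_AA", "devTHETA_AB", "devTHETA_BB", "GenTrain_Score")
  stopifnot("probe_id" %in% names(stats), all(need %in% names(stats)))
  rules <- list(
    meanR_AB       = function(d) d$meanR_AB < 0.2,
    meanR_AA       = function(d) d$meanR_AA < 0.2,
    meanR_BB       = function(d) d$meanR_BB < 0.2,
    Cluster_Sep    = function(d) d$Cluster_Sep < 0.35,
    meanTHETA_AA   = function(d) d$meanTHETA_AA > 0.3,
    meanTHETA_BB   = function(d) d$meanTHETA_BB < 0.7,
    meanTHETA_AB   = function(d) d$meanTHETA_AB < 0.3 | d$meanTHETA_AB > 0.7,
    devTHETA_AA    = function(d) d$devTHETA_AA > 0.025,
    devTHETA_AB    = function(d) d$devTHETA_AB >= 0.07,
    devTHETA_BB    = function(d) d$devTHETA_BB > 0.025,
    GenTrain_Score = function(d) d$GenTrain_Score < 0.7)
  incomplete <- rowSums(is.na(stats[need])) > 0L
  reason <- rep(NA_character_, nrow(stats))
  reason[incomplete] <- "incomplete"
  for (nm in names(rules)) {
    hit <- !incomplete & is.na(reason) & rules[[nm]](stats)
    reason[hit] <- nm
  }
  keep <- is.na(reason)
  structure(stats$probe_id[keep],
            excluded = data.frame(probe_id = stats$probe_id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
}
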