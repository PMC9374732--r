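#' Draw ancestral allele frequencies
#'
#' Per-SNP ancestral alternate-allele frequencies, i.i.d. uniform on
#' \code{[lo, hi]}.
#'
#' @param n_snps Number of SNPs (>= 0).
#' @param lo,hi Frequency bounds, \code{0 < lo <= hi < 1}.
#' @param seed Integer seed.
#' @return Numeric vector of length \code{n_snps}.
#' @export
sample_ancestral_freqs <- function(n_snps, lo = 0.05, hi = 0.95, seed = 1L) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 0) {
    stop("n_snps must be a single non-negative integer")
  }
  stopifnot(lo > 0, hi < 1, lo <= hi)
  if (n_snps == 0) return(numeric(0))
  with_seed(seed, stats::runif(n_snps, lo, hi))
}

#' Balding-Nichols population allele frequencies
#'
#' Each population's frequency at SNP m is drawn
#' \code{Beta(p_m (1-fst)/fst, (1-p_m)(1-fst)/fst)} around the ancestral
#' frequency \code{p_m}, so \code{E[f] = p_m} and the expected fixation index
#' between any two populations is \code{fst}.  Entries are clamped away from
#' 0 and 1.
#'
#' @param ancestral Ancestral frequency vector (entries strictly in (0,1)).
#' @param fst Divergence parameter, strictly in (0,1).
#' @param n_pops Number of populations (>= 1).
#' @param seed Integer seed.
#' @return Matrix \code{n_pops x n_snps}.
#' @export
balding_nichols_freqs <- function(ancestral, fst, n_pops, seed = 1L) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1) {
    stop("fst must lie strictly in (0, 1)")
  }
  stopifnot(n_pops >= 1, all(ancestral > 0), all(ancestral < 1))
  m <- length(ancestral)
  a <- ancestral * (1 - fst) / fst
  b <- (1 - ancestral) * (1 - fst) / fst
  f <- with_seed(seed, {
    matrix(stats::rbeta(n_pops * m, rep(a, each = n_pops),
                        rep(b, each = n_pops)),
           nrow = n_pops, ncol = m)
  })
  clamp_freq(f)
}

#' Simulate unlinked genotypes under the admixture model
#'
#' Dosage \code{g_im ~ Binomial(2, sum_k q_ik f_km)}, independent across
#' samples and SNPs.
#'
#' @param F Population allele-frequency matrix (\code{K x M}, entries in (0,1)).
#' @param Q Ancestry matrix (\code{n x K}, rows on the simplex).  Rownames
#'   become sample ids.
#' @param seed Integer seed.
#' @param chrom,pos Optional variant coordinates; defaults spread SNPs evenly
#'   over 22 autosomes.
#' @return A \code{\link{geno_matrix}}.
#' @export
simulate_genotypes <- function(F, Q, seed = 1L, chrom = NULL, pos = NULL) {
  Q <- rbind(Q)
  if (ncol(Q) != nrow(F)) stop("Q and F disagree on the number of populations")
  if (any(abs(rowSums(Q) - 1) > 1e-8) || any(Q < 0)) {
    stop("each row of Q must lie on the simplex")
  }
  m <- ncol(F)
  P <- Q %*% F                                  # n x M expected half-dosage
  g <- with_seed(seed, {
    matrix(stats::rbinom(length(P), 2L, as.vector(P)), nrow = nrow(P))
  })
  rownames(g) <- rownames(Q)
  if (is.null(chrom)) chrom <- as.character(1L + (seq_len(m) - 1L) %% 22L)
  if (is.null(pos)) pos <- 1000L * (seq_len(m))
  geno_matrix(g, data.frame(chrom = chrom, pos = pos,
                            ref = "A", alt = "C",
                            stringsAsFactors = FALSE))
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders keep their supplied genotypes; every non-founder receives, per
#' SNP, one allele from each parent, each chosen uniformly and independently
#' (a heterozygous parent transmits the alternate allele with probability
#' one half).  Per SNP this reproduces the exact joint genotype distribution
#' of Mendelian transmission, so downstream kinship/IBD estimators see the
#' correct relatedness structure.
#'
#' @param pedigree A \code{\link{pedigree}} object.
#' @param founder_genotypes \code{geno_matrix} whose rownames cover every
#'   founder id of the pedigree.
#' @param seed Integer seed.
#' @return \code{geno_matrix} with one row per pedigree member, founders
#'   passed through unchanged.
#' @export
drop_genes <- function(pedigree, founder_genotypes, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree"))
  ped <- pedigree$members
  founders <- ped$id[is.na(ped$sire)]
  missing <- setdiff(founders, rownames(founder_genotypes$geno))
  if (length(missing)) {
    stop("missing founder genotypes for: ", paste(missing, collapse = ", "))
  }
  m <- n_variants(founder_genotypes)
  out <- matrix(NA_integer_, nrow = nrow(ped), ncol = m,
                dimnames = list(ped$id, NULL))
  out[founders, ] <- founder_genotypes$geno[founders, , drop = FALSE]
  with_seed(seed, {
    for (i in order(pedigree$depth)) {
      if (is.na(ped$sire[i])) next
      gs <- out[ped$sire[i], ]
      gd <- out[ped$dam[i], ]
      out[ped$id[i], ] <- stats::rbinom(m, 1L, gs / 2) +
        stats::rbinom(m, 1L, gd / 2)
    }
  })
  geno_matrix(out, founder_genotypes$variants)
}

#' Default chromosome length table
#'
#' Orang-utan-like magnitudes: 22 autosomes from ~227 Mb down to ~47 Mb,
#' X ~ 140 Mb, Y ~ 26 Mb.  Lengths are configuration, not constants; any
#' named vector with X and Y entries works everywhere a length table is
#' accepted.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
default_chrom_lengths <- function() {
  auto <- round(seq(227e6, 47e6, length.out = 22))
  stats::setNames(c(auto, 140e6, 26e6), c(as.character(1:22), "X", "Y"))
}

#' Simulate per-chromosome mapped-read counts
#'
#' Expected counts are proportional to copy number times chromosome length
#' times depth: autosomes carry 2 copies, X carries 2 (female) or 1 (male),
#' Y carries 1 (male) or a mismapping leak of \code{mismap_rate * 2}
#' female-derived copies.  Counts are Poisson around the expectation
#' (expected count for a 2-copy chromosome = depth * length / read_len with
#' read_len fixed at 100 bp).
#'
#' @param sex "male" or "female".
#' @param mean_depth Mean autosomal depth (> 0).
#' @param mismap_rate Fraction of female X-like reads mismapped to Y
#'   (\code{0 <= mismap_rate < 0.1}).
#' @param chrom_lengths Named lengths in bp including "X" and "Y".
#' @param seed Integer seed.
#' @param sample_id Sample identifier carried through.
#' @return A \code{chrom_counts} data frame (chrom, length, mapped, unmapped)
#'   with the sample id as attribute.
#' @export
simulate_chrom_counts <- function(sex, mean_depth, mismap_rate = 0.01,
                                  chrom_lengths = default_chrom_lengths(),
                                  seed = 1L, sample_id = "sample") {
  if (!sex %in% c("male", "female")) stop("unknown sex label: ", sex)
  stopifnot(mean_depth > 0, mismap_rate >= 0, mismap_rate < 0.1,
            all(c("X", "Y") %in% names(chrom_lengths)))
  read_len <- 100
  copies <- ifelse(names(chrom_lengths) == "X",
                   ifelse(sex == "female", 2, 1),
            ifelse(names(chrom_lengths) == "Y",
                   ifelse(sex == "male", 1, 2 * mismap_rate), 2))
  lambda <- copies / 2 * mean_depth * chrom_lengths / read_len
  mapped <- with_seed(seed, stats::rpois(length(lambda), lambda))
  structure(
    data.frame(chrom = names(chrom_lengths),
               length = unname(chrom_lengths),
               mapped = mapped,
               unmapped = 0L,
               stringsAsFactors = FALSE),
    sample_id = sample_id, class = c("chrom_counts", "data.frame"))
}

#' Duplicate SNPs into correlated blocks
#'
#' Testing aid for LD pruning on otherwise unlinked simulations: each chosen
#' SNP is duplicated \code{copies - 1} times with per-genotype resampling
#' noise (each copy's dosage is redrawn with probability \code{noise}),
#' producing blocks of high but imperfect r-squared at adjacent coordinates.
#'
#' @param gm \code{geno_matrix}.
#' @param block_every Duplicate every \code{block_every}-th SNP.
#' @param copies Number of copies per duplicated SNP (>= 2).
#' @param noise Per-entry resampling probability in [0, 1).
#' @param seed Integer seed.
#' @return \code{geno_matrix} with duplicated columns inserted adjacent to
#'   their source, positions offset by 1 bp steps.
#' @export
add_ld_blocks <- function(gm, block_every = 10L, copies = 2L, noise = 0.05,
                          seed = 1L) {
  stopifnot(copies >= 2L, noise >= 0, noise < 1)
  m <- n_variants(gm)
  src <- seq(1L, m, by = block_every)
  cols <- sort(c(seq_len(m), rep(src, each = copies - 1L)))
  g <- gm$geno[, cols, drop = FALSE]
  v <- gm$variants[cols, , drop = FALSE]
  dup <- duplicated(cols)
  with_seed(seed, {
    for (j in which(dup)) {
      flip <- stats::runif(nrow(g)) < noise
      if (any(flip)) {
        p <- mean(gm$geno[, cols[j]]) / 2
        g[flip, j] <- stats::rbinom(sum(flip), 2L, p)
      }
    }
    v$pos <- v$pos + stats::ave(seq_along(cols), cols, FUN = seq_along) - 1L
  })
  geno_matrix(g, v)
}
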