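#' Genotype matrix container
#'
#' A light container for a samples x variants dosage matrix (counts of the
#' alternate allele, 0/1/2, \code{NA} for missing) together with variant
#' metadata (chromosome, 1-based position, ref and alt alleles).  Multi-allelic
#' records carry comma-separated alt alleles and are flagged for the variant
#' filter rather than rejected at construction.
#'
#' @param geno Integer matrix, samples in rows (rownames are sample ids),
#'   variants in columns; entries in \code{c(0, 1, 2, NA)}.
#' @param variants Data frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, one row per column of \code{geno}.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(geno, variants) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(geno))
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must lie in {0, 1, 2} or be NA")
  }
  variants$chrom <- as.character(variants$chrom)
  rownames(variants) <- NULL
  structure(list(geno = geno, variants = variants), class = "geno_matrix")
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

n_samples <- function(gm) nrow(gm$geno)
n_variants <- function(gm) ncol(gm$geno)

#' Subset a genotype matrix
#'
#' @param gm A \code{geno_matrix}.
#' @param samples Optional sample index/names to keep.
#' @param variants Optional variant (column) index to keep.
#' @return A \code{geno_matrix}.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  g <- gm$geno
  v <- gm$variants
  if (!is.null(samples)) g <- g[samples, , drop = FALSE]
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  geno_matrix(g, v)
}

#' Bind two genotype matrices over the same variants
#'
#' @param ... \code{geno_matrix} objects sharing identical variant tables.
#' @return A \code{geno_matrix} with samples stacked.
#' @export
gm_rbind <- function(...) {
  gms <- list(...)
  v <- gms[[1L]]$variants
  for (gm in gms[-1L]) {
    if (!identical(gm$variants[c("chrom", "pos")], v[c("chrom", "pos")])) {
      stop("genotype matrices must share the same variant table")
    }
  }
  geno_matrix(do.call(rbind, lapply(gms, `[[`, "geno")), v)
}
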