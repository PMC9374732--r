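# canonical chromosome names: strip "chr" prefix, fold mitochondrial aliases
normalize_chrom <- function(x, alias_map = NULL) {
  x <- sub("^chr", "", as.character(x))
  x[x %in% c("M", "Mt", "mt")] <- "MT"
  if (!is.null(alias_map)) {
    hit <- match(x, names(alias_map))
    x[!is.na(hit)] <- unname(alias_map[hit[!is.na(hit)]])
  }
  x
}

#' Read a samtools idxstats-style table
#'
#' Four tab-separated columns: reference name, length, mapped reads,
#' unmapped reads.  Chromosome aliases ("chrX" vs "X") are resolved.
#'
#' @param path File path.
#' @param sample_id Sample id to attach (default: file name sans extension).
#' @param alias_map Optional named vector of extra name aliases.
#' @return A \code{chrom_counts} data frame.
#' @export
read_idxstats <- function(path, sample_id = NULL, alias_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop(sprintf("malformed idxstats line %d in %s (expected 4 fields, got %d)",
                 which(nf != 4L)[1L], path, nf[nf != 4L][1L]))
  }
  df <- data.frame(
    chrom = normalize_chrom(vapply(parts, `[[`, "", 1L), alias_map),
    length = as.numeric(vapply(parts, `[[`, "", 2L)),
    mapped = as.numeric(vapply(parts, `[[`, "", 3L)),
    unmapped = as.numeric(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$length) || anyNA(df$mapped)) {
    stop("malformed idxstats numeric field in ", path)
  }
  structure(df, sample_id = sample_id %||%
              sub("\\.[^.]*$", "", basename(path)),
            class = c("chrom_counts", "data.frame"))
}

#' Write an idxstats-style table
#'
#' @param counts A \code{chrom_counts} data frame.
#' @param path Output path.
#' @export
write_idxstats <- function(counts, path) {
  utils::write.table(counts[c("chrom", "length", "mapped", "unmapped")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF into a genotype matrix
#'
#' Only the GT field is used: "0/0" (or phased) maps to dosage 0, "./." to
#' missing.  Multi-allelic records are preserved (alt keeps its commas) and
#' left to \code{\link{filter_variants}}.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A \code{\link{geno_matrix}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% unlist(strsplit(v@gt[1L, "FORMAT"], ":"))) {
    stop("VCF has no GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, 2L, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (anyNA(x) || any(x == ".")) NA_integer_ else sum(as.integer(x) > 0L)
    }, 0L)
  })
  dose <- matrix(dose, nrow = nrow(v@fix),
                 dimnames = list(NULL, colnames(gt)))
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  geno_matrix(t(dose),
              data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Plain-text VCFv4.2, 1-based positions, unphased genotypes, "./." for
#' missing.  Round-trips through \code{\link{read_vcf}}.
#'
#' @param gm A \code{\link{geno_matrix}}.
#' @param path Output path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$geno)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_variants(gm))) {
    g <- gm$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(gm$variants$chrom[j], gm$variants$pos[j], ".",
                       gm$variants$ref[j], gm$variants$alt[j], ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PED-style pedigree file
#'
#' Tab-separated with a header; columns \code{id}, \code{sire}, \code{dam},
#' \code{sex} (optionally preceded by \code{family}); "0" or empty = unknown
#' parent.  Validation (acyclicity, both-or-none parents) happens in
#' \code{\link{pedigree}}.
#'
#' @param path File path.
#' @return A \code{\link{pedigree}}.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if ("family" %in% names(df)) df$family <- NULL
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file needs columns id, sire, dam (and optionally sex)")
  }
  pedigree(df$id, df$sire, df$dam, df$sex %||% NA_character_)
}

#' Write a pedigree as a PED-style file
#'
#' @param ped A \code{\link{pedigree}}.
#' @param path Output path.
#' @param family Family label for the first column.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  df <- ped$members
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  out <- cbind(family = family, df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

table1_file <- function(name) {
  system.file("extdata", name, package = "trifold", mustWork = TRUE)
}

read_tsv_ <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Load the packaged worked-example fixture
#'
#' Ten re-sequenced orang-utan genomes whose deposited metadata proved to be
#' switched: the published table of reported and corrected identities
#' (BioSample accession, lab id, International Studbook number, name,
#' species code B/S/T, sex), the measured X:Y mapped-read ratio per sample,
#' the published kinship block linking seven samples to eight
#' array-genotyped relatives (IBD-state probabilities, expected and observed
#' kinship), a registry of the ten candidate individuals with their known
#' pedigree links, archival (validated) lab ids, and the X:Y calibration
#' ranges observed in known males (0.369-0.569) and females (4.114-5.827).
#'
#' @return List of class \code{table1_fixture} with elements
#'   \code{samples}, \code{kinship}, \code{registry}, \code{links},
#'   \code{records_lab_ids}, \code{sex_calibration}.
#' @export
load_table1 <- function() {
  samples <- read_tsv_(table1_file("table1_samples.tsv"))
  kinship <- read_tsv_(table1_file("table1_kinship.tsv"))
  registry <- read_tsv_(table1_file("table1_registry.tsv"))
  links <- read_tsv_(table1_file("table1_links.tsv"))
  records <- read_tsv_(table1_file("table1_records.tsv"))
  sexcal <- data.frame(
    ratio = c(0.369, 0.569, 4.114, 5.827),
    sex = c("male", "male", "female", "female"),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, kinship = kinship, registry = registry,
                 links = links, records_lab_ids = records,
                 sex_calibration = sexcal),
            class = "table1_fixture")
}

#' @exportS3Method base::print
print.table1_fixture <- function(x, ...) {
  cat(sprintf("<table1_fixture> %d samples, %d kinship rows, %d registry individuals\n",
              nrow(x$samples), nrow(x$kinship), nrow(x$registry)))
  invisible(x)
}
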