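#' Length-normalized X:Y mapped-read ratio
#'
#' Returns \code{(mapped_X / length_X) / (mapped_Y / length_Y)}.  Males carry
#' one X and one Y, so their ratio sits near 1 under this normalization;
#' females have no Y and their ratio is driven by Y mismapping noise, orders
#' of magnitude higher.  Thresholds are always calibrated from known-sex
#' individuals (\code{\link{calibrate_thresholds}}), so the choice of
#' normalization does not affect calls.
#'
#' @param counts A \code{chrom_counts} data frame (chrom, length, mapped).
#' @return Ratio; \code{+Inf} with attribute \code{y_zero = TRUE} when the Y
#'   mapped count is zero (interpreted as strongly female).
#' @export
xy_ratio <- function(counts) {
  cn <- normalize_chrom(counts$chrom)
  ix <- match("X", cn); iy <- match("Y", cn)
  if (is.na(ix) || is.na(iy)) stop("chrom counts must include X and Y")
  if (counts$mapped[iy] == 0) {
    return(structure(Inf, y_zero = TRUE))
  }
  (counts$mapped[ix] / counts$length[ix]) /
    (counts$mapped[iy] / counts$length[iy])
}

#' Calibrate male/female ratio thresholds from labelled individuals
#'
#' The male band is widened above the largest known-male ratio and the
#' female band below the smallest known-female ratio by a multiplicative
#' margin; ratios between the widened bands classify as undetermined.
#'
#' @param labeled_ratios Data frame with columns \code{ratio} and \code{sex}
#'   ("male"/"female"); at least one of each.
#' @param margin Multiplicative widening, default 0.25.
#' @return List of class \code{sex_thresholds} with \code{male_upper} and
#'   \code{female_lower}.
#' @export
calibrate_thresholds <- function(labeled_ratios, margin = 0.25) {
  stopifnot(is.data.frame(labeled_ratios),
            all(c("ratio", "sex") %in% names(labeled_ratios)))
  rm_ <- labeled_ratios$ratio[labeled_ratios$sex == "male"]
  rf <- labeled_ratios$ratio[labeled_ratios$sex == "female"]
  if (!length(rm_) || !length(rf)) {
    stop("need at least one known male and one known female ratio")
  }
  if (max(rm_) >= min(rf)) {
    stop(sprintf("male and female ratio clusters overlap (max male %.3f >= min female %.3f)",
                 max(rm_), min(rf)))
  }
  male_upper <- max(rm_) * (1 + margin)
  female_lower <- min(rf) * (1 - margin)
  if (male_upper >= female_lower) {
    stop(sprintf(paste0("widened bands overlap (male_upper %.3f >= ",
                        "female_lower %.3f); reduce margin or review labels"),
                 male_upper, female_lower))
  }
  structure(list(male_upper = male_upper, female_lower = female_lower),
            class = "sex_thresholds")
}

#' Classify genetic sex from an X:Y ratio
#'
#' Ratios at or below \code{male_upper} call male, at or above
#' \code{female_lower} call female; the gap between the widened bands is an
#' explicit undetermined zone (ties at a threshold resolve toward the
#' labelled side).
#'
#' @param ratio X:Y ratio(s), possibly \code{Inf}.
#' @param thresholds A \code{sex_thresholds} object.
#' @param sample_id Optional ids carried into the result.
#' @return Data frame (sample, ratio, call).
#' @export
classify_sex <- function(ratio, thresholds, sample_id = NULL) {
  stopifnot(inherits(thresholds, "sex_thresholds"))
  call <- ifelse(ratio <= thresholds$male_upper, "male",
          ifelse(ratio >= thresholds$female_lower, "female", "undetermined"))
  data.frame(sample = sample_id %||% seq_along(ratio),
             ratio = as.numeric(ratio), call = call,
             stringsAsFactors = FALSE)
}
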