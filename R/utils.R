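#' @keywords internal
"_PACKAGE"

# frequency clamp shared by every module that touches allele frequencies
FREQ_EPS <- 1e-6

clamp_freq <- function(x, eps = FREQ_EPS) {
  pmin(pmax(x, eps), 1 - eps)
}

#' Derive a reproducible substream seed from a base seed
#'
#' All scenario randomness flows from one base seed; each stage draws from a
#' named substream so stages can be regenerated independently.  Seeds stay
#' below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param stream Character name of the substream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # cheap string hash (polynomial rolling, 31-bit)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 * 48271 + h) %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
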