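# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; insertion-site G/C values are printed
#' with conventional half-up rounding, so that convention is applied
#' everywhere a value is formatted to a fixed number of decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
#' @noRd
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  # small epsilon guards against representation error at exact .5 boundaries
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a DNA string (A/C/G/T only)
#' @noRd
checkDna <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (!allowEmpty && nchar(x) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  if (grepl("[^ACGTacgt]", x))
    stop(what, " contains non-ACGT symbols", call. = FALSE)
  toupper(x)
}

#' Reverse complement of a plain character string
#' @noRd
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Deterministic child seed derived from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% .Machine$integer.max)
}
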