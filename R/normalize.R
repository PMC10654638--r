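#' Normalize a free-text term
#'
#' Canonicalizes drug names, adverse-event preferred terms and indication
#' terms before any matching or counting: leading/trailing whitespace is
#' trimmed, internal whitespace runs collapse to a single space, and the
#' result is lower-cased. Deterministic; locale-independent for ASCII input.
#'
#' @param raw character vector of free-text terms.
#' @return character vector of normalized terms, same length as `raw`.
#' @examples
#' normalize_term("  Osteonecrosis of Jaw ")   # "osteonecrosis of jaw"
#' normalize_term("Tooth   extraction")        # "tooth extraction"
#' @export
normalize_term <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- tolower(gsub("\\s+", " ", trimws(raw)))
  if (any(!is.na(out) & out == "")) {
    stop("invalid term: empty after normalization", call. = FALSE)
  }
  out
}

## round half away from zero (base round() is round-half-even); used for all
## printed percentages so counts reproduce published tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## percentage of n over denom at the configured rounding; NaN-safe
pct_of <- function(n, denom, digits = 2) {
  if (denom <= 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / denom, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
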