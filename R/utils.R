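#' Normalize kin term forms
#'
#' Applies Unicode NFC normalization and trims surrounding whitespace.
#' Case is preserved: orthographic case may be contrastive in source
#' transcriptions.
#'
#' @param x Character vector of term forms (NA allowed).
#' @return Character vector of the same length.
#' @export
normalize_term <- function(x) {
  out <- stringi::stri_trans_nfc(as.character(x))
  out <- stringi::stri_trim_both(out)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# Deterministic 31-bit seed derived from a root seed and a string id, so
# per-system permutation streams are independent of corpus order.
derive_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483647)
}

# z-threshold classification; sd = 0 degenerates to z = 0 (not significant).
classify_z <- function(z, threshold = 1.96) {
  dplyr::case_when(
    z < -threshold ~ "significantly_low",
    z > threshold ~ "significantly_high",
    TRUE ~ "not_significant"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kin <- function(...) stop(..., call. = FALSE)
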