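#' Edit distance between kin term forms
#'
#' `kin_levenshtein()` is the unit-cost Levenshtein distance -- the number
#' of single-character insertions, deletions or replacements turning one
#' string into the other -- computed over Unicode code points on
#' NFC-normalized input. `normalized_levenshtein()` divides by the length
#' (in code points) of the longer string, giving a value in [0, 1]: 0 for
#' identical forms, 1 when no alignment is cheaper than full replacement.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer distances, or normalized distances in [0, 1].
#' @examples
#' kin_levenshtein("uncle", "cousin")        # 6
#' normalized_levenshtein("uncle", "cousin") # 1
#' normalized_levenshtein("pur", "purza")    # 0.4
#' @export
kin_levenshtein <- function(a, b) {
  a <- normalize_term(a)
  b <- normalize_term(b)
  a[is.na(a)] <- ""
  b[is.na(b)] <- ""
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i)
    as.integer(utils::adist(a[i], b[i], useBytes = FALSE)), integer(1))
}

#' @rdname kin_levenshtein
#' @export
normalized_levenshtein <- function(a, b) {
  a <- normalize_term(a); b <- normalize_term(b)
  a[is.na(a)] <- ""; b[is.na(b)] <- ""
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  len <- pmax(stringi::stri_length(a), stringi::stri_length(b))
  if (any(len == 0))
    stop_kin("normalized edit distance is undefined for two empty strings")
  kin_levenshtein(a, b) / len
}

# All-pairs normalized distances between two form vectors (rows x cols).
normalized_levenshtein_matrix <- function(a, b) {
  d <- utils::adist(a, b, useBytes = FALSE)
  len <- outer(stringi::stri_length(a), stringi::stri_length(b), pmax)
  d / len
}

#' Mean normalized edit distance between parent and child terms
#'
#' Averages the normalized Levenshtein distance over all observed
#' parent-child term pairs of a system. By default pairs are weighted by
#' link multiplicity -- the same enumeration the entropy statistic uses --
#' so a term pair realised on three links counts three times;
#' `pairs = "unique"` deduplicates (parent_term, child_term) pairs first.
#'
#' @param data A kin term table for one system.
#' @param inventory A [kin_inventory()].
#' @param pairs `"links"` (multiplicity-weighted, default) or `"unique"`.
#' @return The mean normalized distance, in [0, 1].
#' @export
mean_parent_child_distance <- function(data, inventory,
                                       pairs = c("links", "unique")) {
  pairs <- match.arg(pairs)
  tp <- term_pairs(data, inventory)
  if (nrow(tp) == 0)
    stop_kin("no observed parent-child term pairs")
  if (pairs == "unique")
    tp <- dplyr::distinct(tp, .data$parent_term, .data$child_term)
  mean(normalized_levenshtein(tp$parent_term, tp$child_term))
}

#' Compositionality test for a corpus of kinship systems
#'
#' Tests whether parent and child kin terms resemble each other in form
#' more than chance: the mean normalized edit distance over parent-child
#' pairs is compared to its permutation baseline (G0 terms reshuffled over
#' referents). A significantly low distance (`z < -threshold`) marks the
#' system as compositional -- parent and child forms are more similar than
#' the system's own term inventory predicts; significantly high distance
#' marks systems whose form resemblances deliberately avoid parent-child
#' pairs.
#'
#' @inheritParams predictive_structure
#' @return A tibble with one row per analysable system (columns as
#'   [predictive_structure()], plus `compositional` =
#'   `classification == "significantly_low"`).
#' @export
compositionality <- function(data, inventory, n_permutations = 1000,
                             seed = 1, threshold = 1.96,
                             mode = c("z", "percentile")) {
  mode <- match.arg(mode)
  out <- predictive_structure(data, inventory, statistic = "edit_distance",
                              n_permutations = n_permutations, seed = seed,
                              threshold = threshold, mode = mode)
  out$compositional <- out$classification == "significantly_low"
  out
}
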