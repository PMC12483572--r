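#' Kinship term tables
#'
#' Throughout the package a corpus of kinship systems is a long-format data
#' frame with one row per (system, kin type, form): columns `system_id`,
#' `kin_type`, `term`, plus any metadata columns (glottocode, family, ...).
#' A single system is simply such a table with one `system_id`. `term`
#' values are normalized with [normalize_term()] on entry; rows whose term
#' normalizes to `NA` count as missing and are dropped.
#'
#' @name kin_terms
NULL

# Validate and canonicalise a term table against an inventory. Unknown kin
# types are dropped (with a warning when warn = TRUE); terms normalized.
as_kin_terms <- function(data, inventory, warn = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("system_id", "kin_type", "term")
  if (!all(need %in% names(data)))
    stop_kin("term table needs columns: ", paste(need, collapse = ", "))
  data$term <- normalize_term(data$term)
  data <- data[!is.na(data$term), , drop = FALSE]
  unknown <- setdiff(unique(data$kin_type), inventory$types$code)
  if (length(unknown) > 0) {
    if (warn)
      warning("ignoring kin types not in inventory: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    data <- data[data$kin_type %in% inventory$types$code, , drop = FALSE]
  }
  data
}

# One system's assignment as a named character vector code -> form.
# Multiple forms per kin type are resolved upstream (see read_kin_terms);
# here the first occurrence wins.
assignment_vector <- function(data) {
  data <- data[!duplicated(data$kin_type), , drop = FALSE]
  stats::setNames(data$term, data$kin_type)
}

#' Enumerate observed parent-child term pairs
#'
#' Every parent-child link of the inventory whose two kin types both carry
#' a term in the system contributes one pair; links touching a missing
#' assignment are silently dropped (pairwise deletion). Pair multiplicity
#' follows link multiplicity: a term pair realised on three links appears
#' three times.
#'
#' @param data A kin term table (see [kin_terms]); may contain several
#'   systems.
#' @param inventory A [kin_inventory()].
#' @return A tibble with columns `system_id`, `parent_type`, `child_type`,
#'   `parent_term`, `child_term`, one row per observed link.
#' @examples
#' inv <- kin_inventory("experiment16")
#' tbl <- tibble::tibble(system_id = "en",
#'   kin_type = c("M", "F", "MB", "B", "MBS"),
#'   term = c("mother", "father", "uncle", "brother", "cousin"))
#' term_pairs(tbl, inv)
#' @export
term_pairs <- function(data, inventory) {
  data <- as_kin_terms(data, inventory)
  links <- inventory$links
  purrr::map_dfr(split(data, data$system_id), function(sys) {
    a <- assignment_vector(sys)
    keep <- links$parent %in% names(a) & links$child %in% names(a)
    lk <- links[keep, , drop = FALSE]
    tibble::tibble(
      system_id = rep(sys$system_id[1], nrow(lk)),
      parent_type = lk$parent, child_type = lk$child,
      parent_term = unname(a[lk$parent]), child_term = unname(a[lk$child])
    )
  })
}

#' Filter systems to those analysable for predictive structure
#'
#' A system is analysable when it has at least one assigned term in each
#' generation (after normalization and inventory matching); only then is
#' the joint distribution over parent-child term pairs defined. This is
#' the same criterion used to select the cross-linguistic sample.
#'
#' @param data A kin term table (possibly many systems).
#' @param inventory A [kin_inventory()].
#' @param quiet Suppress the kept/dropped message.
#' @return The rows of `data` belonging to analysable systems. The ids of
#'   dropped systems are attached as `attr(, "dropped")`.
#' @export
filter_analysable <- function(data, inventory, quiet = FALSE) {
  data <- as_kin_terms(data, inventory, warn = !quiet)
  g1 <- inv_codes(inventory, "G+1")
  g0 <- inv_codes(inventory, "G0")
  ok <- vapply(split(data, data$system_id), function(sys) {
    any(sys$kin_type %in% g1) && any(sys$kin_type %in% g0)
  }, logical(1))
  kept_ids <- names(ok)[ok]
  dropped <- names(ok)[!ok]
  if (!quiet)
    message("filter_analysable: kept ", length(kept_ids), " of ",
            length(ok), " systems (dropped ", length(dropped), ")")
  out <- data[data$system_id %in% kept_ids, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
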