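#' Column-mapping dialect for kin term files
#'
#' Kinbank exports and derived deposits name their columns differently;
#' a dialect maps whatever the file calls them onto the package's
#' canonical `system_id` / `kin_type` / `term` (plus optional metadata
#' columns carried through).
#'
#' @param system_id,kin_type,term Column names in the source file.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @param keep Optional character vector of extra columns to carry through
#'   (e.g. glottocode, family).
#' @return A list of class `kin_dialect`.
#' @export
kin_dialect <- function(system_id = "language_id", kin_type = "kin_type",
                        term = "form", delim = ",", keep = character()) {
  structure(list(system_id = system_id, kin_type = kin_type, term = term,
                 delim = delim, keep = keep), class = "kin_dialect")
}

#' Read kin term tables from delimited UTF-8 files
#'
#' Reads one or more Kinbank-dialect files into the package's long term
#' table. Kin type codes outside the inventory are dropped with a warning;
#' rows whose form normalizes to empty are dropped; multiple forms listed
#' for the same (system, kin type) are resolved by `synonyms`.
#'
#' @param path One or more file paths.
#' @param inventory A [kin_inventory()].
#' @param dialect A [kin_dialect()] describing the columns.
#' @param synonyms `"first"` keeps the first listed form (source row
#'   order); `"error"` fails on any duplicate so curation issues surface.
#' @return A kin term tibble (`system_id`, `kin_type`, `term`, any `keep`
#'   columns).
#' @export
read_kin_terms <- function(path, inventory, dialect = kin_dialect(),
                           synonyms = c("first", "error")) {
  synonyms <- match.arg(synonyms)
  raw <- purrr::map_dfr(path, function(p) {
    readr::read_delim(p, delim = dialect$delim, show_col_types = FALSE,
                      progress = FALSE)
  })
  if (nrow(raw) == 0) stop_kin("empty term table: ", paste(path, collapse = ", "))
  need <- c(dialect$system_id, dialect$kin_type, dialect$term)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop_kin("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  out <- tibble::tibble(
    system_id = as.character(raw[[dialect$system_id]]),
    kin_type = as.character(raw[[dialect$kin_type]]),
    term = as.character(raw[[dialect$term]])
  )
  for (col in intersect(dialect$keep, names(raw))) out[[col]] <- raw[[col]]
  if (any(is.na(out$system_id) | out$system_id == "") ||
      any(is.na(out$kin_type) | out$kin_type == ""))
    stop_kin("system_id and kin_type must be non-empty")
  out <- as_kin_terms(out, inventory)
  dup <- duplicated(out[c("system_id", "kin_type")])
  if (any(dup)) {
    if (synonyms == "error")
      stop_kin("multiple forms listed for: ",
               paste(utils::head(unique(paste(out$system_id[dup],
                                              out$kin_type[dup])), 5),
                     collapse = "; "))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Write a result table as UTF-8 CSV
#'
#' Thin, schema-stable writer used for every output table: column order is
#' preserved, encoding is UTF-8, and an empty table yields a header-only
#' file. Tables round-trip through [readr::read_csv()] without loss.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kin_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
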