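#' The eight artificial kinship system types
#'
#' Each trial of the generalisation experiment presents one of eight
#' underlying kinship systems that differ in which distinctions are drawn
#' among the four aunt/uncle referents (MZ, MB, FZ, FB); mother and father
#' always carry unique terms. The shipped defaults are documented
#' reconstructions, grouped as:
#'
#' \describe{
#'   \item{Type I}{no distinctions: all four aunts/uncles share a term.}
#'   \item{Type II}{one two-way split: by side (`II_side`: maternal vs
#'     paternal), by gender (`II_gen`: aunts vs uncles), or by parallel vs
#'     cross relative (`II_opp`: parent's same-gender sibling MZ+FB vs
#'     opposite-gender sibling MB+FZ).}
#'   \item{Type III}{one aunt/uncle singled out against the remaining
#'     three (`III_fb`, `III_mz`, `III_mb`, `III_fz`).}
#' }
#'
#' @return A tibble with columns `type_id`, `group` (`"I"`, `"II"`,
#'   `"III"`) and `partition` (list-column of character-vector term
#'   classes over the four aunt/uncle codes).
#' @export
kin_system_types <- function() {
  tibble::tibble(
    type_id = c("I", "II_side", "II_gen", "II_opp",
                "III_fb", "III_mz", "III_mb", "III_fz"),
    group = c("I", "II", "II", "II", "III", "III", "III", "III"),
    partition = list(
      list(c("MZ", "MB", "FZ", "FB")),
      list(c("MZ", "MB"), c("FZ", "FB")),
      list(c("MZ", "FZ"), c("MB", "FB")),
      list(c("MZ", "FB"), c("MB", "FZ")),
      list("FB", c("MZ", "MB", "FZ")),
      list("MZ", c("MB", "FZ", "FB")),
      list("MB", c("MZ", "FZ", "FB")),
      list("FZ", c("MZ", "MB", "FB"))
    )
  )
}

# G0 children of each G+1 class-unit in the 16-referent tree. The parental
# unit {M, F} jointly parents the two siblings; each aunt/uncle parents
# its own son and daughter.
unit_children <- function(g1_class) {
  if (all(c("M", "F") %in% g1_class)) return(c("B", "Z"))
  as.vector(t(outer(g1_class, c("S", "D"), paste0)))
}

#' Generate a pool of artificial kin term labels
#'
#' Random pronounceable CV(C) forms, pairwise distinct, in the style of
#' the experiment's artificial languages.
#'
#' @param n Number of forms.
#' @param syllables Syllables per form (2 or 3 chosen at random when
#'   length 2).
#' @return A character vector of `n` distinct forms (uses the current RNG
#'   state).
#' @export
make_label_pool <- function(n = 10, syllables = 2:3) {
  cons <- c("p", "t", "k", "b", "d", "g", "m", "n", "s", "z", "l", "r",
            "w", "v", "f", "h")
  vow <- c("a", "e", "i", "o", "u", "y")
  out <- character(0)
  while (length(out) < n) {
    k <- if (length(syllables) > 1) sample(syllables, 1) else syllables
    form <- paste0(sample(cons, k, replace = TRUE),
                   sample(vow, k, replace = TRUE), collapse = "")
    if (!form %in% out) out <- c(out, form)
  }
  out
}

#' Build one generalisation-experiment trial
#'
#' Constructs the stimulus state for a single trial: all six G+1 referents
#' are labelled according to the system type's term classes, a hidden
#' predictive map assigns one designated G0 form to each class-unit with
#' children (the parental unit and each aunt/uncle class), and exactly two
#' G0 referents from different units are revealed with their designated
#' form. The revealed labels are thus consistent with a maximally
#' predictive completion while leaving the remaining distinctions open.
#' The participant's four candidate labels are the two revealed G0 forms
#' plus two novel forms from the pool.
#'
#' @param type_id One of the eight [kin_system_types()] ids.
#' @param label_pool Character vector of at least
#'   `number of G+1 classes + 4` distinct forms; 10 random forms are
#'   generated when `NULL`.
#' @param types The system-type table (override to use custom partitions).
#' @return An object of class `kin_trial`: a list with `type_id`,
#'   `g1_labels` (named over M, F, MZ, MB, FZ, FB), `given_g0` (named,
#'   length 2), `candidates` (length 4: two given + two novel),
#'   `label_pool`, and the `hidden_map` used in construction.
#' @examples
#' set.seed(1)
#' build_trial("I")
#' @export
build_trial <- function(type_id, label_pool = NULL,
                        types = kin_system_types()) {
  row <- types[types$type_id == type_id, ]
  if (nrow(row) != 1) stop_kin("unknown system type: ", type_id)
  aunt_classes <- row$partition[[1]]
  classes <- c(list("M", "F"), aunt_classes)
  units <- c(list(c("M", "F")), aunt_classes)
  if (is.null(label_pool)) label_pool <- make_label_pool(10)
  label_pool <- unique(normalize_term(label_pool))
  if (length(label_pool) < length(classes) + 4)
    stop_kin("label pool too small: need at least ",
             length(classes) + 4, " distinct forms")
  if (length(units) < 2)
    stop_kin("need at least two G+1 class-units with children")

  pool <- sample(label_pool)
  class_labels <- pool[seq_along(classes)]
  pool <- pool[-seq_along(classes)]
  g1_labels <- stats::setNames(
    rep(class_labels, lengths(classes))[order(unlist(classes))],
    sort(unlist(classes)))
  g1_labels <- g1_labels[c("M", "F", "MZ", "MB", "FZ", "FB")]

  hidden <- stats::setNames(pool[seq_along(units)], seq_along(units))
  pool <- pool[-seq_along(units)]

  reveal_units <- sample(seq_along(units), 2)
  given_refs <- vapply(reveal_units, function(u) {
    kids <- unit_children(units[[u]])
    kids[sample.int(length(kids), 1)]
  }, character(1))
  given_g0 <- stats::setNames(unname(hidden[as.character(reveal_units)]),
                              given_refs)

  candidates <- sample(c(unname(given_g0), pool[seq_len(2)]))

  structure(list(type_id = type_id, g1_labels = g1_labels,
                 given_g0 = given_g0, candidates = candidates,
                 label_pool = label_pool,
                 hidden_map = stats::setNames(
                   unname(hidden),
                   vapply(units, paste, "", collapse = "+"))),
            class = "kin_trial")
}

#' @export
print.kin_trial <- function(x, ...) {
  cat("<kin_trial> type", x$type_id, "\n")
  cat("  G+1:", paste(names(x$g1_labels), x$g1_labels, sep = "=",
                      collapse = " "), "\n")
  cat("  given G0:", paste(names(x$given_g0), x$given_g0, sep = "=",
                           collapse = " "), "\n")
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

# The ten G0 referents of the experiment tree, in display order.
g0_referents <- function() {
  c("B", "Z", "MZS", "MZD", "MBS", "MBD", "FZS", "FZD", "FBS", "FBD")
}

# Gender-paired duos: referents differing only in gender.
gender_duos <- function() {
  list(c("B", "Z"), c("MZS", "MZD"), c("MBS", "MBD"),
       c("FZS", "FZD"), c("FBS", "FBD"))
}
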