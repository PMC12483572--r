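#' Typological analysis of predictive structure
#'
#' The corpus-level pipeline: apply the analysability filter, compute each
#' system's entropy profile, run the symmetric-conditional-entropy
#' permutation test against each system's bespoke baseline, and summarise
#' the classification percentages.
#'
#' @param data A kin term table (or a file path readable by
#'   [read_kin_terms()] with the given `dialect`).
#' @param inventory A [kin_inventory()].
#' @param n_permutations,seed,threshold,mode As in [kin_permtest()].
#' @param dialect Used only when `data` is a path.
#' @param out_dir Optional directory; result tables are written there as
#'   UTF-8 CSV (`entropy.csv`, `predictive_structure.csv`,
#'   `summary.csv`).
#' @return A list with `entropy` (per-system entropy table), `results`
#'   (per-system permutation table), `summary` (classification
#'   percentages), and `dropped` (non-analysable system ids).
#' @export
run_typology <- function(data, inventory = kin_inventory("default"),
                         n_permutations = 1000, seed = 1, threshold = 1.96,
                         mode = c("z", "percentile"),
                         dialect = kin_dialect(), out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(data))
    data <- read_kin_terms(data, inventory, dialect)
  kept <- filter_analysable(data, inventory, quiet = TRUE)
  dropped <- attr(kept, "dropped")
  if (nrow(kept) == 0) stop_kin("no analysable systems in corpus")
  message("typology: ", length(unique(kept$system_id)), " analysable systems (",
          length(dropped), " dropped), ", n_permutations,
          " permutations, seed ", seed)
  ent <- entropy_profile(kept, inventory)
  res <- predictive_structure(kept, inventory,
                              n_permutations = n_permutations, seed = seed,
                              threshold = threshold, mode = mode)
  summ <- classification_summary(res)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_kin_table(ent, file.path(out_dir, "entropy.csv"))
    write_kin_table(res, file.path(out_dir, "predictive_structure.csv"))
    write_kin_table(summ, file.path(out_dir, "summary.csv"))
  }
  list(entropy = ent, results = res, summary = summ, dropped = dropped)
}

#' Joint predictive-structure and compositionality analysis
#'
#' Runs both corpus statistics -- symmetric conditional entropy and mean
#' normalized parent-child edit distance -- against their permutation
#' baselines and joins the two z-scores per system, the table behind the
#' entropy-vs-compositionality cross-plot.
#'
#' @inheritParams run_typology
#' @return A list with `entropy_results`, `distance_results`, `joint`
#'   (one row per analysable system with both z-scores and
#'   classifications) and the two classification summaries.
#' @export
run_composition <- function(data, inventory = kin_inventory("default"),
                            n_permutations = 1000, seed = 1,
                            threshold = 1.96, mode = c("z", "percentile"),
                            dialect = kin_dialect(), out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(data))
    data <- read_kin_terms(data, inventory, dialect)
  kept <- filter_analysable(data, inventory, quiet = TRUE)
  if (nrow(kept) == 0) stop_kin("no analysable systems in corpus")
  ent <- predictive_structure(kept, inventory,
                              n_permutations = n_permutations,
                              seed = seed, threshold = threshold,
                              mode = mode)
  dist <- compositionality(kept, inventory, n_permutations = n_permutations,
                           seed = seed, threshold = threshold, mode = mode)
  joint <- dplyr::inner_join(
    dplyr::select(ent, "system_id", h_sym = "observed", h_sym_z = "z",
                  h_sym_class = "classification"),
    dplyr::select(dist, "system_id", edit_distance = "observed",
                  edit_distance_z = "z",
                  edit_distance_class = "classification"),
    by = "system_id")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_kin_table(joint, file.path(out_dir, "composition_joint.csv"))
    write_kin_table(ent, file.path(out_dir, "predictive_structure.csv"))
    write_kin_table(dist, file.path(out_dir, "compositionality.csv"))
  }
  list(entropy_results = ent, distance_results = dist, joint = joint,
       entropy_summary = classification_summary(ent),
       distance_summary = classification_summary(dist))
}

#' Full analysis of a generalisation-experiment response set
#'
#' Codes every choice for predictive generalisation, summarises the
#' proportion of predictive choices per system type, scores each
#' completed system against its permutation baseline, and produces the
#' co-occurrence and gender-distinction tables.
#'
#' @inheritParams code_choices
#' @param n_permutations,seed,threshold As in [participant_entropy()].
#' @param out_dir Optional directory for the CSV outputs.
#' @return A list: `coded`, `proportions` (per system type),
#'   `participant_z`, `cooccurrence`, `gender`, and `z_summary`.
#' @export
run_experiment <- function(responses, trials, n_permutations = 1000,
                           seed = 1, threshold = 1.96, out_dir = NULL) {
  coded <- code_choices(responses, trials)
  props <- proportion_predictive(coded, .data$system_type)
  pz <- participant_entropy(responses, trials,
                            n_permutations = n_permutations, seed = seed,
                            threshold = threshold)
  cooc <- cooccurrence(responses, trials)
  gend <- gender_distinctions(responses, trials)
  message("experiment: ", length(unique(coded$participant_id)),
          " participants, ", nrow(pz), " completed trials, ",
          n_permutations, " permutations, seed ", seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_kin_table(coded, file.path(out_dir, "coded_choices.csv"))
    write_kin_table(props, file.path(out_dir, "proportions.csv"))
    write_kin_table(pz, file.path(out_dir, "participant_z.csv"))
    write_kin_table(cooc, file.path(out_dir, "cooccurrence.csv"))
    write_kin_table(gend, file.path(out_dir, "gender_distinctions.csv"))
  }
  list(coded = coded, proportions = props, participant_z = pz,
       cooccurrence = cooc, gender = gend,
       z_summary = classification_summary(pz))
}
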