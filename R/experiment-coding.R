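#' Coding experiment responses for predictive generalisation
#'
#' For every label a participant (or simulated agent) assigns to a
#' referent, the coder asks: among the four candidate labels, did this
#' choice produce the greatest possible decrease in symmetric conditional
#' entropy of the partial kinship system, given the labels fixed so far
#' (the G+1 labels, the given G0 labels, and the participant's earlier
#' choices in that trial)? A choice is coded `predictive = 1` when it lies
#' in the argmin set of the four candidates' resulting entropies (ties
#' count as predictive; `n_argmin` records the tie size so analyses can
#' exclude tied choices), `0` otherwise. The partial-system entropy uses
#' only links whose two endpoints are both labelled.
#'
#' @param responses A response table: `participant_id`, `trial_id`,
#'   `referent`, `chosen_form`, `selection_index` (plus `system_type`,
#'   carried through).
#' @param trials A trial table as produced by [simulate_experiment()]:
#'   `participant_id`, `trial_id` and a `trial` list-column of
#'   [build_trial()] objects.
#' @param tol Numerical tolerance for entropy ties (bits).
#' @return `responses` with columns `predictive` (0/1), `n_argmin`, and
#'   `h_after` (the entropy realised by the chosen label).
#' @export
code_choices <- function(responses, trials, tol = 1e-9) {
  responses <- tibble::as_tibble(responses)
  links <- kin_inventory("experiment16")$links
  key <- paste(responses$participant_id, responses$trial_id)
  purrr::map_dfr(split(responses, factor(key, unique(key))), function(rs) {
    trial <- lookup_trial(trials, rs$participant_id[1], rs$trial_id[1])
    rs <- rs[order(rs$selection_index), , drop = FALSE]
    labelled <- trial$given_g0
    rs$predictive <- NA_real_
    rs$n_argmin <- NA_integer_
    rs$h_after <- NA_real_
    for (i in seq_len(nrow(rs))) {
      ref <- rs$referent[i]
      chosen <- rs$chosen_form[i]
      if (ref %in% names(labelled))
        stop_kin("participant ", rs$participant_id[1], " trial ",
                 rs$trial_id[1], ": referent ", ref, " already labelled")
      if (!chosen %in% trial$candidates)
        stop_kin("participant ", rs$participant_id[1], " trial ",
                 rs$trial_id[1], ": chosen form \"", chosen,
                 "\" is not a candidate")
      ents <- choice_entropies(trial, labelled, ref, links)
      amin <- ents <= min(ents) + tol
      rs$predictive[i] <- as.numeric(amin[[match(chosen, trial$candidates)]])
      rs$n_argmin[i] <- sum(amin)
      rs$h_after[i] <- ents[[match(chosen, trial$candidates)]]
      labelled[ref] <- chosen
    }
    missing <- setdiff(g0_referents(), names(labelled))
    if (length(missing) > 0)
      stop_kin("participant ", rs$participant_id[1], " trial ",
               rs$trial_id[1], ": incomplete trial, unanswered referents: ",
               paste(missing, collapse = ", "))
    rs
  })
}

lookup_trial <- function(trials, participant_id, trial_id) {
  hit <- which(trials$participant_id == participant_id &
                 trials$trial_id == trial_id)
  if (length(hit) != 1)
    stop_kin("no unique trial record for participant ", participant_id,
             ", trial ", trial_id)
  trials$trial[[hit]]
}

# h_sym of each candidate label for `referent`, given current labels.
choice_entropies <- function(trial, labelled, referent, links = NULL) {
  if (is.null(links)) links <- kin_inventory("experiment16")$links
  vapply(trial$candidates, function(cand) {
    g0 <- c(labelled, stats::setNames(cand, referent))
    partial_hsym(trial$g1_labels, g0, links)
  }, numeric(1))
}

partial_hsym <- function(g1_labels, g0_assign, links) {
  keep <- links$child %in% names(g0_assign)
  hsym_pairs(unname(g1_labels[links$parent[keep]]),
             unname(g0_assign[links$child[keep]]))
}

#' Proportion of predictive generalisations
#'
#' @param coded Output of [code_choices()].
#' @param ... Grouping columns (tidy-select style), e.g. `system_type`.
#' @param unique_argmin_only Restrict to choices with a unique
#'   entropy-minimising candidate (`n_argmin == 1`); with four candidates,
#'   chance performance on these choices is 25\%.
#' @return A tibble with the grouping columns, `n_choices` and
#'   `prop_predictive`.
#' @export
proportion_predictive <- function(coded, ..., unique_argmin_only = FALSE) {
  if (nrow(coded) == 0) stop_kin("no coded choices")
  if (unique_argmin_only) coded <- coded[coded$n_argmin == 1, , drop = FALSE]
  if (nrow(coded) == 0) stop_kin("no choices left after argmin filter")
  dplyr::summarise(dplyr::group_by(coded, ...),
                   n_choices = dplyr::n(),
                   prop_predictive = mean(.data$predictive),
                   .groups = "drop")
}

#' Completed kinship systems from experiment responses
#'
#' Combines the given G0 labels of each trial with the participant's
#' choices into the full 16-referent system, in long kin-term-table form
#' (one `system_id` per participant-trial).
#'
#' @inheritParams code_choices
#' @return A tibble: `participant_id`, `trial_id`, `system_type`,
#'   `system_id`, `kin_type`, `term`.
#' @export
completed_systems <- function(responses, trials) {
  responses <- tibble::as_tibble(responses)
  key <- paste(responses$participant_id, responses$trial_id)
  purrr::map_dfr(split(responses, factor(key, unique(key))), function(rs) {
    trial <- lookup_trial(trials, rs$participant_id[1], rs$trial_id[1])
    g0 <- c(trial$given_g0, stats::setNames(rs$chosen_form, rs$referent))
    missing <- setdiff(g0_referents(), names(g0))
    if (length(missing) > 0)
      stop_kin("participant ", rs$participant_id[1], " trial ",
               rs$trial_id[1], ": incomplete trial (missing ",
               paste(missing, collapse = ", "), ")")
    assign <- c(trial$g1_labels, g0[g0_referents()])
    tibble::tibble(participant_id = rs$participant_id[1],
                   trial_id = rs$trial_id[1],
                   system_type = trial$type_id,
                   system_id = paste(rs$participant_id[1],
                                     rs$trial_id[1], sep = ":"),
                   kin_type = names(assign), term = unname(assign))
  })
}

#' Permutation z-scores for participants' completed systems
#'
#' Scores each completed trial system exactly as the cross-linguistic
#' analysis scores a language: its symmetric conditional entropy is
#' compared against permutations that reshuffle which G0 referents carry
#' which forms (multiset preserved). By default all ten G0 labels --
#' given and chosen -- participate in the shuffle; `scope = "chosen"`
#' holds the given labels fixed.
#'
#' @inheritParams code_choices
#' @param n_permutations,threshold,mode As in [kin_permtest()].
#' @param seed Root seed; per participant-trial streams are derived from
#'   it.
#' @param scope `"all"` (default) or `"chosen"`.
#' @return A tibble with one row per participant-trial: ids,
#'   `system_type`, `observed`, `baseline_mean`, `baseline_sd`, `z`,
#'   `classification`.
#' @export
participant_entropy <- function(responses, trials, n_permutations = 1000,
                                seed = 1, scope = c("all", "chosen"),
                                threshold = 1.96,
                                mode = c("z", "percentile")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  links <- kin_inventory("experiment16")$links
  refs <- g0_referents()
  child_idx <- match(links$child, refs)
  completed <- completed_systems(responses, trials)
  purrr::map_dfr(split(completed, factor(completed$system_id,
                                         unique(completed$system_id))),
                 function(sys) {
    trial <- lookup_trial(trials, sys$participant_id[1], sys$trial_id[1])
    a <- stats::setNames(sys$term, sys$kin_type)
    f <- unname(a[refs])
    parent_terms <- unname(a[links$parent])
    scope_idx <- if (scope == "all") seq_along(refs) else
      which(!refs %in% names(trial$given_g0))
    set.seed(derive_seed(seed, sys$system_id[1]))
    observed <- hsym_pairs(parent_terms, f[child_idx])
    baseline <- vapply(seq_len(n_permutations), function(i) {
      f2 <- f
      f2[scope_idx] <- f2[scope_idx][sample.int(length(scope_idx))]
      hsym_pairs(parent_terms, f2[child_idx])
    }, numeric(1))
    pt <- summarise_permtest(observed, baseline, "h_sym", n_permutations,
                             derive_seed(seed, sys$system_id[1]),
                             threshold, mode, sys$system_id[1])
    dplyr::mutate(generics::tidy(pt),
                  participant_id = sys$participant_id[1],
                  trial_id = sys$trial_id[1],
                  system_type = sys$system_type[1],
                  .before = 1)
  })
}

#' Exhaustive minimum-entropy completion of a trial
#'
#' Searches every assignment of the four candidate labels to the
#' unlabelled G0 referents (at most 4^8 = 65,536 states) and returns the
#' global minimum symmetric conditional entropy together with every
#' completion attaining it. This is the normative yardstick: a maximally
#' predictive participant ends each trial at exactly this entropy.
#'
#' @param trial A [build_trial()] object.
#' @param tol Tie tolerance in bits.
#' @return A list: `min_h_sym`, `completions` (tibble, one row per
#'   minimizer, one column per unlabelled referent), `n_evaluated`.
#' @export
ideal_completion <- function(trial, tol = 1e-9) {
  links <- kin_inventory("experiment16")$links
  refs <- g0_referents()
  unl <- setdiff(refs, names(trial$given_g0))
  k <- length(unl)
  cand <- trial$candidates
  assign <- c(trial$given_g0, stats::setNames(rep(NA_character_, k), unl))
  child_pos <- match(links$child, names(assign))
  parent_terms <- unname(trial$g1_labels[links$parent])
  fill <- length(trial$given_g0) + seq_len(k)
  combos <- as.matrix(expand.grid(rep(list(seq_along(cand)), k),
                                  KEEP.OUT.ATTRS = FALSE))
  vals <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    assign[fill] <- cand[combos[i, ]]
    vals[i] <- hsym_pairs(parent_terms, unname(assign[child_pos]))
  }
  mn <- min(vals)
  hit <- which(vals <= mn + tol)
  completions <- tibble::as_tibble(matrix(cand[combos[hit, , drop = FALSE]],
                                          nrow = length(hit),
                                          dimnames = list(NULL, unl)))
  list(min_h_sym = mn, completions = completions,
       n_evaluated = nrow(combos))
}

#' Referent co-occurrence proportions
#'
#' For each pair of G0 referents, the proportion of completed
#' participant-trials in which the two referents carry the same label.
#' The diagonal is 1 by definition and the matrix is symmetric.
#'
#' @inheritParams code_choices
#' @param by Optional grouping column of the completed-system table
#'   (default `"system_type"`; use `NULL` to pool everything).
#' @return A long tibble: grouping column (if any), `referent_i`,
#'   `referent_j` (factors in tree order), `proportion`.
#' @seealso [plot_cooccurrence()]
#' @export
cooccurrence <- function(responses, trials, by = "system_type") {
  completed <- completed_systems(responses, trials)
  refs <- g0_referents()
  groups <- if (is.null(by)) list(all = completed) else
    split(completed, completed[[by]])
  if (length(groups) == 0) stop_kin("no completed trials")
  purrr::imap_dfr(groups, function(grp, gname) {
    mats <- lapply(split(grp, grp$system_id), function(sys) {
      a <- stats::setNames(sys$term, sys$kin_type)[refs]
      outer(a, a, "==") * 1
    })
    m <- Reduce(`+`, mats) / length(mats)
    out <- tibble::tibble(
      referent_i = factor(rep(refs, times = length(refs)), levels = refs),
      referent_j = factor(rep(refs, each = length(refs)), levels = refs),
      proportion = as.vector(m))
    if (!is.null(by)) out <- dplyr::mutate(out, !!by := gname, .before = 1)
    out
  })
}

#' Gender-distinction coding of completed systems
#'
#' For each gender-paired duo of G0 referents (brother/sister and each
#' aunt/uncle's son/daughter), codes 1 when the completed system gives the
#' two referents different terms, 0 when they share a term.
#'
#' @inheritParams code_choices
#' @return A tibble: `participant_id`, `trial_id`, `system_type`, `duo`
#'   (e.g. `"MBS/MBD"`), `distinguished` (0/1).
#' @export
gender_distinctions <- function(responses, trials) {
  completed <- completed_systems(responses, trials)
  duos <- gender_duos()
  purrr::map_dfr(split(completed, factor(completed$system_id,
                                         unique(completed$system_id))),
                 function(sys) {
    a <- stats::setNames(sys$term, sys$kin_type)
    tibble::tibble(
      participant_id = sys$participant_id[1],
      trial_id = sys$trial_id[1],
      system_type = sys$system_type[1],
      duo = vapply(duos, paste, "", collapse = "/"),
      distinguished = vapply(duos, function(d)
        as.numeric(a[[d[1]]] != a[[d[2]]]), numeric(1)))
  })
}
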