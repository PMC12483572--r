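#' Specification for a synthetic kinship-terminology corpus
#'
#' The generator emulates the statistical structure the cross-linguistic
#' analysis assumes: each language partitions its G+1 kin types into term
#' classes, and its G0 terms either follow the parent classes (predictive
#' regime) or are drawn independently (null regime), governed by a single
#' mixing parameter.
#'
#' @param n_languages Number of systems to generate.
#' @param n_g1_terms Number of distinct G+1 terms (classes); must not
#'   exceed the inventory's G+1 types.
#' @param n_g0_terms Size of the G0 term pool; must be at least
#'   `n_g1_terms` (the base map class -> G0 term is injective).
#' @param predictiveness rho in [0, 1]: the probability that a G0 kin type
#'   takes its parent class's designated term rather than a uniform draw
#'   from the pool. rho = 1 yields maximally predictive systems for the
#'   class layout; rho = 0 makes G0 labels independent of parent class.
#' @param missingness Per-assignment erasure probability in [0, 1);
#'   applied independently to every (kin type, term) cell after
#'   generation.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `kin_corpus_spec`.
#' @export
corpus_spec <- function(n_languages = 100, n_g1_terms = 8, n_g0_terms = 8,
                        predictiveness = 1, missingness = 0, seed = 1) {
  stopifnot(n_languages >= 1, n_g1_terms >= 1, n_g0_terms >= 1,
            predictiveness >= 0, predictiveness <= 1,
            missingness >= 0, missingness < 1)
  if (n_g0_terms < n_g1_terms)
    stop_kin("n_g0_terms must be >= n_g1_terms (injective base map)")
  structure(list(n_languages = n_languages, n_g1_terms = n_g1_terms,
                 n_g0_terms = n_g0_terms, predictiveness = predictiveness,
                 missingness = missingness, seed = seed),
            class = "kin_corpus_spec")
}

#' Generate a synthetic corpus of kinship systems
#'
#' For each language: G+1 kin types are partitioned uniformly into
#' `n_g1_terms` non-empty classes, each class gets a distinct term form;
#' an injective base map assigns each class a designated G0 form from a
#' pool of `n_g0_terms`; every G0 kin type then takes the designated form
#' of its (canonical, first-linked) parent's class with probability
#' `predictiveness`, otherwise a uniform draw from the pool; finally each
#' assignment is erased independently with probability `missingness`.
#' The per-slot resampling noise model is a simple stand-in that is
#' monotone in the mixing parameter, not a model of historical kin-term
#' change.
#'
#' @param spec A [corpus_spec()].
#' @param inventory A [kin_inventory()] (default the 30-type preset).
#' @param style `"random"` draws unrelated G0 forms; `"suffix"` builds
#'   each class's designated G0 form as the class's G+1 form plus `"za"`,
#'   producing a morphologically compositional corpus.
#' @return A kin term tibble (`system_id`, `kin_type`, `term`). Ground
#'   truth -- the mixing parameter and each language's class layout,
#'   which the analysis path must never see -- is attached as
#'   `attr(, "truth")` and written to a separate file by [write_corpus()].
#' @examples
#' corp <- simulate_corpus(corpus_spec(n_languages = 3, seed = 42))
#' dplyr::count(corp, system_id)
#' @export
simulate_corpus <- function(spec, inventory = kin_inventory("default"),
                            style = c("random", "suffix")) {
  style <- match.arg(style)
  stopifnot(inherits(spec, "kin_corpus_spec"))
  g1 <- inv_codes(inventory, "G+1")
  g0 <- inv_codes(inventory, "G0")
  if (spec$n_g1_terms > length(g1))
    stop_kin("n_g1_terms exceeds the number of G+1 kin types")
  links <- inventory$links
  canon_parent <- vapply(g0, function(cd)
    links$parent[match(cd, links$child)], character(1))
  set.seed(spec$seed)
  out <- vector("list", spec$n_languages)
  truth <- vector("list", spec$n_languages)
  width <- nchar(as.character(spec$n_languages))
  for (i in seq_len(spec$n_languages)) {
    id <- sprintf("lang%0*d", width, i)
    k <- spec$n_g1_terms
    # uniform surjection: k random representatives, the rest uniform
    cls <- sample.int(k, length(g1), replace = TRUE)
    cls[sample.int(length(g1), k)] <- sample.int(k)
    g1_forms <- make_label_pool(k, syllables = 2:3)
    if (style == "suffix") {
      pool <- paste0(g1_forms, "za")
      base_map <- seq_len(k)
    } else {
      pool <- make_label_pool(spec$n_g0_terms)
      base_map <- sample.int(spec$n_g0_terms, k)
    }
    g1_assign <- g1_forms[cls]
    parent_cls <- cls[match(canon_parent, g1)]
    use_base <- stats::runif(length(g0)) < spec$predictiveness
    g0_assign <- ifelse(use_base, pool[base_map[parent_cls]],
                        pool[sample.int(length(pool), length(g0),
                                        replace = TRUE)])
    tbl <- tibble::tibble(system_id = id,
                          kin_type = c(g1, g0),
                          term = c(g1_assign, g0_assign))
    if (spec$missingness > 0)
      tbl <- tbl[stats::runif(nrow(tbl)) >= spec$missingness, , drop = FALSE]
    out[[i]] <- tbl
    truth[[i]] <- tibble::tibble(
      system_id = id, predictiveness = spec$predictiveness,
      n_g1_terms = k, n_g0_terms = length(pool),
      class_layout = paste(g1, cls, sep = "=", collapse = ";"))
  }
  corpus <- dplyr::bind_rows(out)
  attr(corpus, "truth") <- dplyr::bind_rows(truth)
  corpus
}

#' @rdname simulate_corpus
#' @param corpus A corpus from [simulate_corpus()].
#' @param dir Output directory; `terms.csv` (the analysable table) and
#'   `truth.csv` (generator ground truth) are written separately so the
#'   analysis path never reads the truth.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_kin_table(corpus, file.path(dir, "terms.csv"))
  truth <- attr(corpus, "truth")
  if (!is.null(truth)) write_kin_table(truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Simulated respondent policies for the generalisation experiment
#'
#' @param kind `"random"` chooses uniformly among the four candidates;
#'   `"predictive_greedy"` chooses uniformly among the candidates that
#'   minimise the partial system's symmetric conditional entropy at each
#'   step; `"gender_biased"` first (with probability `gender_weight`)
#'   restricts the candidates to those preserving a terminological gender
#'   distinction with the already-labelled opposite-gender sibling of the
#'   same parents, then acts predictively within the restriction.
#' @param gender_weight g in [0, 1]; only used by `"gender_biased"`.
#' @return A list of class `kin_agent_policy`.
#' @export
agent_policy <- function(kind = c("random", "predictive_greedy",
                                  "gender_biased"),
                         gender_weight = 1) {
  kind <- match.arg(kind)
  stopifnot(gender_weight >= 0, gender_weight <= 1)
  structure(list(kind = kind, gender_weight = gender_weight),
            class = "kin_agent_policy")
}

#' Simulate participants completing the generalisation experiment
#'
#' Each simulated participant completes one trial per system type (eight
#' trials), with a fresh random label pool per trial and referents
#' highlighted in a fresh random order, mirroring the experimental
#' procedure.
#'
#' @param n_participants Number of agents.
#' @param policy An [agent_policy()].
#' @param seed Integer root seed.
#' @param types System-type table (default [kin_system_types()]).
#' @return A list with `trials` (tibble: `participant_id`, `trial_id`,
#'   `system_type`, `trial` list-column) and `responses` (tibble:
#'   `participant_id`, `trial_id`, `system_type`, `referent`,
#'   `chosen_form`, `selection_index`).
#' @examples
#' sim <- simulate_experiment(2, agent_policy("predictive_greedy"), seed = 7)
#' head(sim$responses)
#' @export
simulate_experiment <- function(n_participants,
                                policy = agent_policy("random"),
                                seed = 1, types = kin_system_types()) {
  stopifnot(inherits(policy, "kin_agent_policy"), n_participants >= 1)
  set.seed(seed)
  links <- kin_inventory("experiment16")$links
  trials <- list()
  responses <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("agent%03d", p)
    for (type_id in sample(types$type_id)) {
      trial <- build_trial(type_id, types = types)
      rs <- simulate_trial_responses(trial, policy, links)
      rs$participant_id <- pid
      rs$trial_id <- type_id
      rs$system_type <- type_id
      trials[[length(trials) + 1]] <-
        tibble::tibble(participant_id = pid, trial_id = type_id,
                       system_type = type_id, trial = list(trial))
      responses[[length(responses) + 1]] <- rs
    }
  }
  list(trials = dplyr::bind_rows(trials),
       responses = dplyr::bind_rows(responses)[
         , c("participant_id", "trial_id", "system_type", "referent",
             "chosen_form", "selection_index")])
}

simulate_trial_responses <- function(trial, policy, links, tol = 1e-9) {
  labelled <- trial$given_g0
  order_refs <- sample(setdiff(g0_referents(), names(labelled)))
  duos <- gender_duos()
  out <- vector("list", length(order_refs))
  for (i in seq_along(order_refs)) {
    ref <- order_refs[i]
    cands <- trial$candidates
    if (policy$kind == "random") {
      chosen <- cands[sample.int(length(cands), 1)]
    } else {
      restricted <- cands
      if (policy$kind == "gender_biased" &&
          stats::runif(1) < policy$gender_weight) {
        duo <- duos[vapply(duos, function(d) ref %in% d, logical(1))][[1]]
        partner <- setdiff(duo, ref)
        if (partner %in% names(labelled)) {
          keep <- cands != labelled[[partner]]
          if (any(keep)) restricted <- cands[keep]
        }
      }
      ents <- vapply(restricted, function(cand)
        partial_hsym(trial$g1_labels,
                     c(labelled, stats::setNames(cand, ref)), links),
        numeric(1))
      amin <- which(ents <= min(ents) + tol)
      chosen <- restricted[amin[sample.int(length(amin), 1)]]
    }
    labelled[ref] <- chosen
    out[[i]] <- tibble::tibble(referent = ref, chosen_form = chosen,
                               selection_index = i)
  }
  dplyr::bind_rows(out)
}
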