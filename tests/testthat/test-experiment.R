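# A fixed, hand-checkable Type-I-like trial: all aunts/uncles share "pa",
# given labels reveal the hidden map on B (sibling) and MZS (cousin).
fixed_trial <- function() {
  structure(list(
    type_id = "I",
    g1_labels = c(M = "ma", F = "fa", MZ = "pa", MB = "pa",
                  FZ = "pa", FB = "pa"),
    given_g0 = c(B = "sib", MZS = "kuz"),
    candidates = c("sib", "kuz", "nov1", "nov2"),
    label_pool = c("ma", "fa", "pa", "sib", "kuz", "nov1", "nov2",
                   "x1", "x2", "x3"),
    hidden_map = c("M+F" = "sib", "MZ+MB+FZ+FB" = "kuz")),
    class = "kin_trial")
}

fixed_responses <- function(choices) {
  refs <- setdiff(g0_referents(), c("B", "MZS"))
  tibble::tibble(participant_id = "p1", trial_id = "I", system_type = "I",
                 referent = refs, chosen_form = choices,
                 selection_index = seq_along(refs))
}

fixed_trials_tbl <- function() {
  tibble::tibble(participant_id = "p1", trial_id = "I", system_type = "I",
                 trial = list(fixed_trial()))
}

test_that("the eight system types partition the aunts/uncles as designed", {
  st <- kin_system_types()
  expect_equal(nrow(st), 8)
  expect_setequal(st$group, c("I", "II", "III"))
  for (i in seq_len(nrow(st))) {
    members <- sort(unlist(st$partition[[i]]))
    expect_equal(members, c("FB", "FZ", "MB", "MZ"))
  }
  expect_equal(lengths(st$partition),
               c(1, 2, 2, 2, 2, 2, 2, 2), ignore_attr = TRUE)
})

test_that("trial construction satisfies the design constraints for every type", {
  set.seed(14)
  for (type_id in kin_system_types()$type_id) {
    for (r in 1:5) {
      tr <- build_trial(type_id)
      # all six G+1 referents labelled, mother and father distinct
      expect_length(tr$g1_labels, 6)
      expect_false(tr$g1_labels[["M"]] == tr$g1_labels[["F"]])
      # labels respect the type's partition
      part <- kin_system_types()$partition[[
        match(type_id, kin_system_types()$type_id)]]
      for (cls in part)
        expect_length(unique(tr$g1_labels[cls]), 1)
      # exactly 4 candidates, exactly 2 of them given
      expect_length(tr$candidates, 4)
      expect_length(unique(tr$candidates), 4)
      expect_equal(sum(tr$candidates %in% tr$given_g0), 2)
      # 2 given labels, distinct forms, from different class-units
      expect_length(tr$given_g0, 2)
      expect_length(unique(tr$given_g0), 2)
    }
  }
  expect_error(build_trial("I", label_pool = c("a", "b", "c")), "pool")
  expect_error(build_trial("nope"), "unknown")
})

test_that("choice coding recovers predictive and non-predictive choices in a fixed state", {
  trial <- fixed_trial()
  # first highlighted referent: MZD, sibling cousin of a same-class parent
  ents <- kinpredict:::choice_entropies(trial, trial$given_g0, "MZD")
  expect_equal(unname(which.min(ents)), match("kuz", trial$candidates))
  # extending the cousin term is uniquely optimal here
  expect_equal(sum(ents <= min(ents) + 1e-9), 1)

  # code a full predictive completion: every cousin "kuz", Z = "sib"
  refs <- setdiff(g0_referents(), c("B", "MZS"))
  choices <- ifelse(refs == "Z", "sib", "kuz")
  coded <- code_choices(fixed_responses(choices), fixed_trials_tbl())
  expect_equal(coded$predictive, rep(1, 8))

  # choosing a novel form for MZD merges nothing: non-predictive
  bad <- ifelse(refs == "MZD", "nov1", choices)
  coded_bad <- code_choices(fixed_responses(bad), fixed_trials_tbl())
  expect_equal(coded_bad$predictive[coded_bad$referent == "MZD"], 0)
  # merging children of terminologically distinct G+1 classes when a
  # within-class merge is available is non-predictive
  worse <- ifelse(refs == "MZD", "sib", choices)
  coded_worse <- code_choices(fixed_responses(worse), fixed_trials_tbl())
  expect_equal(coded_worse$predictive[coded_worse$referent == "MZD"], 0)
})

test_that("choice coding validates its inputs", {
  refs <- setdiff(g0_referents(), c("B", "MZS"))
  ok <- fixed_responses(rep("kuz", 8))
  bad_cand <- ok; bad_cand$chosen_form[3] <- "zzz"
  expect_error(code_choices(bad_cand, fixed_trials_tbl()), "not a candidate")
  relab <- ok; relab$referent[2] <- "B"
  expect_error(code_choices(relab, fixed_trials_tbl()), "already labelled")
  incomplete <- ok[-5, ]
  expect_error(code_choices(incomplete, fixed_trials_tbl()),
               "p1 trial I.*incomplete")
})

test_that("choice coding is invariant under relabelling of forms", {
  set.seed(22)
  sim <- simulate_experiment(2, agent_policy("random"), seed = 5)
  coded <- code_choices(sim$responses, sim$trials)
  # bijectively rename every form in trials and responses
  forms <- unique(c(unlist(lapply(sim$trials$trial, `[[`, "label_pool")),
                    sim$responses$chosen_form))
  rename <- stats::setNames(paste0("w", seq_along(forms)), forms)
  trials2 <- sim$trials
  trials2$trial <- lapply(trials2$trial, function(tr) {
    tr$g1_labels[] <- rename[tr$g1_labels]
    tr$given_g0[] <- rename[tr$given_g0]
    tr$candidates <- unname(rename[tr$candidates])
    tr$label_pool <- unname(rename[tr$label_pool])
    tr
  })
  resp2 <- sim$responses
  resp2$chosen_form <- unname(rename[resp2$chosen_form])
  coded2 <- code_choices(resp2, trials2)
  expect_equal(coded2$predictive, coded$predictive)
  expect_equal(coded2$n_argmin, coded$n_argmin)
  expect_equal(coded2$h_after, coded$h_after)
})

test_that("proportion tables aggregate predictive flags", {
  flags <- tibble::tibble(predictive = c(1, 1, 0, 1), n_argmin = 1,
                          system_type = "I")
  expect_equal(proportion_predictive(flags)$prop_predictive, 0.75)
  expect_equal(proportion_predictive(flags, system_type)$n_choices, 4L)
  expect_error(proportion_predictive(flags[0, ]), "no coded")
})

test_that("greedy agents reach the exhaustive minimum and are fully predictive", {
  sim <- simulate_experiment(1, agent_policy("predictive_greedy"), seed = 33)
  coded <- code_choices(sim$responses, sim$trials)
  expect_equal(mean(coded$predictive), 1)
  completed <- completed_systems(sim$responses, sim$trials)
  inv16 <- kin_inventory("experiment16")
  for (tid in unique(sim$trials$trial_id)) {
    trial <- sim$trials$trial[[match(tid, sim$trials$trial_id)]]
    ic <- ideal_completion(trial)
    sys <- completed[completed$trial_id == tid, ]
    h <- entropy_profile(dplyr::transmute(sys, system_id, kin_type, term),
                         inv16)$h_sym
    expect_equal(h, ic$min_h_sym, tolerance = 1e-9)
    # all reported minimizers attain the minimum
    pick <- ic$completions[sample.int(nrow(ic$completions), 1), ]
    full <- tibble::tibble(
      system_id = "chk",
      kin_type = c(names(trial$g1_labels), names(trial$given_g0),
                   names(pick)),
      term = c(unname(trial$g1_labels), unname(trial$given_g0),
               unlist(pick, use.names = FALSE)))
    expect_equal(entropy_profile(full, inv16)$h_sym, ic$min_h_sym,
                 tolerance = 1e-9)
  }
})

test_that("participant permutation scores behave at the endpoints", {
  sim <- simulate_experiment(2, agent_policy("predictive_greedy"), seed = 9)
  pz <- participant_entropy(sim$responses, sim$trials,
                            n_permutations = 300, seed = 6)
  expect_equal(nrow(pz), 16)
  # greedy completions sit at the minimum: never above baseline
  expect_true(all(pz$z <= 0))
  # scope = "chosen" keeps given labels fixed but still scores
  pz2 <- participant_entropy(sim$responses, sim$trials,
                             n_permutations = 100, seed = 6,
                             scope = "chosen")
  expect_equal(nrow(pz2), 16)
  # reproducibility
  pz3 <- participant_entropy(sim$responses, sim$trials,
                             n_permutations = 300, seed = 6)
  expect_equal(pz, pz3)
})

test_that("co-occurrence matrices are symmetric with unit diagonal", {
  sim <- simulate_experiment(3, agent_policy("random"), seed = 41)
  co <- cooccurrence(sim$responses, sim$trials)
  expect_true(all(co$proportion >= 0 & co$proportion <= 1))
  diag <- co[as.character(co$referent_i) == as.character(co$referent_j), ]
  expect_true(all(diag$proportion == 1))
  wide <- tidyr::pivot_wider(co[co$system_type == "I", ],
                             names_from = "referent_j",
                             values_from = "proportion")
  m <- as.matrix(wide[, levels(co$referent_j)])
  expect_equal(m, t(m), ignore_attr = TRUE)

  # greedy agents on Type I merge all eight cousins
  simg <- simulate_experiment(2, agent_policy("predictive_greedy"),
                              seed = 12)
  cog <- cooccurrence(simg$responses, simg$trials)
  cousins <- setdiff(g0_referents(), c("B", "Z"))
  cc <- cog[cog$system_type == "I" &
              as.character(cog$referent_i) %in% cousins &
              as.character(cog$referent_j) %in% cousins, ]
  expect_true(all(cc$proportion == 1))
})

test_that("gender coding flags exactly the distinguished duos", {
  refs <- setdiff(g0_referents(), c("B", "MZS"))
  # all cousins get "kuz", Z gets "sib": no duo distinguished except none
  same <- code_choices(fixed_responses(ifelse(refs == "Z", "sib", "kuz")),
                       fixed_trials_tbl())
  g_same <- gender_distinctions(
    fixed_responses(ifelse(refs == "Z", "sib", "kuz")), fixed_trials_tbl())
  expect_equal(sum(g_same$distinguished), 0)
  # distinguish MZS/MZD only
  g_mix <- gender_distinctions(
    fixed_responses(ifelse(refs == "MZD", "nov1",
                           ifelse(refs == "Z", "sib", "kuz"))),
    fixed_trials_tbl())
  expect_equal(g_mix$distinguished[g_mix$duo == "MZS/MZD"], 1)
  expect_equal(sum(g_mix$distinguished), 1)
})
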