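test_that("joint distribution assigns uniform link weights and accumulates identical pairs", {
  inv <- kin_inventory("experiment16")
  # four links, each parent term pairing with exactly one child term
  sys <- tibble::tibble(system_id = "s",
                        kin_type = c("MZ", "MB", "MZS", "MZD", "MBS", "MBD"),
                        term = c("a", "b", "x", "x", "y", "y"))
  d <- pair_distribution(sys, inv)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$p), c(0.5, 0.5))
  expect_equal(sum(d$n), 4)

  fun <- pair_distribution(funcle_system(), inv)
  expect_equal(dplyr::arrange(as.data.frame(fun[1:4]), child_term),
               data.frame(parent_term = c("funcle", "funcle"),
                          child_term = c("brother", "cousin"),
                          n = c(1L, 1L), p = c(0.5, 0.5)),
               ignore_attr = TRUE)
  # marginals equal the joint slices, total mass 1
  expect_equal(sum(fun$p), 1)

  no_g0 <- tibble::tibble(system_id = "s", kin_type = c("M", "F"),
                          term = c("a", "b"))
  expect_error(pair_distribution(no_g0, inv), "analysable")
})

test_that("conditional entropies match the worked toys", {
  inv <- kin_inventory("experiment16")
  fun <- pair_distribution(funcle_system(), inv)
  expect_equal(conditional_entropy(fun, "child_given_parent"), 1.0)
  expect_equal(conditional_entropy(fun, "parent_given_child"), 0.0)

  # deterministic mapping: each parent term -> a single child term
  det <- tibble::tibble(system_id = "s",
                        kin_type = c("MZ", "MB", "MZS", "MBS"),
                        term = c("a", "b", "x", "y"))
  expect_equal(conditional_entropy(pair_distribution(det, inv),
                                   "child_given_parent"), 0)

  # uniform independent 2 x 2: 1 bit in each direction
  u <- tibble::tibble(system_id = "s",
                      kin_type = c("MZ", "MB", "MZS", "MZD", "MBS", "MBD"),
                      term = c("a", "b", "x", "y", "x", "y"))
  ud <- pair_distribution(u, inv)
  expect_equal(conditional_entropy(ud, "child_given_parent"), 1)
  expect_equal(conditional_entropy(ud, "parent_given_child"), 1)
})

test_that("symmetric conditional entropy hits the endpoint examples", {
  inv0 <- kin_inventory("default")
  expect_equal(entropy_profile(bijective_system(), inv0)$h_sym, 0)

  inv <- kin_inventory("experiment16")
  expect_equal(entropy_profile(funcle_system(), inv)$h_sym, 1)
  u <- tibble::tibble(system_id = "s",
                      kin_type = c("MZ", "MB", "MZS", "MZD", "MBS", "MBD"),
                      term = c("a", "b", "x", "y", "x", "y"))
  expect_equal(entropy_profile(u, inv)$h_sym, 2)
})

test_that("entropy agrees with the pair-list oracle on random small systems", {
  set.seed(101)
  inv <- kin_inventory("experiment16")
  for (i in 1:200) {
    sys <- random_small_system(n_g1_forms = sample(1:4, 1),
                               n_g0_forms = sample(1:4, 1),
                               p_missing = 0.25)
    tp <- term_pairs(sys, inv)
    prof <- entropy_profile(sys, inv)
    expect_equal(prof$h_sym, oracle_hsym(tp$parent_term, tp$child_term),
                 tolerance = 1e-9)
    d <- pair_distribution(sys, inv)
    expect_equal(conditional_entropy(d, "child_given_parent"),
                 oracle_cond(tp$parent_term, tp$child_term,
                             "child_given_parent"), tolerance = 1e-9)
    expect_equal(conditional_entropy(d, "parent_given_child"),
                 oracle_cond(tp$parent_term, tp$child_term,
                             "parent_given_child"), tolerance = 1e-9)
    # h_sym decomposes into the two directions
    expect_equal(prof$h_sym,
                 prof$h_child_given_parent + prof$h_parent_given_child,
                 tolerance = 1e-9)
  }
})

test_that("h_sym = 0 exactly when the pair support is a one-to-one matching", {
  set.seed(77)
  inv <- kin_inventory("experiment16")
  seen_zero <- FALSE
  seen_pos <- FALSE
  for (i in 1:120) {
    sys <- random_small_system(n_g1_forms = sample(1:3, 1),
                               n_g0_forms = sample(1:3, 1))
    tp <- term_pairs(sys, inv)
    support <- unique(tp[c("parent_term", "child_term")])
    matching <- !anyDuplicated(support$parent_term) &&
      !anyDuplicated(support$child_term)
    h <- entropy_profile(sys, inv)$h_sym
    if (matching) {
      expect_equal(h, 0, tolerance = 1e-12)
      seen_zero <- TRUE
    } else {
      expect_gt(h, 1e-9)
      seen_pos <- TRUE
    }
  }
  expect_true(seen_zero && seen_pos)
})

test_that("entropy bounds, renaming invariance, and merge monotonicity hold", {
  set.seed(55)
  inv <- kin_inventory("experiment16")
  for (i in 1:40) {
    sys <- random_small_system(n_g1_forms = 3, n_g0_forms = 4,
                               p_missing = 0.1)
    tp <- term_pairs(sys, inv)
    prof <- entropy_profile(sys, inv)
    expect_gte(prof$h_child_given_parent, 0)
    expect_lte(prof$h_child_given_parent,
               log2(length(unique(tp$child_term))) + 1e-12)
    expect_lte(prof$h_parent_given_child,
               log2(length(unique(tp$parent_term))) + 1e-12)

    ren <- sys
    ren$term <- paste0("W", match(ren$term, unique(sys$term)))
    expect_equal(entropy_profile(ren, inv)$h_sym, prof$h_sym,
                 tolerance = 1e-12)

    # merging two child terms (relabelling one into another) never
    # increases H(child | parent)
    g0_forms <- unique(sys$term[grepl("^c", sys$term)])
    if (length(g0_forms) >= 2) {
      merged <- sys
      merged$term[merged$term == g0_forms[1]] <- g0_forms[2]
      expect_lte(entropy_profile(merged, inv)$h_child_given_parent,
                 prof$h_child_given_parent + 1e-9)
    }
  }
})

test_that("a shared string across generations stays role-indexed in the marginals", {
  inv <- kin_inventory("experiment16")
  # same string "kaka" for an aunt and for her children
  sys <- tibble::tibble(system_id = "s",
                        kin_type = c("MZ", "MB", "MZS", "MZD", "MBS", "MBD"),
                        term = c("kaka", "ina", "kaka", "kaka", "ina", "ina"))
  prof <- entropy_profile(sys, inv)
  expect_equal(prof$h_sym, 0)  # support is still a perfect matching
})
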