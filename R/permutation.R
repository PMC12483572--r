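#' Randomly permute a system's G0 term assignment
#'
#' The null model behind every baseline in the package: shuffle which G0
#' kin types carry which term forms, preserving the multiset of forms and
#' the missingness pattern exactly. Only G0 kin types that already carry a
#' term participate; missing slots stay missing, so the permuted system is
#' analysable whenever the original is and the number of observed links is
#' unchanged. G+1 assignments are untouched.
#'
#' @param data A kin term table for one system.
#' @param inventory A [kin_inventory()].
#' @return A tibble like `data` with G0 terms permuted uniformly at random
#'   (uses the current RNG state; seed with [set.seed()] or a wrapper).
#' @export
permute_g0 <- function(data, inventory) {
  data <- as_kin_terms(data, inventory)
  g0 <- inv_codes(inventory, "G0")
  slot <- data$kin_type %in% g0
  if (!any(slot)) stop_kin("no assigned G0 terms to permute")
  data$term[slot] <- data$term[slot][sample.int(sum(slot))]
  data
}

#' Monte-Carlo permutation test for a kinship-system statistic
#'
#' Compares an observed per-system statistic against its distribution over
#' random reassignments of G0 terms to kin types (see [permute_g0()]),
#' summarised as a z-score: how many baseline standard deviations the
#' observed value lies from the baseline mean. Systems whose statistic
#' lies more than `threshold` standard deviations below the mean are
#' classified `significantly_low` (for `statistic = "h_sym"` this is the
#' signature of predictive structure; for `"edit_distance"`, of
#' compositional wordforms), above as `significantly_high`, else
#' `not_significant`. If the baseline has zero spread -- e.g. a system
#' with a single G0 term, where every permutation is identical -- the
#' z-score is defined as 0.
#'
#' @param data A kin term table for a single system.
#' @param inventory A [kin_inventory()].
#' @param statistic `"h_sym"` (symmetric conditional entropy),
#'   `"edit_distance"` (mean normalized parent-child edit distance), or a
#'   function `(data, inventory) -> double` evaluated on each permuted
#'   table.
#' @param n_permutations Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer seed; the test is fully reproducible given
#'   (data, statistic, n_permutations, seed).
#' @param threshold z threshold for classification (default 1.96, the
#'   two-sided 5\% normal cutoff).
#' @param mode `"z"` classifies by z-score; `"percentile"` classifies by
#'   the observed value's position among the permuted values (below the
#'   5th / above the 95th empirical percentile).
#' @return An object of class `kin_permtest`: observed value, baseline
#'   mean/sd, z, classification, the baseline draws, and the call
#'   parameters. Use [generics::tidy()] / [generics::glance()] for a
#'   one-row tibble, `autoplot()` for the baseline histogram.
#' @examples
#' inv <- kin_inventory("experiment16")
#' eng <- tibble::tibble(system_id = "english",
#'   kin_type = c("M", "F", "MZ", "MB", "FZ", "FB", "B", "Z",
#'                "MZS", "MZD", "MBS", "MBD", "FZS", "FZD", "FBS", "FBD"),
#'   term = c("mother", "father", "aunt", "uncle", "aunt", "uncle",
#'            "brother", "sister", rep("cousin", 8)))
#' kin_permtest(eng, inv, "h_sym", n_permutations = 200, seed = 1)
#' @export
kin_permtest <- function(data, inventory, statistic = "h_sym",
                         n_permutations = 1000, seed = NULL,
                         threshold = 1.96, mode = c("z", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 1, threshold > 0)
  data <- as_kin_terms(data, inventory)
  if (length(unique(data$system_id)) != 1)
    stop_kin("kin_permtest expects a single system")
  # canonicalise row order so results never depend on input row order
  data <- data[!duplicated(data$kin_type), , drop = FALSE]
  data <- data[order(match(data$kin_type, inventory$types$code)), ,
               drop = FALSE]
  if (!is.null(seed)) set.seed(seed)

  if (is.function(statistic)) {
    observed <- statistic(data, inventory)
    baseline <- vapply(seq_len(n_permutations), function(i)
      statistic(permute_g0(data, inventory), inventory), numeric(1))
    stat_name <- "custom"
  } else {
    stat_name <- match.arg(statistic, c("h_sym", "edit_distance"))
    eng <- perm_engine_setup(data, inventory, stat_name)
    observed <- eng$stat(eng$child_terms)
    m <- length(eng$child_terms)
    baseline <- vapply(seq_len(n_permutations), function(i)
      eng$stat(eng$child_terms[sample.int(m)]), numeric(1))
  }

  summarise_permtest(observed, baseline, stat_name, n_permutations,
                     seed, threshold, mode,
                     system_id = data$system_id[1])
}

# Precompute everything needed to evaluate the statistic on a permutation
# of the assigned-G0-slot term vector. child_idx maps each retained link
# to a G0 slot; permuting slot terms and indexing reproduces permute_g0.
perm_engine_setup <- function(data, inventory, stat_name) {
  a <- assignment_vector(data)
  g0 <- intersect(names(a), inv_codes(inventory, "G0"))
  if (length(g0) == 0) stop_kin("no assigned G0 terms")
  links <- inventory$links
  keep <- links$parent %in% names(a) & links$child %in% names(a)
  if (!any(keep))
    stop_kin("system is not analysable: no observed term pairs")
  parent_terms <- unname(a[links$parent[keep]])
  child_idx <- match(links$child[keep], g0)
  child_terms <- unname(a[g0])
  if (stat_name == "h_sym") {
    stat <- function(slots) hsym_pairs(parent_terms, slots[child_idx])
  } else {
    up <- unique(parent_terms); us <- unique(child_terms)
    dmat <- normalized_levenshtein_matrix(up, us)
    ip <- match(parent_terms, up)
    is0 <- match(child_terms, us)
    stat <- function(slots) {
      # slots is a permutation of child_terms; recover indices cheaply
      mean(dmat[cbind(ip, match(slots, us)[child_idx])])
    }
  }
  list(stat = stat, child_terms = child_terms, parent_terms = parent_terms,
       child_idx = child_idx)
}

summarise_permtest <- function(observed, baseline, statistic,
                               n_permutations, seed, threshold, mode,
                               system_id = NA_character_) {
  m <- mean(baseline)
  s <- stats::sd(baseline)
  z <- if (is.na(s) || s == 0) 0 else (observed - m) / s
  classification <- if (mode == "z") {
    classify_z(z, threshold)
  } else {
    lo <- stats::quantile(baseline, 0.05, names = FALSE, type = 1)
    hi <- stats::quantile(baseline, 0.95, names = FALSE, type = 1)
    if (s == 0) "not_significant"
    else if (observed < lo) "significantly_low"
    else if (observed > hi) "significantly_high"
    else "not_significant"
  }
  structure(list(system_id = system_id, statistic = statistic,
                 observed = observed, baseline_mean = m,
                 baseline_sd = if (is.na(s)) 0 else s, z = z,
                 classification = classification,
                 n_permutations = n_permutations,
                 seed = seed, threshold = threshold, mode = mode,
                 baseline = baseline),
            class = "kin_permtest")
}

#' @export
print.kin_permtest <- function(x, ...) {
  cat("<kin_permtest> statistic:", x$statistic,
      if (!is.na(x$system_id)) paste0("(system ", x$system_id, ")"), "\n")
  cat(sprintf("  observed %.4f | baseline %.4f +/- %.4f over %d permutations\n",
              x$observed, x$baseline_mean, x$baseline_sd, x$n_permutations))
  cat(sprintf("  z = %.3f -> %s\n", x$z, x$classification))
  invisible(x)
}

#' Corpus-level permutation test of predictive structure
#'
#' Runs the symmetric-conditional-entropy permutation test on every
#' analysable system in a corpus. Each system gets its own RNG stream
#' derived deterministically from `seed` and its `system_id`, so results
#' do not depend on corpus order.
#'
#' @param data A kin term table (many systems).
#' @param inventory A [kin_inventory()].
#' @param statistic Passed to [kin_permtest()] (default `"h_sym"`).
#' @param n_permutations,threshold,mode As in [kin_permtest()].
#' @param seed Root integer seed.
#' @return A tibble with one row per analysable system: `system_id`,
#'   `observed`, `baseline_mean`, `baseline_sd`, `z`, `classification`,
#'   `n_permutations`, `seed` (the derived per-system seed).
#' @seealso [classification_summary()], [plot_z_distribution()]
#' @export
predictive_structure <- function(data, inventory, statistic = "h_sym",
                                 n_permutations = 1000, seed = 1,
                                 threshold = 1.96,
                                 mode = c("z", "percentile")) {
  mode <- match.arg(mode)
  data <- filter_analysable(data, inventory, quiet = TRUE)
  purrr::map_dfr(split(data, data$system_id), function(sys) {
    s <- derive_seed(seed, sys$system_id[1])
    generics::tidy(kin_permtest(sys, inventory, statistic,
                                n_permutations = n_permutations, seed = s,
                                threshold = threshold, mode = mode))
  })
}

#' Summarise permutation classifications across a corpus
#'
#' @param results A tibble from [predictive_structure()] or
#'   [compositionality()].
#' @return A tibble with `classification`, `n`, `percent` (including zero
#'   rows for unobserved classes).
#' @export
classification_summary <- function(results) {
  lv <- c("significantly_low", "not_significant", "significantly_high")
  tb <- table(factor(results$classification, levels = lv))
  tibble::tibble(classification = lv, n = as.integer(tb),
                 percent = 100 * as.integer(tb) / max(1L, nrow(results)))
}
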