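#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x A [kin_permtest()] object.
#' @param ... Unused.
#' @return A one-row tibble: `system_id`, `statistic`, `observed`,
#'   `baseline_mean`, `baseline_sd`, `z`, `classification`,
#'   `n_permutations`, `seed`.
#' @method tidy kin_permtest
#' @export
tidy.kin_permtest <- function(x, ...) {
  tibble::tibble(system_id = x$system_id, statistic = x$statistic,
                 observed = x$observed, baseline_mean = x$baseline_mean,
                 baseline_sd = x$baseline_sd, z = x$z,
                 classification = x$classification,
                 n_permutations = x$n_permutations,
                 seed = x$seed %||% NA_integer_)
}

#' @rdname tidy.kin_permtest
#' @return `glance()` returns a one-row tibble: `observed`, `z`,
#'   `classification`, `n_permutations`.
#' @method glance kin_permtest
#' @export
glance.kin_permtest <- function(x, ...) {
  tibble::tibble(observed = x$observed, z = x$z,
                 classification = x$classification,
                 n_permutations = x$n_permutations)
}
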