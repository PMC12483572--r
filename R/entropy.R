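#' Joint distribution over parent-child term pairs
#'
#' Builds the probability distribution p(T1, T0) over (parent term, child
#' term) pairs for one kinship system: each observed parent-child link
#' contributes equal weight 1/N, and identical term pairs accumulate. The
#' two generations' term alphabets are role-indexed: a string used in both
#' generations is one label inside a joint cell but contributes to each
#' generation's marginal separately, because the conditional entropies
#' condition on role (parent vs child), not on string identity.
#'
#' @param data A kin term table for a single system.
#' @param inventory A [kin_inventory()].
#' @return A tibble of class `kin_pair_distribution` with columns
#'   `parent_term`, `child_term`, `n` (links realising the pair) and `p`;
#'   `attr(, "n_pairs")` holds the number of contributing links.
#' @examples
#' inv <- kin_inventory("experiment16")
#' funcle <- tibble::tibble(system_id = "toy",
#'   kin_type = c("F", "FB", "B", "FBS"),
#'   term = c("funcle", "funcle", "brother", "cousin"))
#' pair_distribution(funcle, inv)
#' @export
pair_distribution <- function(data, inventory) {
  pairs <- term_pairs(data, inventory)
  if (length(unique(pairs$system_id)) > 1)
    stop_kin("pair_distribution expects a single system; got ",
             length(unique(pairs$system_id)))
  if (nrow(pairs) == 0)
    stop_kin("system is not analysable: no observed parent-child term pairs")
  out <- dplyr::count(pairs, .data$parent_term, .data$child_term)
  out$p <- out$n / sum(out$n)
  attr(out, "n_pairs") <- sum(out$n)
  class(out) <- c("kin_pair_distribution", class(out))
  out
}

#' Conditional entropy of one generation's terms given the other's
#'
#' Computes \eqn{-\sum p(T_0,T_1)\,\log_2 p(T_0,T_1)/p(T_c)} where
#' \eqn{T_c} is the conditioning term (the parent term for direction
#' `"child_given_parent"`, the child term otherwise). Cells with zero
#' probability contribute 0; the result is in bits.
#'
#' @param dist A [pair_distribution()] table.
#' @param direction `"child_given_parent"` (how uncertain the child's term
#'   is once the parent's term is known) or `"parent_given_child"`.
#' @return A single non-negative number of bits.
#' @export
conditional_entropy <- function(dist,
                                direction = c("child_given_parent",
                                              "parent_given_child")) {
  direction <- match.arg(direction)
  cond <- if (direction == "child_given_parent") dist$parent_term else
    dist$child_term
  marg <- tapply(dist$p, cond, sum)
  p <- dist$p
  keep <- p > 0
  max(0, -sum(p[keep] * log2(p[keep] / as.numeric(marg[cond])[keep])))
}

#' Symmetric conditional entropy of a kinship system
#'
#' The package's measure of predictive structure: the sum of the
#' conditional entropy of Ego's generation's terms given the parents'
#' generation's terms and vice versa, over parent-child term pairs. It is
#' 0 bits exactly when every term in each generation is uniquely specified
#' by a term in the other (a perfectly mutually predictive system), and
#' grows as cross-generation prediction becomes less reliable.
#'
#' @param data A kin term table; one row per system is returned, so the
#'   table may contain many systems.
#' @param inventory A [kin_inventory()].
#' @return A tibble with one row per analysable system: `system_id`,
#'   `h_child_given_parent`, `h_parent_given_child`, `h_sym` (all bits)
#'   and `n_pairs`. Systems failing the analysability filter raise an
#'   error for single-system input and are dropped with a message
#'   otherwise.
#' @examples
#' inv <- kin_inventory("experiment16")
#' funcle <- tibble::tibble(system_id = "toy",
#'   kin_type = c("F", "FB", "B", "FBS"),
#'   term = c("funcle", "funcle", "brother", "cousin"))
#' entropy_profile(funcle, inv)
#' @export
entropy_profile <- function(data, inventory) {
  data <- as_kin_terms(data, inventory)
  ids <- unique(data$system_id)
  single <- length(ids) == 1
  res <- purrr::map_dfr(split(data, data$system_id), function(sys) {
    pc <- system_pair_terms(sys, inventory)
    if (is.null(pc)) {
      if (single) stop_kin("system ", sys$system_id[1],
                           " is not analysable: no observed term pairs")
      return(tibble::tibble())
    }
    h <- hsym_core(pc$parent_term, pc$child_term)
    tibble::tibble(system_id = sys$system_id[1],
                   h_child_given_parent = h[["child_given_parent"]],
                   h_parent_given_child = h[["parent_given_child"]],
                   h_sym = h[["child_given_parent"]] +
                     h[["parent_given_child"]],
                   n_pairs = length(pc$parent_term))
  })
  if (!single && length(ids) > nrow(res))
    message("entropy_profile: dropped ", length(ids) - nrow(res),
            " non-analysable system(s)")
  res
}

# Observed (parent_term, child_term) vectors for one pre-validated system,
# or NULL when no link has both endpoints assigned.
system_pair_terms <- function(sys, inventory) {
  a <- assignment_vector(sys)
  links <- inventory$links
  keep <- links$parent %in% names(a) & links$child %in% names(a)
  if (!any(keep)) return(NULL)
  list(parent_term = unname(a[links$parent[keep]]),
       child_term = unname(a[links$child[keep]]))
}

# Fast entropy core shared by the corpus path and the permutation engine.
# Direct evaluation of the conditional-entropy sum on tabulated counts.
hsym_core <- function(parent, child) {
  u1 <- unique(parent); u0 <- unique(child)
  i1 <- match(parent, u1); i0 <- match(child, u0)
  k1 <- length(u1); k0 <- length(u0)
  n <- length(i1)
  nj <- tabulate((i1 - 1L) * k0 + i0, nbins = k1 * k0)
  pos <- which(nj > 0L)
  pj <- nj[pos] / n
  p1 <- tabulate(i1, nbins = k1) / n
  p0 <- tabulate(i0, nbins = k0) / n
  row1 <- ((pos - 1L) %/% k0) + 1L
  col0 <- ((pos - 1L) %% k0) + 1L
  c(child_given_parent = max(0, -sum(pj * log2(pj / p1[row1]))),
    parent_given_child = max(0, -sum(pj * log2(pj / p0[col0]))))
}

# h_sym from two aligned term vectors (used in permutation loops).
hsym_pairs <- function(parent, child) {
  h <- hsym_core(parent, child)
  h[[1]] + h[[2]]
}
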