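# Independent oracles and tiny fixture builders shared across tests.

# Levenshtein by memoized recursion, independent of the package's path.
oracle_lev <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    r <- min(rec(i - 1, j) + 1,
             rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (av[i] != bv[j]))
    memo[[key]] <- r
    r
  }
  rec(length(av), length(bv))
}

# Symmetric conditional entropy from an explicit pair list, via the
# chain-rule identity H(X|Y) = H(X,Y) - H(Y) on table() counts.
oracle_hsym <- function(parent, child) {
  n <- length(parent)
  H <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log2(p))
  }
  hj <- H(as.numeric(table(paste(parent, child, sep = "\r"))))
  (hj - H(as.numeric(table(parent)))) + (hj - H(as.numeric(table(child))))
}

# Both conditional entropies, same route.
oracle_cond <- function(parent, child, direction) {
  n <- length(parent)
  H <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log2(p))
  }
  hj <- H(as.numeric(table(paste(parent, child, sep = "\r"))))
  if (direction == "child_given_parent")
    hj - H(as.numeric(table(parent)))
  else hj - H(as.numeric(table(child)))
}

# All permutations of a vector (n <= 7).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# A tiny custom inventory: 2 parents, 1 uncle, 3 children, 3 links
# (hand-enumerable).
toy_inventory <- function() {
  new_kin_inventory(
    types = tibble::tibble(
      code = c("P1", "P2", "U", "C1", "C2", "K"),
      generation = c("G+1", "G+1", "G+1", "G0", "G0", "G0")),
    links = tibble::tibble(parent = c("P1", "P2", "U"),
                           child = c("C1", "C2", "K")))
}

# Random small system on the experiment16 inventory: terms drawn from
# small alphabets, optional missingness, always analysable.
random_small_system <- function(id = "sys", n_g1_forms = 3, n_g0_forms = 3,
                                p_missing = 0) {
  inv <- kin_inventory("experiment16")
  g1 <- inv$types$code[inv$types$generation == "G+1"]
  g0 <- inv$types$code[inv$types$generation == "G0"]
  repeat {
    tbl <- tibble::tibble(
      system_id = id,
      kin_type = c(g1, g0),
      term = c(sample(paste0("p", seq_len(n_g1_forms)), length(g1), TRUE),
               sample(paste0("c", seq_len(n_g0_forms)), length(g0), TRUE)))
    if (p_missing > 0)
      tbl <- tbl[stats::runif(nrow(tbl)) >= p_missing, , drop = FALSE]
    ok <- any(tbl$kin_type %in% g1) && any(tbl$kin_type %in% g0) &&
      nrow(term_pairs(tbl, inv)) > 0
    if (ok) return(tbl)
  }
}

# The funcle toy: father and father's brother share a term; their
# children split into distinct sibling/cousin terms.
funcle_system <- function() {
  tibble::tibble(system_id = "funcle",
                 kin_type = c("F", "FB", "B", "FBS"),
                 term = c("funcle", "funcle", "brother", "cousin"))
}

# A system whose pair support is a one-to-one matching (h_sym = 0) on the
# default inventory: parents share one term, maternal and paternal
# aunts/uncles each their own, children follow their parent class.
bijective_system <- function(id = "bij") {
  aunts <- c("MeB", "MyB", "MeZ", "MyZ", "FeB", "FyB", "FeZ", "FyZ")
  cousins <- as.vector(t(outer(aunts, c("S", "D"), paste0)))
  side <- ifelse(grepl("^M", aunts), "matk", "patk")
  tibble::tibble(
    system_id = id,
    kin_type = c("M", "F", aunts, "eB", "yB", "eZ", "yZ", cousins),
    term = c("par", "par", side, rep("sib", 4), rep(side, each = 2)))
}
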