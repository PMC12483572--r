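---
title: "Measuring predictive structure in kinship terminologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring predictive structure in kinship terminologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(kinpredict)
library(dplyr)
```

## The question and the statistic

Languages differ enormously in how they carve kin relations into named
categories, yet the variation is constrained. One candidate constraint is
*predictive structure*: the category a relative belongs to in one
generation tends to be predictable from the category of their parent or
child in the adjacent generation. A language in which the children of
every "uncle"-class relative are reliably "cousins" is predictively
structured; one in which the child of an uncle might be called any of
four different things is not.

`kinpredict` operationalises this for two generations: Ego's generation
(G0 — siblings and cousins) and the parents' generation (G+1 — parents,
aunts and uncles). Every G0 kin type is linked to its consanguineal
parent type(s): siblings to both mother and father, each cousin to its
connecting aunt or uncle. Over the linked pairs a system induces a joint
distribution $p(T_0, T_1)$ — the probability that a uniformly drawn
parent–child link carries parent term $T_1$ and child term $T_0$. The
statistic is the **symmetric conditional entropy**

$$H_{sym}(G^0; G^{+1}) = H(G^0 \mid G^{+1}) + H(G^{+1} \mid G^0),$$

with each direction the usual conditional entropy in bits,
$H(G^0 \mid G^{+1}) = -\sum p(T_0,T_1)\log_2 p(T_0,T_1)/p(T_1)$.
$H_{sym} = 0$ exactly when the observed term pairs form a one-to-one
matching — every term in each generation uniquely specifies its partner
in the other — and it grows as cross-generation prediction degrades.
Summing the two directions avoids building into the measure any
assumption about the direction in which people predict.

```{r}
inv <- kin_inventory("experiment16")
funcle <- tibble::tibble(
  system_id = "toy",
  kin_type = c("F", "FB", "B", "FBS"),
  term = c("funcle", "funcle", "brother", "cousin"))
entropy_profile(funcle, inv)
```

The toy above merges father and father's brother into one term while
keeping their children distinct: knowing the child's term determines the
parent's (0 bits), but predicting the child from "funcle" costs a full
bit — $H_{sym} = 1$.

### Probability model and missing data

Published cross-linguistic kin term tables do not come with link
weights, so each parent–child kin-type link counts once (uniform
1/N). Missing assignments are handled by pairwise deletion: a link is
dropped when either endpoint lacks a term, and a system enters the
analysis only if it retains at least one term in each generation
(`filter_analysable()`). A term string used in both generations is one
label inside a joint cell but the marginals stay role-indexed, because
the entropies condition on generational role, not on string identity.
Entropy uses base-2 logarithms with $0 \log 0 := 0$.

## The permutation baseline

Raw $H_{sym}$ confounds predictive structure with lexicon size: a system
with two terms can hardly fail to be predictive. Each system is therefore
compared to its own Monte-Carlo null: shuffle which G0 kin types carry
which term forms (`permute_g0()`), preserving the term multiset and the
missingness pattern exactly, recompute the statistic, and summarise the
observed value as a z-score against the permuted distribution
(`kin_permtest()`, 1,000 permutations by default). A system is classified
`significantly_low` when $z < -1.96$ — more predictive structure than its
own term inventory would produce by chance.

Numerical conventions, all of which matter in edge cases:

* **Zero spread.** If every permutation yields the same value (e.g. a
  single G0 term), $z := 0$ and the system is `not_significant`. A
  one-term-per-generation system has $H_{sym} = 0$ *and* $z = 0$: it is
  perfectly predictive but no more so than chance.
* **Permutation scope.** Only G0 types that carry a term are shuffled;
  missing slots stay missing, so the permuted system is always
  analysable and the link count is constant across permutations.
* **Classification mode.** The default reads significance off the
  z-score (`mode = "z"`); `mode = "percentile"` instead compares the
  observed value to the empirical 5th/95th percentiles of the permuted
  values. The two can disagree for skewed baselines, which is why both
  are exposed rather than silently resolved.
* **Seeding.** Corpus runs derive one RNG stream per system from the
  root seed and the system id, so results are independent of corpus
  order and of which other systems are present.

```{r}
corp <- simulate_corpus(corpus_spec(n_languages = 20, n_g1_terms = 6,
                                    n_g0_terms = 6, predictiveness = 1,
                                    seed = 42))
res <- predictive_structure(corp, kin_inventory("default"),
                            n_permutations = 300, seed = 1)
classification_summary(res)
```

## Compositionality as a rival explanation

Predictive structure could be a by-product of morphology: if cousin terms
are built from aunt/uncle terms plus an affix, predictiveness follows for
free. The package therefore also measures wordform similarity between
parent and child terms: the Levenshtein distance (unit-cost edits over
Unicode code points, after NFC normalization) divided by the longer
string's length, averaged over the same link enumeration the entropy
uses, and compared to the same permutation null
(`compositionality()`). Systems with significantly *low* mean distance
are compositional; significantly *high* distance marks systems whose
form resemblances deliberately avoid parent–child pairs (morphemes
encoding, say, shared gender rather than descent). Averaging is
multiplicity-weighted by default — a pair realised on three links counts
three times — with `pairs = "unique"` available since sources are not
explicit about deduplication; orthographic rather than phonemic strings
are used, the two being strongly correlated in practice, and diacritics
count as differences.

## The generalisation experiment

The experimental component asks whether predictive structure emerges
when people extend known kin terms to unlabelled relatives. A trial
presents a 16-referent, two-generation tree (6 G+1, 10 G0). The G+1
labels realise one of eight system types differing in which distinctions
are drawn among the four aunts/uncles (`kin_system_types()`): none
(Type I), one two-way split by side, gender, or parallel/cross
(Type II), or one relative singled out (Type III). Mother and father are
always distinct. Two G0 referents from different class-units are revealed
with labels consistent with a maximally predictive completion; the
respondent labels the remaining eight, choosing per referent among four
candidates — the two revealed forms plus two novel ones. The shipped
partitions, the label-pool generator (random CV syllable forms), and the
"reveal two referents from different units" rule are documented
reconstructions of a standard design of this kind; all are
configuration-level choices, not hard-coded.

Choices are coded sequentially (`code_choices()`): a choice is
*predictive* when, among the four candidates, it yields the greatest
decrease in $H_{sym}$ of the partial system given everything labelled so
far (links with an unlabelled endpoint are excluded, mirroring the
pairwise-deletion rule). Ties are counted as predictive, and the argmin
set size is logged so analyses can restrict to unique-argmin choices —
on those, a uniform-random chooser is correct 25% of the time, which is
the package's calibration check. Completed systems are scored against
permutation baselines exactly like languages
(`participant_entropy()`; by default the shuffle includes the given
labels, with `scope = "chosen"` as the alternative since the
permutation's treatment of given labels is a genuinely open design
point). `ideal_completion()` finds the global entropy minimum by
exhaustive search over the at most $4^8$ candidate assignments, and
`cooccurrence()` / `gender_distinctions()` produce the categorisation
summaries.

```{r}
sim <- simulate_experiment(4, agent_policy("predictive_greedy"), seed = 3)
coded <- code_choices(sim$responses, sim$trials)
proportion_predictive(coded, system_type) |> head(4)
```

## What the synthetic data does and does not emulate

`simulate_corpus()` generates languages by partitioning G+1 types into
term classes, mapping each class injectively to a designated G0 form,
and labelling each G0 type with its (first-linked) parent class's form
with probability $\rho$, otherwise a uniform pool draw; assignments are
then erased at the missingness rate. This reproduces the *statistical*
signature the corpus analysis targets — a monotone relationship between
$\rho$ and the entropy z-score, verified by the parameter-recovery test
($\rho \in \{0, 0.5, 1\}$, 100 languages each, 1,000 permutations) — and
nothing more. Per-slot resampling is not a model of historical kin-term
change; generated forms carry no phylogenetic signal, no areal
structure, no borrowing, and (except in the `style = "suffix"` mode
used to exercise the compositionality path) no morphology. Ground truth
is emitted in a separate table so the analysis path never sees it.
Because siblings link to both parents, a $\rho = 1$ language whose
mother and father fall in different term classes is maximally predictive
*within the generator's class-consistent family* but not always at the
unconstrained entropy minimum; the test suite checks the exact-minimum
property in the regime where it provably holds (parents co-classified,
minimum 0).

Simulated respondents (`agent_policy()`) are intentionally simple:
uniform-random (calibration), greedy entropy-minimising (normative upper
bound), and gender-biased (greedy within a constraint to keep
gender-paired duos distinct). They bound and calibrate the coding
machinery; they are not cognitive models of human participants.

## Problem sizes, defaults, and limitations

Defaults follow the analysis they implement: 1,000 permutations,
threshold $|z| = 1.96$, uniform link weights, synonym policy "first
listed form". The shipped 30-type inventory (10 G+1, 20 G0, 24 links) is
a reconstruction of a typical two-generation kin-type set; real corpora
should declare their own inventory via `read_inventory()` — all
statistics are inventory-relative, and restricting the inventory (e.g.
to the 16 experiment referents) changes every downstream number. The
test suite exercises the pipeline at sizes chosen to be decisive yet
quick: 100-language corpora per $\rho$ level for recovery, 100 random
agents (about 5,000 unique-argmin choices) for coding calibration,
exhaustive $4^8$ searches per trial for the normative minimum.

Known limitations: grandparent/grandchild generations and affinal kin
are out of scope; no multiple-testing correction is applied across
systems (each system is its own hypothesis, as in the analyses this
package supports); the edit-distance measure sees only parent–child
pairs, so morphology encoding anything other than descent registers as
*anti*-compositional; and mixed-effects modelling of coded choices is
deliberately left to the user — the package exports tidy coded tables
rather than model fits.
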