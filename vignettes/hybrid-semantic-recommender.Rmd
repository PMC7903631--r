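---
title: "Hybrid semantic recommendation for ontology-annotated items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid semantic recommendation for ontology-annotated items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ontorec)
```

## The problem

Researchers interact with far more chemical compounds than they can track:
literature mining can tell us which compounds an author has already written
about (implicit feedback — counts of articles, with no negative examples),
and the task is to rank, for each researcher, the thousands of compounds
they have *not* yet touched so that the most relevant ones surface first.

Pure collaborative filtering (CF) handles implicit feedback well but cannot
score an item nobody has rated (item cold-start), and its recommendations
are hard to justify. Compounds, however, live in an ontology — a directed
acyclic graph of `is_a` relations — and semantically close compounds tend
to interest the same researcher. **ontorec** implements a hybrid: a
content-based (CB) scorer driven purely by ontology semantic similarity,
fused with implicit-feedback CF, evaluated under a ranked top-k protocol.

## Semantic similarity

An ontology parsed from OBO (`parse_obo()` / `read_obo()`) yields a DAG
over primary term accessions; secondary accessions (`alt_id`, left behind
by term merges) resolve to their primary term by default. A strict mode
refuses them, reproducing the failure mode of primary-id-only tools — a
real pipeline hazard, since a relevant item hiding behind a secondary id
silently becomes unrecommendable.

Each term gets an intrinsic information content from its descendant count:

IC(t) = −log2( (desc(t) + 1) / N )  bits,

where `desc(t)` counts strict descendants and `N` is the ontology size. A
root subsuming everything has IC 0; leaves carry log2 N bits. The base is
fixed at 2 and matters downstream: Resnik similarities are raw IC values
and enter hybrid fusion unnormalized.

Three pairwise measures are derived from the most informative common
ancestor (MICA), the shared ancestor with maximal IC:

* **Resnik**: IC(MICA); non-negative, unbounded above, grows with ontology
  depth.
* **Lin**: 2·IC(MICA) / (IC(a) + IC(b)) in [0, 1], with the convention
  1 for a term with itself and 0 otherwise when both ICs are 0.
* **Jiang–Conrath**: the distance d = IC(a) + IC(b) − 2·IC(MICA),
  converted to a similarity 1 / (1 + d) in (0, 1], equal to 1 exactly at
  distance 0. The conversion is a design choice (the literature offers
  several); this one is monotone, bounded and parameter-free.

Only `is_a` edges are traversed; other relation types a real ontology may
carry are ignored at parse time. Obsolete terms are dropped.

Because scoring needs similarities between every candidate and every item
in a user's history, all pairwise values over the item universe are
precomputed once (`build_sim_cache()`), optionally on several forked
workers, and persisted as a single self-describing TSV
(`write_sim_cache()` / `read_sim_cache()`). Pairs are enumerated in a
fixed canonical order and the per-pair arithmetic is identical under any
partition, so the store is record-identical for any worker count — a
property the test suite asserts rather than assumes. The store keeps one
record per unordered pair (self-pairs included) with a unique pair key,
canonicalized lexicographically so symmetry is structural.

## The scorers

**ONTO (content-based).** For a user with train items T and a candidate
item c, the score is the arithmetic mean of the semantic similarities
between c and the `n` most similar members of T (`score_items_onto()`).
`n = 5` is the default — the neighborhood size that performed best in
ranked evaluation — with `n = 1` giving max-similarity and `n = "all"`
the plain mean. Ties at the cutoff break by descending similarity then
ascending item id. No rating of any candidate is consulted, so an item
with zero ratings dataset-wide is still scorable: CB has no item
cold-start.

**ALS (collaborative).** `fit_als()` implements confidence-weighted
matrix factorization for implicit data: preference p = 1 for any observed
count, confidence c = 1 + α·r, loss
Σ c·(p − x'y)² + λ(Σ‖x‖² + Σ‖y‖²), minimized by exact alternating ridge
solves. The objective is evaluated after every sweep and can only
decrease; users with no observations get the zero vector. Defaults:
α = 40, λ = 0.01, 150 factors at literature scale (tests and the shipped
experiments use 4–16 factors at their much smaller sizes).

**BPR (collaborative).** `fit_bpr()` maximizes
Σ ln σ(x_u'(y_i − y_j)) − λ‖Θ‖² over sampled (user, observed, unobserved)
triplets by SGD. Some implementations shift ranking scores by +1 to keep
them positive; `bpr_shift = TRUE` reproduces that, which is irrelevant to
BPR's own ranking but changes mean-rule hybrids. Users whose observations
cover the whole universe admit no negative sample and are excluded with a
warning.

Both fitters are bit-deterministic given their seed; initialization is
uniform on (0, 1/√f).

**Fusion.** For items scored by both modules, `combine_metric1()`
multiplies the two scores and `combine_metric2()` averages them. The
product rule is invariant to rescaling either side by a positive
constant; the mean rule is not, so unbounded Resnik scores dominate a
mean with sub-1 CF scores — which is why mean-rule hybrids pair best with
the [0, 1]-bounded measures. Items only one module can score are dropped
by default (CF cannot score train-unseen items under the `exclude`
policy); `cb_only_fallback = TRUE` instead keeps them at their CB score,
a documented divergence that restores cold-start coverage to hybrids.
Rankings sort descending with ties broken by ascending item id, so every
list is reproducible.

## Evaluation protocol

`split_folds()` partitions users and items into q = 5 seeded blocks each
and pairs block f of users with block f of items: fold f's test ratings
are the test users' ratings on the test items, everything else trains the
CF model. Each test user must rank the *entire* test-item block, rated or
not (about a fifth of the universe), mirroring offline protocols where
thousands of candidates are ranked per user. The pairing is read as
paired blocks (not the q² crossing) because only that reading yields
per-user candidate universes of ~20% of the items.

Relevance is binary: any positive count is relevant — an item written
about once is as relevant as one written about five times — and unrated
candidates are negatives. `evaluate_run()` computes precision, recall,
F-measure, MRR and nDCG at k = 1..20 (k = 0 is vacuous and not reported),
macro-averaged over users then folds; users with no relevant item in a
fold are excluded from that fold's means, with counts attached to the
report. No validation split is used: hyperparameters are not selected by
the protocol, so cross-validation alone suffices. Algorithms evaluated in
one call share folds and CF fits, making comparisons paired.

## The synthetic generator

Real literature-derived ratings cannot be shipped, so `gen_ontology()`
and `gen_ratings()` emulate their structure: a single-root DAG grown with
recency-biased attachment (deep rather than star-shaped, with optional
secondary ids); users anchored to a subtree from which a `concentration`
fraction of their ≥ 20 rated items is drawn, the rest from a power-law
popularity pool (many single-rater items, few popular ones); counts
dominated by 1s and capped at 5 — the cap is cosmetic, since binarization
erases it. `concentration = 0.9` gives strongly ontology-correlated
interests; `0` is a negative control in which CB signal is absent.
`gen_rank1_ratings()` is a minimal single-axis variant for exercising
pairwise rankers, and `fixture_toy()` pins the five-term DAG used in
examples (root `T:R`; `T:A`, `T:B` under it; leaves `T:C`, `T:D` under
`T:A`), where every similarity value is checkable by hand.

What the generator does **not** emulate: real ontologies' multiple
relation types and annotation-based (extrinsic) term frequencies; the
long-tail degree distribution of a curated chemical ontology; temporal
structure in authorship; and any correlation between rating magnitude and
preference strength. Tests passing on this generator therefore establish
the algorithms' contracts and the direction of the hybrid effect, not
absolute metric levels on real data.

## Numerical and design choices

* IC uses descendant counts (intrinsic IC); the log base is 2 everywhere.
* Empty common-ancestor sets give shared IC 0 (disjoint components score
  0 rather than erroring).
* ALS solves are exact (`solve()` on f×f systems); the objective check
  tolerates accumulation error of 1e-8 per sweep comparison.
* The similarity store holds doubles at full precision; its text
  serialization uses 17 significant digits, enough to round-trip IEEE
  doubles exactly.
* Fold sizes differ by at most one; q must not exceed the number of users
  or items.
* Degenerate inputs: empty train sets, users with all items positive,
  unknown accessions, cycles and duplicate ids in OBO input all raise
  typed, named errors rather than propagating NA.

### Scaled-down study sizes

The shipped experiments run on one CPU in seconds, with sizes chosen once
as realistic small-scale analogues: the directional hybrid experiment
uses a 150-term ontology, 120 items, 40 users with ≥ 20 ratings each,
concentration 0.9, 5 folds, ALS with 16 factors and 10 sweeps; the ALS
objective contract uses a 50×80 count matrix at 15% density; the BPR
contract uses the 30×40 rank-one fixture. At the rank-one fixture's size,
BPR needs stronger regularization than the large-scale default: held-out
positives are necessarily sampled as negatives during training, so a
weakly regularized model memorizes the training positives instead of the
shared popularity axis. The small-data setting lr = 0.05, λ = 0.25
recovers that axis (held-out AUC ≈ 0.81–0.87 against a Bayes ceiling of
≈ 0.92); the large-scale defaults remain lr = 0.01, λ = 1e-4.

On the concentrated generator, mean-rule hybrids on the bounded measures
(LIN, JC) consistently match or beat ALS alone on nDCG@10 across
generator seeds; the mean-rule hybrid with Resnik is *expected* to be
unstable relative to ALS because of the scale mismatch discussed above,
which is why the directional claim is asserted for the bounded measures.

## Known limitations

* Only `is_a` edges contribute to similarity; relation-type allow-lists
  beyond `is_a` are not implemented.
* Extrinsic (annotation-count) IC is not implemented; IC is structural.
* The disjunctive-common-ancestor refinement of shared IC is not
  implemented; MICA is the contract.
* No learned fusion weights, switching hybrids, or significance testing
  between algorithms.
* The evaluation is offline only.

## A worked example

```{r example}
toy <- fixture_toy()
ic <- compute_ic(toy$ontology)
round(ic, 4)

store <- build_sim_cache(toy$ontology, ic, toy$ontology$ids)
get_similarity(store, "T:C", "T:D", "resnik")   # IC of their parent T:A
score_items_onto(store, c("T:A", "T:B"), c("T:C", "T:D"), "lin", n = "all")

rec <- hybrid_recommender(toy$ratings, toy$ontology, "ALS_ONTO_LIN_m2",
                          factors = 2, iterations = 5, seed = 1)
predict(rec, "u2")
```

A full cross-validated comparison on generated data:

```{r evaluate}
onto <- gen_ontology(100, seed = 1)
data <- gen_ratings(onto, n_users = 20, n_items = 80,
                    min_items_per_user = 10, concentration = 0.9, seed = 1)
report <- evaluate_run(c("ALS", "ONTO_LIN", "ALS_ONTO_LIN_m2"), data, onto,
                       q = 5, seed = 1, k_max = 10,
                       factors = 8, iterations = 10)
report
```
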