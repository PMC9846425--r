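---
title: "Aligning fragmentary sequence datasets with an ensemble of profile HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning fragmentary sequence datasets with an ensemble of profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehmmalign)
```

## The problem

Large sequence datasets often mix full-length sequences with short
fragments (partial genes, reads, truncated database entries). Global
aligners treat every sequence as full-length and tend to smear fragments
across the alignment; the resulting homology errors propagate into trees,
selection scans and structure inference. `ehmmalign` takes the
divide-and-conquer route: align only the sequences that look full-length,
model that *backbone* alignment with many profile hidden Markov models, and
then dock every remaining sequence individually into the backbone through
the model that most plausibly generated it.

## The three stages

**Stage 1 — backbone.** A subset of sequences is deemed full-length and
aligned. Two selection rules are provided:

* *median window* (default): sequences within 25% of the median length are
  eligible; at most `target_size` (1000 by default, 10000 when the input
  has at least 25000 sequences) are kept, sampled uniformly when more are
  eligible.
* *sliding window*: scan candidate lengths `L` (the observed lengths) and
  choose the `L*` maximizing the number of sequences within `25%·L` of
  `L`; keep every sequence of length at least `0.75·L*`. This is the rule
  to use when length histograms are multimodal — e.g. heavily fragmented
  datasets — where the median can fall between length classes.

The median here is the ordinary sample median (the midpoint average for
even counts). This matters: an "observed value" median is always inside
its own eligibility band, so selection could never fail; with the midpoint
convention a dataset whose lengths cluster far from the median — exactly
half fragments, say — is detected and reported with a pointer to the
sliding-window rule instead of silently building a backbone out of
fragments.

The backbone is aligned either with the built-in progressive aligner (a
UPGMA guide tree on k-mer distances, profile–profile Needleman–Wunsch with
affine gaps; +1/−1 match/mismatch with gap open −3, extend −1 for
nucleotides, BLOSUM62 with −11/−1 for proteins) or with any external
aligner through a `cmd:` template (`{input}`/`{output}` placeholders), the
route a production run would take with MAGUS or PASTA. The backbone tree
is neighbor joining on p-distances by default, or an external tool
(e.g. FastTree) via the same mechanism.

**Stage 2 — the ensemble.** The backbone tree is cut at a *centroid edge*
(the edge whose removal splits the leaves most evenly; ties go to the
first edge in a deterministic pre-order traversal). Each half keeps its
induced subtree (degree-2 nodes suppressed) and is cut again, until every
subset has at most `z` sequences (`z = 2` by default; `z = 10` reproduces
the older, coarser decomposition). Every subset produced along the way —
including the full set — contributes one profile HMM trained on the
subalignment induced by the backbone alignment, so the models form a
rooted binary hierarchy ordered by pre-order node ids.

**Stage 3 — placement and merge.** Each query is scored against models of
the ensemble, aligned to its selected model by Viterbi, lifted onto
backbone columns through the subset's column map, and finally all
per-query *extended alignments* are merged by transitivity: output columns
are the backbone columns in order, with one private column per insertion
residue spliced in after its anchor column. Insertions from different
queries are never aligned to each other and are written in lowercase, the
usual insertion-state convention; every insertion column therefore holds
exactly one residue. Restricting the merged alignment to the backbone rows
reproduces the backbone alignment exactly — a property the test suite
asserts on every pipeline run.

## Adjusted bit-scores and model selection

A profile HMM's bit-score is the log-likelihood ratio
`b(q) = log2 P(q | H) / P(q | null)`. The raw score does not answer the
question Stage 3 actually asks — *which model generated this query?* —
because subsets differ in size. Assuming exactly one of the ensemble's
models generated `q`, with prior probability proportional to the subset
size `s_i` (a sequence is a priori equally likely to belong to any
backbone sequence's neighborhood), Bayes' rule gives

    P(H_i | q) ∝ s_i · P(q | H_i)  ∝  2^{b_i + log2(s_i)}

so ranking by the *adjusted bit-score* `β_i = b_i + log2(s_i)` ranks by
posterior probability, and normalizing `2^{β_i}` over any scored set
(done in log space) yields the posteriors themselves; the null-model terms
cancel. `posterior_over()` exposes this.

Three search strategies select the model:

* **exhaustive** — score all models; the best (adjusted) score wins, ties
  to the smallest pre-order node id.
* **Hierarchical** — score the root, then repeatedly score the two
  children of the current node and descend into the higher-scoring
  subtree (ties broken by a seeded coin flip) until a leaf; the best score
  seen anywhere wins. At most two models are scored per level, so the
  cost is logarithmic in the ensemble size.
* **EarlyStop** (default) — Hierarchical, but stop descending as soon as
  both children score strictly below the best score seen so far: they and
  everything below them are deemed less likely to have emitted the query.

EarlyStop never evaluates more models than Hierarchical, which never
evaluates more than exhaustive; the suite asserts this ordering per query
on every run, and the package's acceptance checks show the accuracy of
EarlyStop and exhaustive search agreeing to within a few thousandths of
SPFN on low-divergence data.

## The profile HMM engine

The engine implements the classic glocal match/insert/delete architecture
(global in the model, global in the query, as required when every query
residue must land somewhere in the output):

* **Match columns**: backbone subalignment columns with non-gap fraction
  at least 0.5 — the standard `symfrac` rule.
* **Emissions**: per-column counts with a Laplace pseudocount (default
  1.0) over the canonical alphabet; insert states emit the background
  distribution of the subalignment. Ambiguity codes (N, X, ...) emit with
  probability one under both the model and the null, making them exactly
  ranking-neutral.
* **Transitions**: per-column counts regularized by an informative
  Dirichlet prior (total mass `3 × pseudocount` per source state, weights
  favoring match continuation, `M→M ≈ 0.95`, and sticky delete runs,
  `D→D ≈ 0.36` against `D→I ≈ 0.025`), in the shape of the
  single-component priors used by the standard profile-HMM builders. The
  prior is load-bearing, not cosmetic: with a flat pseudocount, delete
  states that were never observed in a two-sequence training alignment
  get uniform exit probabilities, and the Viterbi path of a short fragment
  can then hop out of a delete run onto any coincidentally matching
  column at no cost — fragments get scattered instead of placed
  contiguously. We observed exactly this failure mode on low-divergence
  fixtures (placement-driven SPFN around 0.09 that the prior reduces
  to under 0.01).
* **Numerics**: all arithmetic in natural-log space with log-sum-exp;
  impossible events are `-Inf`, and a query with no valid path reports
  `-Inf` (forward) or an explanatory error (Viterbi). With a positive
  pseudocount every parameter is positive, so scores are finite; the
  forward recursion is verified against an explicit enumeration of every
  state path on all toy sizes `k ≤ 3`, `|q| ≤ 4`.

The forward and Viterbi recursions, and the profile–profile
Needleman–Wunsch of the internal aligner, are small C++ kernels; everything
else is plain R.

## The simulator and what passing tests mean

`simulate_msa()` evolves a root sequence down a tree (random, balanced, or
user-supplied; rescaled to a chosen height) under uniform
(Jukes–Cantor-like) substitution with geometric-length indels, with exact
column bookkeeping so the true alignment is known. `fragmentize()` builds
"high-fragmentary" datasets: `floor(fraction·n)` sequences (default half)
are replaced by contiguous substrings whose length is
`round(mean_ratio · median length)` (default a quarter; optional normal
noise via `length_sd`, default 0 for deterministic fixtures), start
positions uniform. `fragment_reference()` restricts the true alignment to
the surviving residues, giving the reference that a perfect method would
reproduce.

The simulator reproduces the *structure* that matters to this method —
length heterogeneity, indel-induced gaps, known homologies — but not
realistic substitution processes (no rate heterogeneity, no empirical
exchange matrices, no structure-constrained evolution). Passing the
accuracy checks therefore demonstrates that the machinery places fragments
where the generating process put them at moderate divergence; it does not
by itself certify accuracy on real rRNA or protein families, which is what
the external-tool adapters (MAGUS/FastTree/HMMER-scale backbones) are for.

Problem sizes in the test suite and acceptance script were chosen to
exercise every code path at desk scale: 10–100 taxa for unit and property
tests, a 5000-sequence selection check, 200 queries for the search-cost
bound, and a 60-taxon / 30-fragment pipeline for accuracy recovery
(average p-distance kept under 0.1, where SPFN lands well below 0.05).

## Design choices where the design was open

* **Sampling eligible backbone sequences** beyond `target_size` is plain
  uniform sampling without replacement; nothing suggested stratifying by
  length.
* **Backbone-eligible sequences excluded by downsampling** are treated as
  queries — they are "remaining sequences" like any other.
* **Centroid ties** break on a deterministic traversal order; **descent
  ties** use the pipeline RNG (reproducible under the run seed);
  **final-best ties** use pre-order rank.
* **Subtree extraction** after a centroid cut suppresses degree-2 nodes,
  the standard induced-subtree semantics.
* **Insertion columns** are strictly singleton. Under the unaligned
  convention any layout is equivalent; consecutive private columns in
  query order are canonical and keep the merge a single deterministic
  pass.
* **The size-proportional prior** behind the adjusted score is isolated in
  `adjusted_bitscore()`; a different prior (e.g. uniform over models)
  would change only the additive constant there.
* **Hierarchical/EarlyStop under raw scores** is available (`scoring =
  "raw"`) to complete the design matrix, though adjusted scoring is the
  recommended default.

## Limitations

* One model per query: no weighted combination of several HMMs.
* The internal progressive aligner is a fallback for desk-scale work, not
  a substitute for MAGUS/PASTA on hard datasets; use the `cmd:` adapters.
* No E-value calibration, local alignment modes, or Dirichlet mixture
  emission priors; the engine is glocal only.
* Queries are placed independently; insertions are never re-aligned
  across queries.
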