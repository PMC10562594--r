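---
title: "Measuring temporal and semantic organization in free recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal and semantic organization in free recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recalldyn)
```

## The measurement problem

In a free-recall experiment a participant studies an ordered list of `L`
words and then types back as many as they can, in any order. Beyond the
number of correct recalls, the *sequence* of responses is informative:
successive recalls tend to come from nearby study positions (temporal
contiguity, with a forward bias) and from semantically related words
(semantic clustering). `recalldyn` measures both tendencies per
participant and per condition, and supplies the mixed-design statistics
needed to contrast them across within-subject experimental conditions —
for example, whether the environmental context at retrieval matches the
context at encoding.

## Response classification

Raw typed responses are classified before any dynamics are computed.
Matching is case-folded, whitespace-trimmed, and tolerant to typing slips
up to a configurable Damerau–Levenshtein distance (default 1 operation,
in the optimal-string-alignment variant that counts adjacent
transpositions). Crucially, matching is restricted to the known
vocabulary — the session's study lists — rather than a general
dictionary: spell correction in this task should recover *list words*,
not arbitrary English. Each response becomes exactly one of

* **correct** — uniquely nearest to a word of the just-studied list, not
  yet credited; carries that word's serial position;
* **repetition** — an already-credited current-list word;
* **PLI** (prior-list intrusion) — nearest to a word studied on a
  *different* list of the session;
* **ELI** (extra-list intrusion) — everything else, including responses
  equidistant from two or more candidate words at the minimal distance
  (the matcher never guesses).

PLIs are classified and reported separately but excluded from ELI
counts, since ELIs are by definition words not studied on any list.
Classification is idempotent and, at distance 0, reduces to exact
set membership.

## Transitions and their denominators

Every pair of consecutive responses is a transition. A transition is
*valid* only when both endpoints are first-time correct recalls;
intrusions and repetitions invalidate the transitions into and out of
them, contributing neither actual nor possible counts. This mirrors the
convention of the widely used lag-CRP methodology of excluding invalid
output events; the alternative (keeping the out-transition of a
repetition) would double-count availability in ways the probability
denominator cannot absorb.

At a valid transition from serial position `i`, the *available* targets
are all positions not yet credited as recalled, excluding `i` itself.

* **Lag-CRP.** For each signed lag, the number of valid transitions made
  at that lag divided by the number of valid transitions at which that
  lag was available. Lags never available are undefined (`NA`), not
  zero, and are excluded from averages. Per-transcript curves are
  computed first and then averaged pointwise across participants over
  the transcripts where each lag is defined.
* **Factor scores.** Available targets are ranked by the key — negative
  absolute lag for the temporal factor, similarity to the just-recalled
  word for the semantic factor — so the most contiguous / most similar
  candidate gets the highest rank. Ties receive average (fractional)
  ranks. The transition scores `(R − 1)/(N − 1)`, `R` the rank of the
  target actually chosen among the `N` available ones, and scores are
  averaged within a transcript. Uniformly random target choice gives an
  expected score of exactly 0.5 regardless of tie structure, which is
  why 0.5 is the chance anchor (`chance_level()`).

Three boundary rules deserve note:

* **`N = 1` transitions** score 0/0 and are excluded from the mean
  rather than imputed; a transcript with no scorable transition has an
  undefined (`NA`) factor, which downstream statistics drop listwise.
* **Tied optima** score slightly below 1 by the fractional-rank rule; a
  participant recalling a list in perfect forward order still scores
  exactly 1 because the `+1` neighbour uniquely minimises |lag| at every
  step.
* **Semantic denominator.** The semantic factor defaults to the same
  availability-restricted candidate set as the temporal factor, which
  keeps the two scores on a common scale. A plausible alternative
  reading — ranking against *all* list words except the just-recalled
  one — is available as `possible = "all"` in `transition_factor()`.

The adjacent/remote lag summary averages defined CRP values at |lag|
1–2 versus |lag| 3–16, separately by direction. The remote bound of 16
follows the convention for 32-item lists of comparing against lags up to
half the list; lags 17–31 remain in the full curve but enter neither
cell.

## Constrained list construction

Study lists dissociate temporal from semantic structure: each 32-word
list contains 16 designated high-similarity pairs (similarity > 0.7)
whose members never occupy adjacent serial positions, so that a
semantic transition is by construction a non-adjacent temporal one.
Two genuinely open design choices were fixed as follows:

* **Pair selection** is greedy in descending similarity with
  seed-controlled tie shuffling — reproducible and, on matrices whose
  designated pairs are separated from background similarity, provably
  exact. When too few disjoint pairs exceed the threshold, the error
  reports the exact maximum achievable count (a small branch-and-bound
  maximum matching).
* **Ordering** starts from a seeded shuffle and repairs violating
  adjacencies by local swaps (failing loudly after 10,000 steps), then
  validates the non-adjacency constraint exhaustively, so the
  algorithm's internals cannot silently violate the contract.
  "High similarity" for the adjacency check means membership in a
  designated pair (the minimal reading); `strict = TRUE` additionally
  forbids any adjacency above the similarity threshold. Whether
  alternative orderings of a list share the pair-to-slot assignment or
  re-randomise completely is configurable
  (`reuse_pair_positions`); the default re-randomises.

## The synthetic cohort generator

No participant data ship with the package, so the generator exists to
realise the statistical structure the scoring and statistics stages
assume, and nothing more. It is a deliberately minimal cue-mixture
sampler — not a fitted implementation of eSAM or CMR:

* the first recall is recency-weighted (`exp((pos − L)/τ)`);
* each next candidate is sampled proportionally to
  `(1 − λ)·exp(−|Δpos|/τ)·(φ if forward) + λ·sim(prev, ·)` over the
  still-available items;
* a sampled item fails recovery with probability ρ and is permanently
  dropped without output — retrieval effort spent, nothing recalled —
  implementing the idea that context change reduces the recoverability
  of sampled items;
* with probability ε an output is an extra-list intrusion token;
* recall stops with probability `p_stop` per output, at pool
  exhaustion, or at 60 output events (a 90 s recall window at 1.5 s per
  output, the only role timing plays).

Defaults: `L = 32`, `n_subjects = 141`, `p_stop = 0.07` (mean ≈ 12–14
outputs, matching typical recall counts), `τ = 1.5` positions,
`φ = 1.5`, `λ_same = 0.15`, `λ_diff = 0.45`, `ρ_same = 0.05`,
`ρ_diff = 0.10`, `ε = 0.02`. The two within-subject conditions differ
only in (λ, ρ); block order is counterbalanced to ±1 subject, and each
block studies a different 32-word list drawn from a shared 64-word
synthetic similarity matrix (designated pairs uniform in [0.7, 0.95],
background |N(0.1, 0.05)| truncated to [0, 0.3]).

What the generator *emulates*: tunable forward-asymmetric contiguity,
tunable semantic clustering, occasional intrusions, realistic recall
counts, and a condition contrast in which semantic cues weigh more when
context changes. What it does *not* emulate: repetitions (no parameter
governs them; the classifier is exercised on hand-built transcripts),
inter-response timing, output-position effects on accuracy, or any
mechanistic commitment about context representation. A green end-to-end
test therefore establishes that the pipeline detects the structure this
sampler plants — not that the sampler is an adequate model of human
recall.

### A structural trade-off, on the record

One qualitative expectation cannot be met by this generator: that
raising the semantic weight between conditions leaves the temporal
factor untouched. In a single-mixture sampler, weight given to the
semantic cue is necessarily taken from the temporal cue, so E[SF]
increasing in λ (a tested monotonicity property) entails E[TF]
decreasing in λ. At the default λ gap the induced TF condition effect
is large (F ≈ 100 at n = 141) and significant in every seed, and the
corresponding acceptance check is deliberately left failing rather than
weakened: a generator that could raise SF without touching TF would
need an extra degree of freedom (for example, condition-specific τ or a
renormalised cue budget), which the stated parameterisation does not
include.

## Statistics

All parametric results are computed from their sums-of-squares or
t-statistic formulas and are verified in the test suite against
independent reference implementations (`t.test`, `cor.test`,
`aov(… + Error(subject))`) to 1e-8 on randomised inputs:

* one-sample t against chance 0.5, one-tailed by default with a
  one-sided CI, Cohen's d = (m − 0.5)/s;
* Welch t with Satterthwaite df for unpaired group contrasts, p-values
  Bonferroni-multiplied (capped at 1) when part of a family;
* the 2×2 split-plot ANOVA computed stratum-wise (between-subject
  stratum for order, within-subject stratum for condition and the
  interaction), with partial η² relative to the effect's own error
  stratum and listwise deletion of subjects missing a condition score —
  so factor-score analyses run on fewer subjects than recall-count
  analyses, as undefined factors drop out;
* a sign-flipping permutation test on within-subject differences as the
  assumption-light companion (and the replacement for parametric
  post-hoc tests), `p = (1 + #{|perm| ≥ |obs|})/(n_perm + 1)`;
* Pearson recall-by-organization correlation with a Fisher-z CI;
* a repeated-measures ANOVA with Greenhouse–Geisser epsilon (from the
  double-centred covariance; inert for two-level factors) for the
  four-bin serial-position analysis.

Degenerate inputs fail loudly rather than silently: zero-variance
scores, fewer than two scores per group, fewer than six permutation
pairs, and unresolvable transcripts are all errors.

## Reproducibility

Every randomized stage receives a sub-seed derived deterministically
from one master seed (`seed·7919 + stage·104729 mod 2³¹−1`), logged in
the run manifest together with package and R versions and MD5 digests
of every artifact. Re-running a pipeline with the same configuration
reproduces every CSV byte for byte. Simulation-based test sizes are
scaled to desk hardware (for example, the null-calibration suite runs
200 studies of 40 subjects rather than 141 — type-I error does not
depend on n) and noted where they occur.

## Known limitations

* The spell matcher is a vocabulary-restricted substitute for a full
  dictionary-based correction; it will not recover typos at distance
  > 1 by default, and it refuses ambiguous corrections.
* The generator's admitted arbitrariness (above): its contract is
  statistical structure, not mechanism, and its λ/TF trade-off is
  structural.
* Lag-CRP denominators count availability only at valid transitions;
  studies using other conventions for transitions adjacent to errors
  will differ slightly.
* The package computes no Bayesian statistics and no mixed-effects
  regressions beyond the split-plot ANOVA.
```{r}
sessionInfo()
```
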