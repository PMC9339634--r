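---
title: "Mining class-targeted risk-factor rules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining class-targeted risk-factor rules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromine)
```

## The model

A patient record becomes a *transaction*: a set of `attribute=level` items,
exactly one per retained attribute, one of which is the class item
(`Class=Negative` / `Class=Positive`). For a transaction database
T = {X₁, …, X_N}, an association rule A ⇒ C is scored by

* **support** = freq(A ∪ C) / N — the share of the database in which
  antecedent and consequent co-occur, and
* **confidence** = freq(A ∪ C) / freq(A) — the conditional frequency of the
  consequent among transactions containing the antecedent.

Rules are generated *within class strata*: the cohort is split into the
disease-negative and disease-positive groups and each group is mined
separately, with the group's class item as the fixed consequent and N equal
to the **group** size. Group-relative support is the only reading under which
a sick-group rule can have support 0.88 when positives are ~6% of the cohort;
it also has a structural consequence:

> **Stratified-confidence theorem.** If C is present in every transaction of
> the mined database, then freq(A ∪ C) = freq(A) for every A, so every
> emitted rule has confidence exactly 1.

The uniform 1.00 confidence column in this kind of stratified analysis is
therefore not an empirical observation but a theorem; the test suite asserts
it over randomized groups, and its failure would indicate an encoding or
stratification bug, not an interesting dataset.

A rule is categorized **frequent** iff support ≥ s_min *and* confidence ≥
c_min, both inclusive; everything else — including low-support rules of
perfect confidence — is infrequent and dropped. Defaults are s_min = 0.6,
c_min = 0.9, the operating point of the study designs the presets encode.

## Two miners, one contract

Frequent itemsets are found twice, by deliberately independent
implementations with an identical output contract (exact integer counts,
inclusive threshold):

* `apriori_mine()` — level-wise: frequent single items, then repeated
  candidate generation (`join_candidates()`: join k-itemsets sharing k−1
  items, prune candidates with an infrequent k-subset) and exact counting
  against a logical incidence matrix.
* `fpgrowth_mine()` — tree-based: items below threshold are discarded, the
  rest are written in descending support order (ties broken
  lexicographically on the rendered item, applied identically when
  reordering transactions — the published procedure specifies only
  "descending", and determinism requires a total order), transactions are
  inserted into a prefix tree with per-node counts and per-item header
  chains, and mining recurses over conditional pattern bases in ascending
  header order.

`mutual_rules()` intersects the two rule sets by (antecedent, consequent)
key. Because both miners are exact, the default metric tolerance is 0 and the
consensus stage should be the identity on either input; any `only_*` rule or
metric discrepancy is a bug detector. This is why the pipeline always runs
both algorithms. One documented judgement call: the source procedure says
conditional trees require support "larger than" the threshold while the
level-wise text implies pruning below it; published rules sitting exactly at
the threshold (support 0.61, 0.71 at s_min 0.6) survive only under the
inclusive reading, so both miners compare inclusively — consistency between
the algorithms is a precondition for the mutual-rule stage to mean anything.

Two resolved interface questions: (a) when a shared key's metrics disagree
beyond tolerance, the key stays in the `mutual` partition (carrying the first
input's metrics) and the disagreement is listed in `metric_discrepancies` —
recorded rather than silently merged, while keeping
mutual ∪ only_first = first input as a key partition; (b) the level-wise
miner realizes "enumerate all combinations" as the classic join-plus-prune,
the efficient equivalent of unrestricted enumeration with identical output
(the triple-equivalence test against an exhaustive power-set oracle is the
evidence).

## Numerical choices

Counts are integers throughout; support fractions are materialized only for
reporting. The inclusive threshold test converts the fraction once to the
smallest admissible count, `ceiling(min_support * N - 1e-9)`; the `1e-9`
guard absorbs only binary representation error of the product (e.g.
`0.6 * 5`), never a genuinely sub-threshold count, so thresholding is
float-artifact-free. Reported support/confidence are rounded half-up to two
decimals in CSV outputs (matching the convention of published rule tables);
JSON artifacts carry the exact counts. Canonical orders — lexicographic items
inside itemsets, descending support then antecedent string for rules — make
artifacts byte-stable across runs.

## Discretization presets

`spec_dataset1()` (thyroid "sick" design, 21 attributes): decade age bins
over 20–80, sex, thirteen boolean flags, five laboratory reference ranges
(TSH 0.27–4.2, T3 1.3–3.1, TT4 62–164, T4U 0.7–1.8, FTI 53–142), class.
`spec_dataset2()` (cardiovascular-records design, 15 attributes): age split
at 50, gender, twelve boolean comorbidities, class. Decisions where the
source designs were silent:

* Laboratory intervals are **closed on both ends** (the printed ranges read
  "lo ≤ x ≤ hi"); `Abnormal` is the complement.
* Age bins are **half-open [lo, hi)** with the last bin closed — the printed
  bins share endpoints ("20–30", "30–40") and one side must win for the
  mapping to be a function. Ages outside 20–80 are a domain error by
  default; `encode_transactions(out_of_range = "drop")` removes them and
  surfaces the count, since the source design does not say how such ages
  were handled.
* Boolean spellings (`f/t`, `0/1`, `N/Y`, `no/yes`) normalize to
  `False`/`True` so rules render uniformly across datasets; class labels
  normalize to `Negative`/`Positive`, with an id-suffix strip for the
  `negative.|3733`-style class column of the UCI export.
* Missing values are removed **after** attribute selection: a record missing
  only an unselected attribute (e.g. TBG, never analyzed) is kept, which
  maximizes usable records. The canonical missing marker is `NA_character_`,
  which no category label can collide with.

## The synthetic world

`generate_transactions()` draws, in a fixed order under one seeded stream
(class, then per class the planted-pattern flags and each attribute in
configuration order, then missingness), so output is bit-stable per seed.
Planted patterns use a mixture: with probability p the whole itemset is
forced; otherwise the pattern's attributes are drawn independently from
residual marginals rescaled so overall marginals match the configuration.
When a pattern item's marginal *equals* p the residual probability of that
level is zero, making the realized joint exactly p — the configuration used
by the parameter-recovery acceptance test (planted joints 0.95 / 0.75 / 0.55
at ~5,000 records per class), whose 3-binomial-SE bounds are then exact
rather than approximate. Patterns sharing an attribute within one class are
rejected outright, keeping ground-truth supports exact. Ground truth is
recorded on the complete table before missingness; a direct recount matches
whenever `missing_rate = 0`.

The presets state a world, not a fit. `preset_dataset1_like()` mirrors the
sick database's shape — 2800 records, ~6% positive, 21 attributes, per-cell
missingness 0.0066 (≈13% incomplete records over 21 attributes, the study's
cleaning loss) — and plants one pattern per group echoing its published
rules (healthy: no I131 treatment ∧ no hyperthyroid query, joint 0.92; sick:
female ∧ abnormal T3, joint 0.80). `preset_dataset2_like()` does the same at
303 records (healthy: no CRF ∧ no CVA, 0.97; sick: obesity ∧ not ex-smoker,
0.71). Only attributes featured in published rules carry the real data's
very high (>0.9) marginals; unfeatured attributes sit near 0.5, below the
0.6 support threshold, so the frequent lattice stays small enough (≈10
frequent items per group) for exhaustive offline verification. Consequently
a green synthetic run establishes the *machinery* — encoding, stratification,
both miners, thresholds, consensus — not the real datasets' joint
distribution, their between-attribute correlations, or their full (curated)
rule tables. Reproducing the published rule metrics requires the two
original UCI files, which are not redistributed here; with them in hand,
`pipeline_config(input = , dialect = "uci_data", spec = "dataset1")` runs the
identical path, and the preset selections/discretizations encode the
published designs verbatim. The published 2800 → 2437 cleaning count is
sensitive to an ambiguity the source leaves open (whether anything beyond
missing-value removal, such as an age-range filter, was applied); both
cleanings are expressible here (`out_of_range = "error"` vs `"drop"`).

## Degenerate inputs and limitations

Empty tables encode to an N = 0 database; `min_support = 1` mines only
items present in every transaction (an empty rule set is legal and
serializes cleanly); `min_support ≤ 0` is refused because it would enumerate
the power set. Mining is exact and in-memory: the design favors
oracle-verifiability over scale, which is appropriate for cohorts of
thousands of records and a few dozen items but not for dense databases with
many correlated high-support items, where the frequent lattice grows
exponentially (a `max_len`/`max_antecedent` cap is available). No
lift/leverage metrics and no significance testing are computed — the
support/confidence framework is the method being implemented, and its known
weakness (confidence is uninformative under stratification, by the theorem
above) is intentional and visible rather than patched.
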