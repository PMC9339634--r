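# thyromine

Class-targeted association-rule discovery of clinical risk factors from
categorical patient records.

## The problem

Which attributes of a patient record — comorbidities, treatment history,
laboratory values discretized against their reference ranges — co-occur so
reliably with a disease label that they are worth flagging as candidate risk
factors? `thyromine` answers this with class-stratified association-rule
mining: records are encoded as transactions of `attribute=level` items, the
disease-positive and disease-negative groups are mined separately, and every
rule takes the form *antecedent itemset ⇒ class item*.

For a transaction database T = {X₁, …, X_N} the two rule metrics are

    support(A ⇒ C)    = freq(A ∪ C) / N
    confidence(A ⇒ C) = freq(A ∪ C) / freq(A)

and a rule is **frequent** only when support ≥ s_min *and* confidence ≥
c_min (inclusive; defaults s_min = 0.6, c_min = 0.9). Low-support /
high-confidence rules are categorized as infrequent and discarded: risk-factor
discovery requires rules backed by a large share of the group.

The package's integrity device is algorithmic redundancy: frequent itemsets
are mined by **two independent from-scratch implementations** — level-wise
Apriori (`apriori_mine()`, candidate join + downward-closure prune, exact
integer counts) and FP-Growth (`fpgrowth_mine()`, prefix-tree compression with
header chains and recursive conditional-tree mining) — and only the rules
**mutual** to both (`mutual_rules()`) are reported. Since both miners are
exact, any disagreement is a bug detector, not a finding.

Bundled discretization presets (`spec_dataset1()`, `spec_dataset2()`) encode
two published thyroid-disease study designs: decade age bins, boolean
history/comorbidity flags normalized to `False`/`True`, thyroid-function
laboratory values (TSH, T3, TT4, T4U, FTI) mapped to `Normal`/`Abnormal` by
closed reference ranges, and a `Negative`/`Positive` class. A synthetic
generator (`generate_transactions()`) with planted within-class patterns and
exact ground truth makes every stage testable offline.

## Worked example

```r
library(thyromine)
res <- simulate_pipeline("dataset2", seed = 7)   # generate + mine end to end
writeLines(res$stage_log)
```

```
read: 303 records, 15 attributes
select: 303 records, 15 attributes retained
clean: 262 records remain (41 incomplete removed)
encode: 262 transactions, 30 distinct items (0 out-of-range dropped)
group Negative: 246 transactions
group Positive: 16 transactions
group Negative: 325 frequent itemsets, 162 mutual rules (0 apriori-only, 0 fpgrowth-only)
group Positive: 81 frequent itemsets, 40 mutual rules (0 apriori-only, 0 fpgrowth-only)
```

The stage log is the cleaning audit trail: 303 synthetic records lose 41 to
missing values, encode to 262 transactions over 30 distinct items, and split
into a healthy group (246) and a sick group (16). Both miners agree exactly
(`0 apriori-only, 0 fpgrowth-only`), so the mutual set is the full rule set:

```r
print(res$groups$Positive$consensus$mutual)
```

```
<rule_set> 40 rule(s) [mutual(apriori,fpgrowth) | synthetic-dataset2 | group Positive | s>=0.6 c>=0.9]
  CRF=False => Thyroid_disease=Positive  (support 0.94, confidence 1.00, n=15)
  CVA=False => Thyroid_disease=Positive  (support 0.94, confidence 1.00, n=15)
  Ex_smoker=False => Thyroid_disease=Positive  (support 0.94, confidence 1.00, n=15)
  ...
  Hypertension=True => Thyroid_disease=Positive  (support 0.81, confidence 1.00, n=13)
  Ex_smoker=False; Obesity=True => Thyroid_disease=Positive  (support 0.69, confidence 1.00, n=11)
```

Support is group-relative: `Hypertension=True` holds in 13 of the 16
sick-group transactions (0.81). Confidence is 1.00 for every rule — a
structural consequence of stratified mining (the class item is in every
transaction of its group), which the test suite asserts as a theorem. The
planted sick-group pattern (obese never-ex-smoker, joint probability 0.71) is
recovered at its realized frequency.

Real data runs use `run_pipeline()` with a `pipeline_config()` (or a JSON
config via `read_run_config()`), e.g. pointing `input` at a UCI-style `.data`
file with `dialect = "uci_data"` and `spec = "dataset1"`; a thin CLI wrapper
with `mine` / `simulate` / `compare` subcommands ships in `inst/cli/`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
both synthetic presets are generated at the given seed and pushed through the
entire pipeline (ingest → clean → discretize → stratify → Apriori + FP-Growth
→ rules → consensus), failing if the two miners ever disagree, then writes the
acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
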