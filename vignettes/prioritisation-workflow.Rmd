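---
title: "Joint prioritisation of risk factors and epidemic-prone diseases: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint prioritisation of risk factors and epidemic-prone diseases: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohrank)
```

## The problem

Epidemic-prone diseases — most of them zoonotic — compete for scarce
surveillance and control resources across the human-health, animal-health and
environment sectors. A One Health prioritisation workshop brings those
sectors' stakeholders together to decide, for a given local context, which
candidate *risk factors* (drivers of emergence and outbreaks) and which
candidate *diseases* deserve attention first. `ohrank` is the computational
engine for such a workshop: it takes the participants' votes, pairwise
judgments and ordinal scores as plain text files and turns them into
defensible, auditable rankings. The judgments stay human; the arithmetic is
automated and deterministic.

The workflow has five steps, run separately but identically for the two
streams (risk factors and diseases):

1. **Identification** — each participant individually marks every candidate
   for inclusion; the highest-voted candidates form the shortlist.
2. **Criterion weighting** — each group weights the stream's criteria by
   pairwise comparison (AHP).
3. **Scoring** — each group scores every shortlisted item on every criterion
   against a three-level rubric.
4. **Composite scores** — computed automatically per item and group.
5. **Ranking** — min–max normalisation, group-wise ranks, and a combined
   cross-group rank.

## The model

### Criteria

Each stream combines *weighted* criteria with one unweighted *multiplier*:

* risk stream: three likelihood criteria — scope of exposure, frequency of
  exposure, mitigation strategy — and the potential-for-outbreak multiplier;
* disease stream: four threat criteria — severity (case fatality rate),
  prevalence, transmissibility, preventive and control strategy — and the
  disease-burden multiplier.

Every criterion is scored on an ordinal 1–3 rubric. Directionality is
uniform: **a larger score is always worse**. This is worth flagging for the
two strategy criteria, where 3 means *no* strategy is available. Criteria are
data, not code: the catalogue ships as an editable YAML file
(`default_criteria()`), and locally adapted criterion sets are accepted when
count enforcement is relaxed, though the 3+1 / 4+1 structure is the validated
default.

### Shortlisting (step 1)

Votes are unweighted; an item's tally is the number of participants who
marked it for inclusion (a missing vote is an exclusion). `select_top()`
keeps the `k` highest-tallied items **plus every item tied at the cutoff
count**: a tied candidate is never dropped by the engine, because the final
list size is a stakeholder decision. Participant-added candidates enter the
catalogue like any other; the 50-per-stream cap applies to the post-addition
list (exceeding it is a validation error, surfaced before any stage runs).

### AHP weighting (step 2)

For a stream with $n$ weighted criteria each group supplies the
$n(n-1)/2$ upper-triangle judgments $a_{ij}$ on the 1–9 scale (or exact
reciprocals when $j$ dominates $i$). The full reciprocal matrix — $3^2 = 9$
cells for risks, $4^2 = 16$ for diseases — is completed mechanically
($a_{ii} = 1$, $a_{ji} = 1/a_{ij}$), so reciprocity cannot be violated by
transcription. Eliciting only the triangle, with intermediate values
rejected, was a deliberate intake decision.

Weights are the normalised principal right eigenvector of $A$, obtained by
power iteration (tolerance $10^{-12}$ on the weight vector, capped at
10,000 iterations — convergence is guaranteed for positive matrices, the cap
is a guard). The row-geometric-mean estimator is available via
`method = "geometric-mean"`; both agree to $10^{-9}$ on any consistent
matrix, and the eigenvector is the default because it is the classic AHP
estimator. Consistency is diagnosed with

$$\lambda_{\max} = \frac{1}{n}\sum_i \frac{(A w)_i}{w_i}, \qquad
  CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad
  CR = \frac{CI}{RI(n)},$$

with Saaty's Random Index values ($RI(3) = 0.58$, $RI(4) = 0.90$; the table
is user-overridable). $CR > 0.10$ raises a prominent flag but does **not**
stop the pipeline: inconsistent judgments are a matter for moderated
consensus in the room, not a reason for software to halt a live workshop.
`strict = TRUE` (or `--strict-consistency` on the command line) upgrades the
flag to an error for offline quality control. Weights remain per group
throughout; no consensus matrix is formed.

### Composite scores (step 4)

For item $i$ scored $s_{ic} \in \{1,2,3\}$ on weighted criterion $c$ with
group weight $w_c$ and multiplier score $m_i$:

$$\text{composite}_i \;=\; \Big(\sum_c s_{ic}\, w_c\Big) \times m_i .$$

Since $\sum_c w_c = 1$, the weighted sum lies in $[1,3]$ and the composite in
$[1,9]$, attaining the bounds only for all-1 or all-3 input. The multiplier
is never weighted. Scores must be single integers per cell — no half-points,
no abstentions, no imputation; discrepancies within a group are resolved by
consensus before data entry. Full precision is kept internally; the
4-decimal rounding seen in output is presentational only.

### Normalisation and ranking (step 5)

Within each group,

$$\text{normalised}_i = \frac{\text{composite}_i - \min_j \text{composite}_j}
        {\max_j \text{composite}_j - \min_j \text{composite}_j},$$

so each group's best item scores 1 and worst 0. If a group's composites are
all equal the denominator vanishes; the engine sets every normalised score to
0 and flags the group *degenerate* rather than failing — loudly documented,
because 0 here does not mean "lowest priority".

Ranking is descending **competition ranking** ("1, 1, 3"): tied items share
the best applicable rank and the next rank is skipped. Ties are detected by
equality after rounding to 9 decimals — composites are short products of
small rationals, so $10^{-9}$ cannot conflate genuinely different inputs on
this scale with at most five groups, while absorbing float noise. Tie sets
are reported, never broken silently; `apply_overrides()` lets stakeholders
resolve them by consensus, accepting only overrides that touch reported tie
sets and leave a valid competition ranking.

The **combined rank** is computed from the arithmetic mean of an item's
normalised scores across groups, ranked with the same rule. The cross-group
combination rule is genuinely open design space (summed ranks and Borda
counts are reasonable alternatives); the mean of normalised scores was chosen
as the least-structured rule that uses the per-group normalised columns
directly, and it is labelled as the engine's documented default in the
report. The `combined_rank_method` field leaves room for alternatives without
changing file formats. A combined score of 1 is possible only for an item
ranked top in every group.

## Files, pipeline and determinism

All artefacts are plain UTF-8 CSV ("." decimal, header row) or YAML; the
canonical directory layout is documented in `load_bundle()`. The pipeline is
a DAG — votes → shortlist → {judgments → weights, scores} → composites →
ranking — and `run_pipeline()` executes it through any prefix. Two properties
are load-bearing for auditability:

* **Determinism.** Identical input bundles produce byte-identical output
  files. Numeric columns are written with 17 significant digits, which
  round-trips IEEE doubles exactly; the run log records stage sequence
  numbers and input-file MD5 hashes rather than wall-clock timestamps.
* **Validation before computation.** Intake problems (catalogue over the
  50-candidate cap, more than 5 groups, off-scale judgments, incomplete
  score sheets, scores for non-shortlisted items) are collected into a
  report with file/line locations; errors block the pipeline, warnings
  (e.g. group sizes outside the usual 5–7 participants, a deliberately soft
  bound) do not.

## The synthetic workshop generator

Real workshop data are judgments of human panels; there is no deposited
dataset to test against. `simulate_workshop()` therefore generates complete,
statistically controllable input bundles:

* **Votes**: per-item inclusion probabilities (drawn from Beta(2, 2) when not
  supplied) and i.i.d. Bernoulli votes per participant.
* **Judgments**: from known *true weights* $w$, each elicited ratio is
  $(w_i/w_j)\,e^{\varepsilon}$ with $\varepsilon \sim N(0, \sigma)$, then
  snapped to the nearest admissible scale value *in log space* (the scale is
  multiplicative), with exact midpoints resolved toward 1 — the conservative
  judgment. Snapped matrices always satisfy the reciprocal-matrix
  invariants.
* **Scores**: i.i.d. draws per (group, item, criterion) from a 1–3
  distribution, with an optional correlation knob that drives cells from a
  shared per-item latent severity so that inter-group agreement can be
  dialled up for ranking-stability experiments.

A single seed drives all draws in a fixed, documented order, so a bundle is
reproducible from the spec alone. Defaults describe a realistic mid-size
workshop: 30 + 30 candidates, 24 participants in 4 groups of 6, shortlists
of 10, true weights $(4/7, 2/7, 1/7)$ for risks and $(8, 4, 2, 1)/15$ for
diseases — chosen because their pairwise ratios all lie exactly on the 1–9
scale, making noise-free recovery exact — and log-scale judgment noise 0.1.

`recover_weights_experiment()` closes the loop: generate noisy judgments,
re-estimate weights, summarise mean absolute error and the CR distribution.
With zero noise the true weights are recovered to $10^{-9}$; MAE and the
fraction of CR flags grow with the noise level. The package's validation
suite exercises these properties at 200 replicates per noise level, the
composite-score oracle at 10,000 random draws, the normalisation contract
across 1,000 random groups, and end-to-end determinism on a full-size
workshop (5 groups, 50 + 50 candidates) — sizes chosen to probe the full
configuration space the workshop format allows.

What the generator does **not** emulate: consensus dynamics within groups
(groups are independent scorers), sector-correlated voting blocs, and
systematic judgment biases (e.g. centrality bias on the 1–9 scale). Passing
tests therefore demonstrate the engine's arithmetic and contracts, not the
behavioural validity of any particular workshop's outputs.

## Degenerate and edge inputs

* A single-item group normalises to 0 with the degenerate flag.
* Fewer voted items than the requested shortlist size `k` keeps all voted
  items and warns; zero-vote items are never shortlisted.
* `n < 3` criteria cannot be inconsistent; CR is reported as 0 with a note.
* Judgment values are validated against the exact admissible set
  {1..9} ∪ {1/2..1/9}; 9.5 or 10 are intake errors.

## Known limitations

* The severity rubric bands CFR "in one or both sectors" without prescribing
  which band wins when human and animal CFRs disagree; the engine records
  the group's chosen score and leaves the interpretation to the scorers.
* No inter-group agreement statistics (e.g. Kendall's W) are computed; the
  per-group columns of the ranking table support doing so externally.
* Vote weighting by stakeholder sector is deliberately not supported; every
  participant's vote counts equally.
* The spreadsheet-style wide ranking CSV is a one-way export; the engine
  never reads spreadsheets back, to avoid formula and locale drift.
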