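# ohrank

A deterministic engine for One Health prioritisation workshops: shortlist
candidate **risk factors** and **epidemic-prone diseases** from participant
votes, weight the decision criteria per stakeholder group with the Analytic
Hierarchy Process (AHP), compute composite risk-impact and disease-burden
scores from ordinal 1–3 criterion scores, and produce min–max normalised
group-wise and combined rankings with explicit tie reporting.

It is written for the people who run and analyse such workshops — One Health
moderators, public-health and veterinary epidemiologists — who need the
automated steps of the exercise to be transparent, auditable and exactly
reproducible: all inputs and outputs are plain CSV/YAML, identical inputs
yield byte-identical outputs, and every run is logged with input hashes.

## The method

Both streams follow the same five steps. For a stream with weighted criteria
$c = 1,\dots,n$ (risk: scope of exposure, frequency of exposure, mitigation
strategy, $n = 3$; disease: severity, prevalence, transmissibility,
preventive/control strategy, $n = 4$):

1. **Shortlist**: items are tallied by inclusion votes; the top $k$ are kept,
   plus *all* items tied at the cutoff.
2. **Weights**: each group fills the upper triangle of a pairwise comparison
   matrix $A$ on the 1–9 scale ($a_{ij} \in \{1..9\} \cup \{1/2..1/9\}$,
   $a_{ji} = 1/a_{ij}$); weights $w$ are the normalised principal eigenvector
   of $A$, with consistency ratio
   $CR = \frac{(\lambda_{\max} - n)/(n-1)}{RI(n)}$ flagged when $CR > 0.10$.
3. **Scores**: each group scores every shortlisted item on every criterion
   with an integer $s_{ic} \in \{1,2,3\}$ (larger is always worse).
4. **Composite**: $\text{composite}_i = \big(\sum_c s_{ic} w_c\big) \times m_i$,
   where $m_i \in \{1,2,3\}$ is the unweighted multiplier score (potential
   for outbreak / disease burden); the composite lies in $[1, 9]$.
5. **Rank**: per group, $\text{norm}_i = (x_i - \min x)/(\max x - \min x)$;
   descending competition ranks ("1, 1, 3") within groups; the combined rank
   orders the mean of each item's normalised scores across groups. Ties are
   reported for stakeholder consensus, never broken silently.

## Worked example

A group judged scope of exposure twice as important as frequency and four
times as important as mitigation strategy, and frequency twice as important
as mitigation:

```r
library(ohrank)

A <- pairwise_matrix(
  data.frame(
    criterion_i = c("scope", "scope", "frequency"),
    criterion_j = c("frequency", "mitigation", "mitigation"),
    value       = c("2", "4", "2")
  ),
  c("scope", "frequency", "mitigation")
)
w <- compute_weights(A)
w
#> AHP weights (eigenvector method, n = 3)
#>      scope  frequency mitigation
#>     0.5714     0.2857     0.1429
#> lambda_max = 3.000000, CI = 0.000000, CR = 0.000000
```

The judgments are perfectly consistent ($\lambda_{\max} = n = 3$, $CR = 0$),
and the weights are exactly $(4/7, 2/7, 1/7)$. A risk factor this group
scored 2 on scope, 3 on frequency, 1 on mitigation, with outbreak potential
2, then gets:

```r
s <- risk_impact_score(
  c(scope = 2, frequency = 3, mitigation = 1),
  w$weights,
  outbreak_potential = 2
)
cat("weighted_sum =", round(s$weighted_sum, 4), " composite =", round(s$value, 4), "\n")
#> weighted_sum = 2.1429  composite = 4.2857
```

i.e. a weighted likelihood of 2.14 on the 1–3 scale, doubled by the medium
outbreak potential to a composite risk-impact score of 4.29 on the 1–9
scale. Composites from all groups then flow into `ranking_table()`.

An entire workshop is driven from a directory of CSV/YAML files:

```r
b <- load_bundle("my-workshop/")   # config, criteria, catalogue, votes, judgments, scores
b <- run_pipeline(b)               # shortlists -> weights -> composites -> rankings
render_report(b)                   # top items, weights + CR flags, ties, degenerate groups
```

or from a shell via the thin CLI (`simulate` generates a seeded synthetic
workshop for training and testing):

```sh
Rscript inst/cli/ohrank simulate --seed 5 --groups 3 --candidates 12 --out demo-ws
Rscript inst/cli/ohrank run --workshop demo-ws
Rscript inst/cli/ohrank report --workshop demo-ws
```

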