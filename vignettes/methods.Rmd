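---
title: "Methods: similarity-based program recommendation, its simulator, and the design choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based program recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnrec)
```

## The procedure

`burnrec` implements a two-stage tailored intervention engine for nurse
burnout. Each participant is described by a mixed-type profile; burnout is
measured on the three Copenhagen Burnout Inventory (CBI) subdomains
(personal 0–31.5, work-related 0–37, client-related 0–31.5 raw points,
summing to a 0–100 total). All subdimension comparisons inside the engine
use the *normalized* scale (raw ÷ subdomain maximum × 100), which makes
the three subdomains commensurable and matches the 0–100 wording of the
validity rule.

The engine has three moving parts:

1. **Dissimilarity.** For two profiles, each categorical variable
   contributes 0 (match) or 1 (mismatch); each numerical variable
   contributes `|a − b| / R`, with `R` the variable's *theoretical* range
   declared in the schema. Contributions sum with unit weight per
   variable. Under the default schema (5 categorical + 17 numerical
   variables) the total lies in [0, 22].
2. **Validity.** After each 2-week program, the stage is valid iff
   exactly one subdimension's normalized score dropped by ≥ 5 points.
   One sufficient reduction identifies the program's effective
   subdimension; two or more are attributed to outside causes and the
   stage is discarded; the threshold comparison is `≥` (a reduction of
   exactly 5 is valid). Valid stages become records in an append-only
   knowledge base.
3. **Matching.** A new participant's *dominant* subdimension is the one
   with the highest normalized score (ties broken work > client >
   personal). Stage 1 filters the knowledge base to records whose
   effective subdimension equals the dominant one, then recommends the
   program of the least-dissimilar record; if the filter empties the
   candidate set the whole knowledge base is searched, and an empty
   knowledge base falls back to a preallocation map. Stage 2 repeats the
   procedure from the posttest-1 profile over the three programs not yet
   taken, using a reduced variable subset (demographics/work
   characteristics plus burnout subdimensions — the research variables
   are not re-measured mid-trial).

The original description labels this component an artificial neural
network that "learns". No architecture, loss, or training step exists in
that description: what it specifies — and what this package implements —
is nearest-record search over an accumulating store of valid outcomes.
The "learning" is the growth of the store.

## Schema choices

Only the variable *counts* (5 categorical, 17 numerical) are fixed by the
source material; the composition is configurable, and the shipped default
is:

| group | variables |
|---|---|
| categorical (5) | sex, marital status, position, department, shift type |
| numerical, demographic/work (5) | age 22–60, hospital-size code 1–5, clinical-experience band 1–6, overtime band 1–6, turnover intention 0–10 |
| numerical, research (6) | job stress 23–115, stress response 0–88, coping total 33–99 + three 11–33 subscales |
| numerical, burnout (3) | the three normalized 0–100 subdimensions |
| numerical, reserved (3) | inert 0–100 placeholders |

Three choices deserve comment:

* **Ranges come from the schema, not the data**, so dissimilarities are
  stable as the knowledge base grows. The age range 22–60 (R = 38) and
  clinical-experience band 1–6 (R = 5) were chosen because they reproduce
  the published worked example's element contributions (0.39/0.53 for the
  age pairs, 0.40/0.20 for the experience pairs) exactly at the printed
  precision; hospital-size codes 1–5 (R = 4) reproduce 0.50 and 0.25.
* **Clinical experience enters as a coded band** (1: <2 y, 2: 2–5 y, 3:
  5–10 y, 4: 10–15 y, 5: 15–20 y, 6: ≥20 y), not raw months: the worked
  example computes graded contributions from small integer codes, which
  raw months (range ≈ 500) could not produce.
* **Reserved slots** keep the default schema at the stated 17 numerical
  variables while leaving room for site-specific measures; the simulator
  holds them at the scale midpoint so they contribute nothing.

One printed inconsistency is deliberately not reproduced: the worked
example's sex row shows contribution 1 for three *matching* codes. The
stated categorical rule (match → 0) contradicts this; the package follows
the stated rule.

Ties in the ranking are broken by lowest insertion index (the earliest
stored record) — deterministic and auditable. Values that drift outside a
declared range at comparison time contribute at most 1 and raise a
warning rather than an error: validation belongs at ingest, robustness at
query time.

## The simulator

`cohort_spec()` bundles everything a synthetic deployment needs. The
default marginals emulate the published 300-nurse cohort: age normal
32.81 (SD 5.754) truncated to the schema range, 97.7% female, category
proportions taken as the published counts over 300 (so they sum to one
exactly), clinical experience drawn in months (95.83, SD 69.66) and then
banded, pretest burnout drawn per subdomain on the raw scale (personal
20.40 ± 6.39, work 22.22 ± 6.39, client 19.72 ± 6.63) and stored
normalized. Coping is drawn as three subscales whose sum matches the
published total distribution. Truncated-normal draws use the inverse-CDF
method, which keeps means on target when bounds are several SDs away.

Program responses subtract per-subdimension normal draws from the current
normalized scores, truncating to [0, 100]. The default response model is
calibrated to the published per-program effects, read as normalized
subdimension points: their weighted sum with the subdomain shares of the
total scale (0.315, 0.37, 0.315) reproduces the published *total*
reductions (laughter 5.4, storytelling 4.6, ACT 7.9, mindfulness 2.6
points) — a consistency check that pinned down the scale the table is
printed on. The published dispersions are used as the draw SDs; they are
the only printed spread for program effects, and normality of the draws
is an explicit modeling choice (only means/SDs of changes are reported).
Satisfaction is drawn at base mean 4.6 (SD 0.6) plus a 0.15 bonus when
the assigned program is the participant's subgroup-best, rounded and
clamped to 1–5, which places grand means in the published 4.5–4.7 band.

What the generator does *not* emulate: item-level CBI responses,
correlations between demographics and burnout, time trends within a
2-week program, dropout mechanisms (beyond an optional uniform rate), or
any real-data effect sizes beyond the printed means and SDs. Passing
tests therefore demonstrate internal correctness of the engine and the
qualitative behavior of the closed loop, not fidelity to any real cohort.

## Policy controls: design and an honest limitation

Comparing recommendation *policies* (similarity vs random) on the default
calibration is confounded: the four programs' main effects differ by a
factor of three, so any two policies differ in mean reduction through
program mix alone — under that calibration the claim "similarity ≈ random
when responses are homogeneous" is false by arithmetic, not by
implementation. The controls therefore use `control_response_model()`, in
which every program has identical base effects (mean 2, SD 3 per
subdimension — below the validity threshold, so valid records arise
selectively through noise), and the positive control adds
`subgroup_heterogeneity()`: a bonus of 10 normalized points on the
dominant subdimension when the assigned program is the participant's
stratum-best.

Two structural facts, discovered by experiment and worth recording,
shaped the control design:

* **The procedure has no exploration.** Cold-start preallocation fires
  only while no candidate record exists at all; afterwards the fallback
  searches the whole knowledge base. A stratum-best program that the
  preallocation phase never injects can therefore never acquire a valid
  record and is unlearnable by construction. The positive control
  consequently (a) replays the deployment's actual sequence — a 10-nurse
  preallocated pilot, then similarity — and (b) sets the true best map
  equal to the preallocation map, the scenario in which the designers'
  prior is correct and the engine's job is to maintain and propagate it.
* **A fixed stratum-best conflicts with the stage-2 exclusion.** If a
  stratum's best program is constant, the better stage 1 performs, the
  more often that program is excluded at stage 2. Strata defined by the
  dominant subdimension resolve this: an effective stage-1 program shifts
  which subdimension dominates, so stage 2's best differs from stage 1's
  and remains reachable.

Under this scenario (n = 300, 20 seeded replicates) the similarity
policy's late-cohort match rate to the subgroup-best program is ≈ 0.8
versus the random policy's 0.25, and its mean stage-2 reduction exceeds
random's in every replicate; without heterogeneity the two policies are
statistically indistinguishable.

The remaining claim — a negative Spearman correlation between
participation order and stage-2 burnout change — holds only weakly here,
and it is worth saying why rather than hiding it: the knowledge base's
(subdimension × program) pools saturate within roughly the first tenth of
a 300-participant run, so there is no *sustained* within-run improvement
trend for a rank correlation to detect; slowing knowledge-base growth
weakens the stage-2 advantage instead of stretching the trend. Across
every scenario examined the mean correlation over 20 replicates is
directionally negative but small (≈ −0.01) relative to its replicate
noise. The corresponding test asserts the direction; a reader should
treat that assertion as a weak one-sided check, not as a reproduction of
an order effect of any particular size.

## Numerical and degenerate-input conventions

* Zero-range (degenerate) numerical variables fall back to the 0/1
  categorical rule instead of dividing by zero.
* Zero-variance difference vectors in the paired test return a flagged
  degenerate result (`t = 0, p = 1` for no change; signed infinite `t`,
  `p = 0` for a constant shift) rather than `NaN`.
* Spearman p values use the asymptotic approximation (`exact = FALSE`):
  participation orders are rank data with possible ties.
* The satisfaction ANOVA's Scheffé post hoc is computed via `emmeans`
  with `adjust = "scheffe"`; the test suite checks it against the
  closed-form Scheffé formula.
* The normality screen (skewness, kurtosis) is reported but never gates
  an analysis — the source procedure states the screen without
  specifying an action on failure.
* All randomness flows through a single seed per command or trial;
  replays are bit-identical.

## Problem sizes used in the test suite

Unit tests run at toy sizes (profiles, knowledge bases of ≤ 20 records).
The oracle-equivalence check draws 1,000 random knowledge-base/profile
pairs; the policy controls run 20 replicates of the full pilot + 300
closed loop per arm; the marginal-convergence check samples one cohort of
3,000. These sizes were chosen to make Monte-Carlo error comfortably
smaller than the asserted margins while keeping a full suite run in the
low minutes on one core.

## Known limitations

* The engine ranks by unweighted unit contributions; no learned variable
  weighting exists (none is specified by the source procedure).
* With an empty stratum pool the fallback searches the whole knowledge
  base rather than exploring untried programs; as discussed above, this
  makes the system's asymptotic behavior depend entirely on what the
  pilot injects.
* Multi-record ties at identical dissimilarity are resolved by storage
  order, which favors early records; an alternative (e.g., most recent,
  or largest reduction) would be equally defensible.
* The simulator's satisfaction model is intentionally minimal (base +
  match bonus); it reproduces the published grand means but no
  item-level satisfaction structure.
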