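---
title: "De-identifying longitudinal claims under a re-identification risk budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying longitudinal claims under a re-identification risk budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdeid)
```

## The problem

A longitudinal claims release consists of two linked tables: one row per
patient (age, sex, and hospital-day outcomes — the *level-1*
quasi-identifiers) and many rows per patient in a claims table whose
quasi-identifying columns (specialty, place of service, CPT code, length of
stay, days since first claim, diagnosis — *level-2*) an adversary may know
in part. Identity disclosure is the risk managed here: an adversary who
links background knowledge about a person to a released record learns which
record is theirs. Attribute disclosure is deliberately out of scope.

The package's model of the adversary and the release is:

* the release is a fraction `alpha` of a source population, and the
  adversary is assumed (conservatively) to know whether their target is a
  member of that population, but membership of the *sample* is only
  probabilistic (`alpha`);
* the adversary knows the target's level-1 values exactly, and for each
  level-2 quasi-identifier knows `p_ih` of the target's claim values — not
  which values co-occurred in a claim, and not their order;
* matching is done against the released, generalized vocabulary.

## Risk parameters

| parameter | default | meaning |
|---|---|---|
| `theta` | .05 | maximum acceptable per-record re-identification probability |
| `F_min` | `1/theta` = 20 | implied population equivalence-class floor |
| `alpha` | data-dependent | sampling fraction, recorded on the dataset |
| `k` | `ceiling(alpha * F_min)` | minimum sample class size enforced by the search |
| `u` | 0.0004 | residual population-uniqueness rate of the reference (Safe Harbor) standard |
| `maxsup` | `u/theta` = 0.008 | tolerated proportion of above-threshold records |
| `p_m` | 5 | adversary power cap per quasi-identifier |

The `maxsup` derivation equates risk exposures: if every above-threshold
record were re-identified with probability 1, a proportion `u/theta` keeps
`theta * maxsup = u`, the exposure of the reference standard. The
conservative ceiling in `k` never admits a class whose implied population
size is below `F_min`. The worst-case expected re-identified fraction is
then `maxsup + (1 - maxsup) * theta` (5.8% at the defaults) — an upper
bound, not an estimate.

Two readings of the calculus required a choice. First, the exposure
identity only yields a 0.8% budget if the reference uniqueness rate is
0.04% (`u = 0.0004`); we use that value consistently. Second,
`k = ceiling(alpha * F_min)` (4 at `alpha = 0.2`, `F_min = 20`) is the
reading consistent with the threshold-to-floor correspondence
`F_min = 1/theta`; the package documents and implements this one.

## Preprocessing

Top-coding caps `PayDelay` and the `DaysInHospital` columns at the
nearest-rank 99th percentile — extreme values are identifying on their own.
The nearest-rank definition (order statistic at `ceiling(p * n)`) is used
for every percentile in the package because it is well defined on small
samples; no interpolation rule is assumed.

Truncation caps each patient's claim count at the 95th percentile of
per-patient counts. The claims to delete are chosen by a rarity score: the
sum over level-2 quasi-identifiers of `-log2(relative frequency)` of the
claim's value in the full claims table, so the most re-identifying claims
go first. Ties break toward larger `dsfc`, then larger row index,
preserving the earliest clinical history and making output deterministic.
The untruncated dataset ("D1") is kept alongside the released one ("D2")
because the simulated attack draws the adversary's knowledge from D1.

Patients carrying any code from a configurable high-risk list (stigmatized
conditions; exact or ICD-9 prefix match) are removed entirely — for them no
residual risk is acceptable. Provider, vendor and PCP identifiers are
suppressed wherever the estimated number of population providers sharing
the claim's (specialty, place, CPT, diagnosis) pattern falls below 20;
distinct providers are counted, not claims, and the count is scaled by
`1/alpha`. Note the direction of that estimator: a smaller `alpha` implies
a larger population behind the same sample count, so raising `alpha`
toward a census can only add suppressions.

Identifier fields are pseudonymized by HMAC-SHA256 under a release secret,
truncated to 64-bit hex tokens, with the field name bound into the message.
Equal inputs map to equal tokens within a release (the linkage survives),
and tokens cannot be inverted or replayed across releases without the
secret. An unkeyed hash is refused: member and provider IDs have little
entropy and would fall to a dictionary attack.

## Generalization hierarchies and the lattice

Each quasi-identifier has a ladder of coarsenings (level 0 = raw values):
age in 5-, 10-, then 20-year bands with an `80+` catch-all (bands are
left-closed and anchored at 0 — the interval widths are standard, the
anchors are a package choice); hospital days to 2-week then 1-week/2-week
bands; length of stay through four coarsenings ending in `<4 weeks` plus
coarser week-bins; days since first claim through weeks, 2-week and 28-day
blocks. Sex is never generalized. The four categorical code columns have
exactly one predetermined grouping level each, driven by two-column CSV
tables; the packaged tables are small synthetic demonstrations. Day
arithmetic treats stored `dsfc` as 0-based with 1-based display, so weeks
are days 1–7, 8–14, …; "months" are fixed 28-day blocks, which is the only
convention under which the final 4-week generalization coincides with the
month level.

The cross product of ladder levels forms a lattice ordered componentwise;
applying a node rewrites every quasi-identifier column at its level. Two
properties carry the search: partitions refine monotonically along the
order, and the non-uniform entropy loss
`sum(-log2(count(original value within its generalized group) / group size))`
is monotone non-decreasing up the lattice (it is `n` times the empirical
conditional entropy of the original value given the label).

## Adversary power

For patient `i` and quasi-identifier `h` with `n` claims and `u` distinct
values, the power is `clamp(ceiling(n/u), 1, min(p_m, n))` — the reciprocal
of diversity, clipped by the cap and the claim count. This is the simplest
formula satisfying the stated monotonicities (knowledge grows with claim
count, shrinks with diversity); it is a package default and replaceable,
since chronic patients with repeating diagnoses are exactly the ones whose
values are easy to know. Power is computed on the generalized values of the
node under evaluation: the adversary's knowledge is expressed in released
vocabulary, and coarsening can only lower diversity, hence raise power —
evaluating risk on raw-value power would understate it.

## Node evaluation and search

A node's high-risk proportion is estimated by hierarchical bootstrap:
per iteration, sample `patients_per_iteration` patients with replacement;
for each, draw a background-knowledge instance (per-QI simple random
sample of `min(p_ih, n_i)` values without replacement) and count matching
records in the generalized data; flag the draw high-risk when the matching
class has fewer than `k` records (the sample-side equivalent of an
estimated population class below `F_min`, cheaper than estimating `F` per
draw). The node estimate is the mean over iterations. Reference analyses
use 1000 iterations of 10,000 patients; the package exposes both knobs and
its CLI defaults to 200 × 2000, with a `--paper-scale` switch. The tests
and examples in this package run at a few tens of iterations on fixtures
of 10–150 patients, sizes chosen so the whole suite runs on one CPU in
minutes while keeping Monte-Carlo standard errors small enough for
three-sigma checks.

The search walks the lattice evaluating nodes near the median open height,
using predictive tagging: an acceptable node makes all its generalizations
acceptable, an unacceptable one all its specializations unacceptable.
Because the estimate is stochastic, tagging is applied only when the
estimate clears the `maxsup` boundary by at least two Monte-Carlo standard
errors; boundary-hugging nodes are evaluated directly. All evaluations in
one search share one seed (common random numbers), so compared nodes see
identical draws and the monotonicity the tagging relies on holds for the
realized estimates on enumerable fixtures. Candidates are the acceptable
nodes; the optimum minimizes entropy loss, with ties broken toward the
lower total level then lexicographically. Since the loss is monotone up
the lattice, only minimal candidates are scored. If even the top node is
unacceptable the result is an explicit cannot-release value, not an error
— on small samples with a release-scale budget this is the correct and
common outcome.

## The simulated attack

The attack evaluator is implemented independently of the search's matcher
(separate code path, different matching mechanics) and the two are
cross-checked against each other and a brute-force oracle in the tests.
Per iteration: a Bernoulli(`alpha`) membership draw (failures count in the
denominator), a uniform target from D1, a background-knowledge draw from
D1, matching against D2, a uniform pick from the matching class, success
iff the pick is the target. Variants relax the assumptions: `same_claim`
adds one full claim tuple (the known claim is chosen uniformly — the data
do not say which claim an adversary would know); `ordered` adds one
precedence-ordered value pair per quasi-identifier with power above 1,
with ties in `dsfc` counting as consistent with either order (simultaneous
claims cannot falsify an order claim). The grid over variants and power
caps uses one master seed per variant row so power comparisons are paired.

## Synthetic data

The generator emulates the structures that drive longitudinal
re-identification risk: negative-binomial per-patient claim counts
(defaults `mu = 13`, dispersion 1.2, minimum 1 — a median near 11 with a
long tail, echoing the shape of real claims data without claiming to
reproduce any specific dataset); a chronic fraction whose diagnosis repeats
across all claims (low diversity, maximal power); Zipf-skewed categorical
vocabularies drawn from the packaged demonstration tables so generated data
are always covered by the default hierarchies; strictly increasing
`dsfc` within each patient-year starting at 0; heavy-tailed hospital days
and pay delays so top-coding is exercised. Sampling is fixed-size without
replacement (reproducible fixture sizes, not Bernoulli). An optional
blueprint pins exact level-1 tuples and class sizes for closed-form oracle
tests. What the generator does **not** model: clinically realistic code
co-occurrence, calendar structure, provider networks, or the marginals of
any real claims dataset — so a passing suite demonstrates correctness of
the machinery, not that any particular real release would be safe.

## Numerical choices and degenerate inputs

* Percentiles: nearest rank everywhere; ties in truncation scores break by
  `dsfc` then row index.
* Zero-truncated Poisson estimator: `lambda` solved by bracketed root
  finding on `(0, f]` (the mean function is increasing and bounded by
  `1 + lambda`); `f = 1` returns `f`; the estimate is floored at `f`
  because a population class is never smaller than its sample class.
* A patient with no claims has power 0 on every level-2 quasi-identifier
  and is matchable on level-1 values only; a match count of 0 is possible
  when truncation removed the claims the adversary knows.
* An empty secret for pseudonymization, an empty value vector for
  diversity or top-coding, and a claims row referencing an unknown patient
  are all refused with named errors.

## Limitations

The packaged grouping tables, Charlson weights and high-risk code list are
synthetic demonstrations; real releases must supply authoritative tables.
Risk is evaluated against the stated adversary model — errors in the
adversary's knowledge would lower realized match rates, and correlations
between quasi-identifier diversities are not modelled jointly (power is
per-QI). Attribute disclosure, journalist risk, record-level suppression
and multidimensional recoding are out of scope.
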