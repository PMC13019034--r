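---
title: "Modelling hospital noise, annoyance, comfort, and intention to leave with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hospital noise, annoyance, comfort, and intention to leave with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisebn)
```

## The problem

Hospital wards are noisy, and patients differ in how strongly they react to
noise. This package models how two drivers — objective 24-hour noise exposure
(the day–evening–night level, $L_{den}$, in dB) and trait noise sensitivity
(the 21-item Weinstein scale, 0–105) — jointly shift the probabilities of
three patient outcomes: noise annoyance (0–100 visual-analogue scale),
acoustic comfort (7-point semantic differential, higher = more comfortable),
and the intention to leave the hospital early (0–100 VAS).

The analysis chain is: (1) compute $L_{den}$ from interval Leq logs;
(2) discretize all five continuous measures into ordered states
low / moderate / high at the sample P25 and P75; (3) fit the conditional
probability tables (CPTs) of a discrete Bayesian network over an
expert-specified DAG; (4) propagate hard evidence exactly and summarize each
scenario by delta-p, the change of each target-state probability in
percentage points.

## The acoustic indicator

Interval Leq values are pooled energetically — on the $10^{L/10}$ energy
scale — never as arithmetic means of dB. The source logs use a grid of eight
3-hour intervals; measurement intervals that straddle an analysis-period
boundary (the 22:00–01:00 interval crosses the 23:00 evening/night split) are
split proportionally by overlap hours, so the total sampled duration is
preserved without double counting. A 15-minute Leq standing in for a 3-hour
slot is weighted by the full represented duration. Period levels then combine
as

$$L_{den} = 10\log_{10}\!\Big(\tfrac{1}{24}\big(12\cdot10^{L_{day}/10} +
4\cdot10^{(L_{evening}+5)/10} + 8\cdot10^{(L_{night}+10)/10}\big)\Big),$$

with the standard +5 dB evening and +10 dB night penalties over the
12 / 4 / 8-hour periods (day 07:00–19:00, evening 19:00–23:00, night
23:00–07:00). Useful analytic identities, both tested to $10^{-9}$ dB:
`compute_lden(L, L-5, L-10) = L` (the penalties cancel the weights), and
$L_{den}$ is strictly increasing in every period level. Whether the source
data's per-patient exposure was a ward-level or bedside quantity is left to
the input table: `lden_by_location()` computes per-location values and the
join to patients is the caller's.

## Discretization

Cut-offs are the sample 25th and 75th percentiles computed with the linear
interpolation of order statistics (`stats::quantile` type 7) — the default of
mainstream numerical stacks, chosen for reproducibility since no estimator is
canonical for this design. Values exactly at a cut-off belong to the closed
moderate band, matching "low (<P25)" / "high (>P75)" semantics; tied values
always receive the same label. Comfort is *not* reverse-coded: "low comfort"
is the bottom quartile of comfort scores. With at least 4 finite values the
cut-offs are well defined; degenerate (constant) variables collapse to all
moderate, which is the honest reading of the rule rather than an error.

## The network and its estimation

The default DAG places `lden` and `sensitivity` as exogenous roots, both
feeding `annoyance` and `comfort`, which in turn feed `itl`
(intention to leave). There is deliberately no edge between the two roots and
no direct root-to-`itl` edge: the mediating topology is the point of the
model, and the evidence-propagation tables it produces show the two roots
mutually independent under single-root evidence. The structure is plain data
(`bn_structure()`), so direct effects can be added by anyone who wants them.

CPTs are relative frequencies with an optional Laplace pseudocount
(default 0, i.e. plain maximum likelihood). A parent-state combination with
zero support and zero pseudocount yields a uniform row plus a warning —
silent NaNs are never produced. Records with missing states are rejected
with the patient and field named; no missing-data EM is attempted, and
masked cohorts exist in the generator purely to exercise that rejection.

Inference is exact variable elimination with a greedy min-width elimination
order; at five ternary nodes speed is irrelevant and exactness is the
contract. An independent brute-force enumeration oracle (`enumerate_oracle`,
capped at $10^6$ joint cells) is kept in the package and the two are tested
against each other to $10^{-9}$ on 100 random ternary networks of up to 12
nodes. Evidence with prior probability zero is an error. Probabilities are
kept at full precision internally and rounded to 3 decimals only in report
tables, with the largest entry adjusted so printed rows sum to 1.000.

Delta-p is computed as `100 * (updated - baseline)` per state, where the
baseline is always the prior marginals of the same net. Per-variable entries
sum to zero by construction (probability conservation, tested). Evidence
variables are reported as `-`; formatting rounds to one decimal with an
explicit sign (`+10.6 %`, `-9.4 %`, `0 %`). Only hard (100%) evidence is
supported, matching how the scenarios are defined.

## The synthetic cohort generator

No patient-level data ships with the package, so a generator
(`sample_cohort()`) provides cohorts with known ground truth. Design
choices:

* **Categories first, scores second.** Each patient's five states are
  forward-sampled from a known generating network
  (`default_generating_net()`); the continuous score is then drawn given the
  state. This makes the CPT ground truth exact, which is what
  parameter-recovery testing needs — the alternative (a latent Gaussian
  copula) has no closed-form CPT truth.
* **The generating net.** Root priors are set to the reference baseline
  marginals. Child rows are linear in an ordinal parent score with slopes
  0.09 (annoyance, comfort per parent step) and 0.08 (intention to leave per
  step of the annoyance-minus-comfort contrast), with intercepts solved so
  the implied prior marginals of *all five* variables reproduce the
  reference marginals exactly (linearity makes the marginal depend only on
  the parents' mean score). Every row pair is stochastically ordered in the
  monotone directions: more exposure or sensitivity raises annoyance and
  lowers comfort; more annoyance or less comfort raises intention to leave.
  The slopes are this package's choice — the source tables identify
  marginals and signs, not dependency strengths — and are sized to give
  single-evidence delta-p values of roughly the published order (≈ ±9 pp on
  the extreme annoyance states under high exposure).
* **Scores.** For each variable a parent normal is solved (2-parameter
  moment match, residual < $10^{-10}$) so that its truncation to the scale
  limits — Lden [35, 85] dB, WNSS [0, 105], VAS [0, 100], comfort [1, 7] —
  has exactly the configured mean and SD (defaults 57.95 ± 6.61, 42.57 ±
  18.16, 38.46 ± 17.07, 4.73 ± 1.45, 26.06 ± 11.78). That truncated normal
  is then partitioned into three bands whose masses equal the generating-net
  marginals, and a patient's score is drawn by inverse CDF within their
  category's band. The mixture over categories is therefore exactly the
  moment-matched truncated normal: cohort means and SDs are unbiased, which
  is what the 2-standard-error moment-emulation test checks at n = 10,000.
  Bands are ordered and non-overlapping, so scores determine categories.
* **Noise logs.** Each patient gets eight 3-hour intervals on the standard
  grid with a diurnal profile (louder daytime, quiet small hours, ±1.5 dB
  interval noise), then a common shift so the log's aggregated $L_{den}$
  equals the patient's continuous value exactly (adding a constant to all
  interval levels adds that constant to $L_{den}$).

Everything is a deterministic function of the `generator_config()` seed.

**What the generator does not emulate:** demographic or ward structure, any
covariate effects, measurement error of the sound level meter, longitudinal
dynamics, the source study's true (unpublished) dependency strengths, and
the quirks of its published tables (the descriptive sensitivity/comfort
rows are not mutually consistent with the published baseline marginals, so
the pipeline reports empirical frequencies and fitted marginals separately
rather than forcing agreement). Passing tests on synthetic cohorts
demonstrate that the machinery is correct and well calibrated under the
stated generating assumptions — not that real hospital data satisfies them.

## Quartile-relabelling attenuation

One subtlety is documented rather than hidden. The generating extreme-state
masses are ≈ 0.20–0.35, but P25/P75 relabelling pins the extreme categories
to fixed 25% tails. Refitting on relabelled data therefore attenuates or
inflates delta-p entries by factors of roughly (0.25 / band mass), ≈ 0.65–1.5
here. So the full discretize→fit→query round trip reproduces the generating
net's delta-p *signs and ordering* (tested), not its magnitudes; magnitude
recovery within 1 pp holds when CPTs are fit to the sampled categories
themselves. Likewise, at n = 50,000 the posterior of a child under evidence
on *both* its parents is a single CPT row with sampling SE ≈ 0.6–0.7 pp, so
the worst double-evidence delta-p discrepancy is of that order (a few
tenths to ≈ 1.7 pp depending on seed) even though every row passes a total
variation bound of 0.02; single-evidence scenarios, which average over rows,
recover well within 1 pp.

## Problem sizes and numerical conventions

The shipped tests use cohorts of 2,000–10,000 for distributional properties
and 50,000 for parameter recovery, 100 random networks (up to 12 ternary
nodes) for the inference cross-check, and tolerances of $10^{-9}$ for exact
algebraic identities, 0.05 pp for table-derived delta-p values, 2 SE for
moment emulation, and total variation 0.02 per CPT row for recovery — sizes
chosen so each property is tested at a scale where its expected noise is
well inside the asserted bound. Seeds are fixed in the tests; the
acceptance script takes its seed on the command line.

## Limitations

The model is cross-sectional and makes no causal or mediation claims beyond
the expert DAG; structure learning, soft evidence, continuous or hybrid
nodes, missing-data EM, tornado-style CPT sensitivity, and frequency-weighted
acoustic metrics (L10/L90, A/C weighting, guideline compliance scoring) are
out of scope. Real cohort statistics cannot be reproduced without the
deposited data; the package's claims about them are limited to what the
generator is configured to emulate.
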