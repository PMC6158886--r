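---
title: "Methods: dosage-fitness analysis of the GAL network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-fitness analysis of the GAL network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galdose)
```

This vignette documents the statistical model behind each stage of the
pipeline, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the underlying experimental protocol leaves the details open.

## The measurement model

Each competition experiment mixes a query strain (one of the 16
copy-number genotypes over *GAL2*, *GAL3*, *GAL4*, *GAL80*, read
P~GAL1~-YFP) with a constitutive-mCherry reference strain and observes
the mixture by flow cytometry at 0, 24 and 48 h. Two quantities are
extracted per sample after gating:

* the **population odds** R(t) = n~query~/n~reference~, and
* the **normalized expression** E = mean(YFP~query~)/mean(mCherry~reference~),
  which cancels acquisition and density effects common to the sample.

Under exponential growth with a per-hour selection coefficient *s*, the
log odds is linear in time, log R(t) = log R(0) + s·t. Relative fitness
is defined multiplicatively as the per-24 h odds fold-change

$$ w = \left( \frac{R(t_1)}{R(t_0)} \right)^{24/(t_1 - t_0)}, $$

which equals e^{24s}: it is strictly positive, equals 1 for neutral
competition, is invariant to the initial mixing ratio, and makes the
multiplicative epistasis null dimensionally coherent. A log-scale
(selection-coefficient) variant is available via `type = "selection"` in
`raw_fitness()`; the per-24 h exponent is a convention constant, since
wild-type normalization makes downstream contrasts only approximately
invariant to it. Raw fitness is then divided by the mean wild-type raw
fitness of the same environment, so the wild-type normalized mean is
exactly 1.

Per-strain uncertainty is the s.e.m. over the N biological replicates
(`sem`). Because all strains of an environment share the same noisy
wild-type divisor, `fitness_summary()` also reports `sem_norm`, which
adds the relative s.e.m. of the wild-type raw mean in quadrature; it is
the appropriate scale when comparing a strain to an external reference
value, while `sem` matches the error bars conventionally plotted for
between-strain comparisons.

## Density gating

Cytometry samples contain debris and morphologically unusual cells. The
gate retains the densest 30–40% of events in the FSC–SSC plane. Density
is estimated by a 2-D histogram on a 64×64 grid spanning the robust
1st–99th percentile channel ranges (out-of-range events are clamped into
edge bins); events are ranked by their bin count and admitted in order of
decreasing density, with exact ties broken by stable event index. This
makes the gate deterministic, exactly reproducible by a brute-force
density sort, and nested in the target fraction. The default target is
0.35, the midpoint of the 30–40% band; the realized fraction is always
⌈0.35·n⌉/n. Zero-variance scatter (a degenerate sample) falls back to
retaining the first ⌈f·n⌉ events by index. A kernel-density estimate was
considered and rejected for the default because histogram ranking makes
tie behavior explicit and auditable.

## Classification and expression

The reference strain is identified per event by its constitutive mCherry
signal: events above a threshold are reference, all others query. The
protocol does not fix a threshold rule, so by default the threshold is
placed at the minimum of the smoothed log~10~-mCherry density between its
two largest modes, recomputed per sample; a fixed threshold can be
supplied (`mcherry_threshold`), which is also the fast path for large
simulation sweeps. Expression uses the arithmetic mean of linear-scale
fluorescence, matching the convention of averaging reporter fluorescence;
each replicate's expression is the mean of its three timepoint values,
and the strain estimate is the replicate mean with s.e.m. = sd/√N.

## Dosage effects and epistasis

For gene *g*, the eight genotype pairs differing only in *g*'s copy
number are averaged: Δw̄ = mean(w~halved~ − w~intact~), with uncertainty
√(Σ(sem²~halved~ + sem²~intact~))/8, treating the 16 strain means as
independent. Wild-type normalization induces a weak common dependence
that this propagation ignores; the approximation is documented rather
than corrected because the shared term cancels in within-environment
differences to first order. Differences of strain means (not means of
replicate differences) are used, as replicates of different strains are
not paired.

The overall epistatic deviation of a gene set M (|M| ≥ 2) is

$$ \varepsilon_M = w_M - \prod_{i \in M} w_i, $$

the departure of the multi-reduced strain from the product of its
single-reduction fitness values. Its standard error is first-order
propagation assuming independence:
SE² = sem(w_M)² + Σ_i (∏_{j≠i} w_j)² sem(w_i)². The net deviation
removes all lower-order interactions recursively,

$$ \varepsilon'_M = \varepsilon_M - \sum_{S \subset M,\ |S| \ge 2} \varepsilon'_S,
\qquad \varepsilon'_M = \varepsilon_M \text{ for } |M| = 2, $$

equivalent to the signed inclusion–exclusion expansion
ε′~M~ = Σ~S⊆M,|S|≥2~ (−1)^{|M|−|S|} ε~S~. Its standard error adds the
overall-deviation standard errors of the expansion in quadrature,
ignoring the covariance induced by shared single-gene terms; an exact
covariance-aware propagation would require the full replicate-level
covariance of the 16 strain means, which the summary-level interface
deliberately does not carry. By construction Σ~S⊆M,|S|≥2~ ε′~S~ = ε~M~
exactly, which the test suite verifies numerically to 10⁻¹².

Significance uses a two-tailed Z-test of H₀: ε = 0 with the
Holm–Bonferroni step-down applied per environment and per panel — the 11
overall deviations form one family, the 5 higher-order net deviations
(four triples and the quadruple) another. A study-wide family is
available (`family = "study"`). A third-order net deviation draws on 7
distinct fitness values and the fourth-order one on 15, which is why
higher-order deviations carry large propagated uncertainties.

## Dose-response model

Across pure-galactose environments, fitness is modeled as linear in
expression with a slope linear in log concentration:

$$ w = \beta_0 + (\beta_1 + \beta_2 \ln g)\,E, $$

fitted by unweighted OLS on strain means from the 0.3% and 1% training
environments (inverse-variance weighting is an option). The "simple
linear model" description leaves the concentration dependence open;
distinct prediction lines per concentration imply an interaction term,
and ln g is the minimal such parameterization. Alternatives (separate
slope per concentration; slope linear in g) are selectable. The
saturation diagnostic evaluates held-out points at one concentration and
reports the mean signed residual, together with the residual under a
substitute concentration (e.g. predicting the 2% environment with the 1%
line); a negative gap that shrinks under the substitute indicates the
dose response has saturated above the training range.

## The synthetic generator

The generator produces ground-truth-known studies with the statistical
structure the analysis assumes:

* **Dynamics** — deterministic exponential competition on the log odds
  with per-replicate growth-rate jitter (sd `replicate_sd`, default
  5×10⁻⁴ h⁻¹), observed by binomial sampling of 25,000 events; no lag or
  diauxic phases, since cultures are equilibrated before competition.
* **Fluorescence** — log-normal channels with CV 0.25; the mean YFP of a
  query population equals its true normalized expression times the
  reference mCherry scale, so expression estimates are directly
  comparable to truth. In the mannose-dominated environment A the query
  YFP is a two-component on/off mixture (induced fraction 0.6),
  emulating the bimodal single-cell distributions seen at minimal
  galactose.
* **Contamination** — 10% of events are drawn uniformly over an enlarged
  FSC–SSC box with near-zero fluorescence, giving the density gate real
  work; cells sit in a tight log-normal scatter cluster.
* **Ground truth shapes** (free choices, fixed once): baseline expression
  0.6 + 0.5·log₁₀(g/0.03) rising with galactose; expression multipliers
  1.6 (GAL80 halved), 0.75 (GAL4), 0.85 (GAL3), 0.95 (GAL2); fitness
  linear in expression with slope 0.05·ln(min(g,1)/0.3) in galactose
  environments (negative at 0.1%, zero at 0.3%, positive and saturating
  at ≥1%); a hockey-stick map with optimum 0.7 in environment A; and a
  GAL2 fitness factor of 0.93 at ≤0.15% galactose and 1.01 at ≥1%.
  These reproduce the qualitative trends the analysis is meant to
  detect: GAL80 reduction raises expression, GAL2 reduction costs
  fitness only at low galactose, and expression is beneficial only at
  high galactose.

What the generator does **not** emulate: instrument spillover and
autofluorescence, doublets, cell-cycle and volume structure, day-to-day
batch effects beyond a scalar growth-rate jitter, and any mechanistic
GAL kinetics. Passing recovery tests therefore validates the estimators
under the stated statistical model, not the instrument physics of real
data.

Randomness: one master seed expands to per-sample seeds by a stable
polynomial hash of (environment, genotype, replicate, …) modulo 2³¹−1
(`derive_seed()`), so studies are fully deterministic and any single
sample can be regenerated in isolation.

## Problem sizes and runtime choices

The default study (16×6×9 samples × 3 timepoints × 25,000 events)
simulates and analyses ~65 million events in about a minute. Unit tests
use reduced designs (1–2 environments, 2–3 replicates, 1,000–8,000
events) chosen so that the assertions' statistical tolerances — binomial
bounds, 3-s.e.m. bands — remain meaningful at those sizes; the
calibration suites use 500 simulated fitness-table studies for
family-wise error and 1,000 random lattices for the algebraic
identities.

## Known limitations

* Threshold classification assigns residual post-gate debris to the
  query population; with the default contamination this biases fitness
  by ≲0.2%, well inside replicate noise, but heavier contamination would
  need a debris-aware classifier.
* The Z-test treats propagated standard errors as known; with N = 9
  replicates the statistics are mildly heavier-tailed than normal, so
  family-wise error is controlled slightly less tightly than nominal
  when standard errors are estimated rather than supplied.
* The mixing-ratio invariance test controls FDR at 5% and will, by
  design, flag something in roughly one null study in twenty.
* The automatic mCherry threshold needs two visible density modes; very
  unbalanced mixtures (query fraction near 0 or 1) require a fixed
  threshold.
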