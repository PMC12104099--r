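---
title: "Imputing gaps in categorical state sequences: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing gaps in categorical state sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqgaps` imputes missing data in univariate categorical longitudinal
panels: n individuals observed at T equally spaced time points, each cell
one state from a small alphabet. This vignette explains the statistical
machinery, the parameters that matter, and the design decisions taken where
the problem left the design genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

A `SequencePanel` stores an n × T integer-coded state matrix, the alphabet,
sequence identifiers, optional fixed (time-constant) covariates, and a
structural-padding mask for ragged panels. Missingness is `NA`; padding is
a distinct trailing marker (`*` in CSV) excluded from every statistic and
from imputation. Time indices are 1-based inclusive everywhere a user sees
them. Panels containing a fully missing sequence are rejected at load and
at every imputation entry point, with the offending identifier named:
nothing can be learned about such a row from within the panel.

A **gap** is a maximal run of missing cells. Relative to a predictor window
of `np` past and `nf` future cells, gaps are classified as *internal*
(enough contiguous observed cells on both sides), *initial* (starting at
t = 1), *terminal* (ending at the last effective time point), or
*left-/right-/both-hand* (deficient on one or both sides). `n_before` and
`n_after` count **contiguous** observed cells only: an adjacent gap
truncates availability, which is the operative constraint because
predictors must be observed or previously imputed when their turn comes.

## MICT

Internal gaps are filled left to right, by decreasing remaining gap length
G. The first missing cell of a gap with remaining length G is predicted
from the `np` cells immediately before it (observed or previously imputed)
and the `nf` cells beyond the gap's far edge. The model for a given G is
fitted once, on every fully observed displacement window in the panel —
rows (i, t) whose cells at offsets {−np..−1, 0, +G..+G+nf−1} around the
target t are all observed — so all gaps of the same remaining length share
one model regardless of position. Imputed cells count as observed for later
steps, so the gap shrinks from the left and the shared-model invariant is
maintained.

Initial gaps are imputed from the far right to the left using future
predictors only; terminal gaps mirror this. Under past-only predictor
presets (`P1`, `P5`, where nf = 0) an initial gap has no usable side, so
the algorithm falls back to `np` future predictors (and symmetrically for
terminal gaps when np = 0); near the sequence boundary the count is
truncated to what fits, with one model per available count. The
edge-constrained types are processed last with `np` reduced to `n_before`
and/or `nf` to `n_after`, then treated as internal.

**Within-gap order.** We fill strictly left to right within each gap, with
the future-predictor block anchored past the *remaining* gap. An
alternating-edges order (filling from both ends in turn) was considered and
not implemented: it would break the one-model-per-remaining-length sharing
that also underpins the timing variant, and the left-to-right order is the
one the recursive-edge description pins down unambiguously.

**Sparse-training fallback ladder.** If a training set holds fewer than
`minTrainRows` windows (default 10 — below that a multinomial fit is
dominated by the ridge prior anyway), the engine (1) shrinks the window to
at most one predictor per side, (2) falls back to a first-order Markov
model pooled over all adjacent observed pairs, applied to the nearest
available neighbour, and (3) finally to the marginal distribution of
observed states. Every fallback is recorded in the fit log.

## MICT-timing

Two changes: gaps of the same remaining length are imputed *separately by
target position*, and each model is trained only on windows whose target
lies within `radius` time points of the cell being imputed. Radius 0 uses
same-position windows only; radius T − 1 is provably identical to MICT
(the test suite asserts training-set equality row for row). The time-frame
filter applies to the *target* position of a window, not its predictors —
the quantity that must be locally stationary is the conditional
distribution of the target.

When a frame is too sparse the radius is widened one step at a time
(logged) before the MICT ladder engages; this preserves the timing idea as
long as any local data exist. Whether a reference implementation would
widen or fall back immediately is not determined by the algorithm's
description; widening is this package's choice.

The cost of position-specific models is real (hundreds to thousands of
small fits per imputation on monthly-scale panels) but each fit sees few
rows, and duplicate predictor/response rows are collapsed into case
weights, which keeps the multinomial fits cheap without changing the
likelihood.

## FCS

Each time point is one categorical variable. Missing cells are initialised
by draws from their column's observed marginal; the algorithm then cycles
`nIter` times (default 10; with strongly informative neighbours the chain
moves little after a handful of sweeps) over t = 1..T in ascending order.
At each visited column with original missingness it fits a model on the
rows *originally observed* there — predictors taken from the current
working values of the chosen set — and redraws all originally missing cells
of that column. `nIter = 0` is defined as "initial fill only" and doubles
as a marginal-draw baseline (`methodMarginal`). Predictor sets: `P1`,
`PF1`, `P5`, `PF5`, `all`, `past`, with indices clipped to the axis; an
empty set (t = 1 under `past`) degrades to a marginal redraw, logged.
Collinearity among the one-hot predictors under `all` is handled by the
same ridge protection as everywhere else rather than by predictor pruning.
We redraw the target column only on each visit (the sequential
chained-equations reading); no convergence diagnostic is computed — the
iteration count is the only stopping rule.

## VLMC

The observed subsequences (sequences split at gaps) feed a context tree up
to `maxDepth` (default 6 — deep enough that on yearly panels the AIC, not
the cap, does the selecting, while keeping length-72 monthly panels
tractable). Contexts are stored most-recent-first; the suffix of a context
drops its oldest state. Positions without a full-depth history contribute
to every truncated context they do have, so a node's counts equal its
children's plus boundary occurrences.

Pruning is bottom-up. The *context algorithm* keeps a node iff its deviance
against its suffix, 2 Σ_s n(s|c) log(P(s|c)/P(s|suffix)), exceeds the
chi-square quantile qchisq(1 − q, |A| − 1), or a descendant survives. The
*Learn-PSA* criterion keeps a node iff some next-state probability ratio
against the suffix reaches r (or 1/r), with a minimum-count guard: contexts
seen fewer than twice are pruned regardless — this guard plus add-1/|A|
smoothing at prediction time stands in for the full Learn-PSA
minimum-probability machinery, whose settings the two-sentence standard
description leaves open. Candidate thresholds are q ∈ {0.1, 0.05, 0.04,
0.03, 0.02, 0.01, 0.001} and r ∈ {1, 1.05, 1.1, 1.2, 1.5}.

The threshold is selected by AIC = −2 logLik + 2 k (|A| − 1), where k
counts the terminal contexts of the *completed partition*: every leaf is
one cell, and an internal node with c kept children contributes |A| − c
complement cells. Counting only the contexts actually used would
under-penalise single spurious splits (a kept noise node whose deviance
just clears a lenient quantile would pay for itself); the partition count
is the parameter count of the model as a predictor and restores the
expected behaviour that iid data select the memoryless model. Ties go to
the smaller tree.

Imputation fits the tree once; each of the M imputations scans every
sequence left to right, drawing each missing cell from the smoothed
next-state distribution of the longest matching context of the
observed-plus-imputed prefix. The first cell of an initial gap has no
prefix and is drawn from the panel-wide state distribution. By
construction the algorithm never reads the future — the suite verifies
that permuting a sequence's future cells leaves an imputed draw unchanged
under a fixed tree.

## Amputation mechanisms

The MAR gap generator sweeps each unprotected sequence: a gap starts at
t = 1 with probability 0.06; at t > 1, when no gap is running, with hazard
0.20 if the *true* previous state is in the configured high-risk set and
0.03 otherwise; an ongoing gap continues with probability 0.66. Attrition
triggers from t = ceiling(T/2) + 1 with hazards 0.10 / 0.015 and blanks
everything from the trigger on. The small-sample variant subsamples 200
cases uniformly, then applies the MAR mechanism — protection applies within
the subsample, since the subsample is the dataset the analysis sees.

Hazards are evaluated against the true pre-amputation state: the generator
is a simulation device that sees complete data. After a gap ends, a new gap
may start at the next step (a renewal process); the stated probabilities
are per-step hazards, which makes empirical recovery by direct counting
exact. 40% of sequences (ceiling) are protected as fully observed; a
sequence losing more than 75% of its cells has its mask regenerated from
scratch, sequence by sequence, which introduces a mild truncation bias in
the realised hazards — for that reason every hazard-recovery check (tests
and the acceptance script) disables the redo rule and the protection. The
high-risk state set is a required argument: it should name states frequent
enough across the time axis that missingness can occur at any time.

## Estimands, pooling, and the study engine

Timing estimands are state frequencies per time point; duration estimands
are mean spell lengths per state (total cells in the state divided by the
number of maximal runs, pooled over sequences; states with no spells are
dropped with a note, which is distinct from a mean of zero); sequencing
estimands are relative risks RR(a→b) pooled over all adjacent pairs. The
pooling over t (rather than per-t risks) is a definitional choice — the raw
transition counts are exposed so alternative definitions can be computed.
An infinite RR is capped (default 100) and flagged; a rare-frequency floor
for timing estimands exists but defaults to 0 (keep all).

Within-imputation variances come from a sequence-level bootstrap (default
B = 1000). Rubin's rules combine the M estimates: total variance
W̄ + (1 + 1/M) B, degrees of freedom (M − 1)(1 + W̄/((1+1/M)B))², infinite
when B = 0, and a 95% t interval. M defaults to 5 — the conventional
choice, configurable everywhere.

`runStudy` resamples the complete panel with replacement each repetition,
amputes, imputes with each method, pools, and reports per-estimand bias,
coverage and variance with Monte Carlo standard errors
(sd/√R for bias, √(c(1−c)/R) for coverage, multiplier 1.96 for the Monte
Carlo intervals in the summary). The truth is, by default, the estimand on
the original complete panel, fixed across repetitions; scoring each
repetition against its own resample is available via `truth = "resample"`.
The fixed-truth default makes the oracle method's coverage interpretable
(the bootstrap variance estimates exactly the resampling variability
around the fixed target) and is asserted by the calibration test. Method
failures are caught per repetition, counted, and excluded for that method
only; an optional on-disk cache makes long runs resumable. Identical
master seed and configuration give bitwise-identical results — every
repetition, method, imputation and bootstrap derives its own stream from
the master seed.

## Imputation models

The multinomial model is a softmax regression on one-hot expansions of the
categorical predictors (all |A| columns per predictor; the redundancy is
harmless under a penalty), fitted via `nnet`. Perfect-prediction protection
is a small ridge penalty (`lambda = 1e-3`) on the weights: it keeps every
weight finite, hence every fitted probability of a category seen in
training strictly inside (0, 1), including under complete separation. This
is a penalisation-style implementation of the protection idea; the penalty
also covers the collinearity that arises under rich predictor sets. A
single-category response cannot be fitted; it returns a
degenerate-but-protected distribution with probability 1 − ε on the seen
category (ε ≤ 0.005, shrinking with the training size) — the one situation
where mass leaks to otherwise-unseen categories, since a strict (0, 1)
guarantee and exact zeros cannot coexist on a one-category vector.
Otherwise categories absent from training receive probability exactly 0,
so imputation can never invent states the windows never showed. A
predictor category unseen in training maps to the all-zero one-hot block —
never an error. Duplicate (predictor, response) rows are collapsed into
case weights before fitting; the weighted likelihood and penalty are
identical, and fits on low-order categorical designs become essentially
constant-time.

The random forest (via `randomForest`) uses 100 trees, √p candidate
predictors per split and unlimited depth — the standard default
parameterisation, which random forests are known to tolerate well; class
probabilities are the fraction of trees voting for the class, and fits are
deterministic under a fixed seed.

## Synthetic archetypes

`panelPreset` provides six first-order (optionally time-heterogeneous)
Markov generators emulating the main configurations of life-course data:
near-constant yearly civil-status records (~1.6% transitions), volatile
ordinal health-satisfaction scores (~36.5%), strongly age-graded careers
(~10%, education-exit hazard ramping with age), monthly school-to-work
sequences (~3.6%, school-leaving concentrated at months 12, 24, …, 72),
near-irreversible cohabitation histories (forward-only moves, average
number of visits ≈ 1), and a generic moderate-persistence small-sample
template. The presets are calibrated to those headline transition
percentages, sequence lengths and alphabet sizes — not to the
micro-structure of any proprietary panel — so simulation results with them
are expected to reproduce qualitative method rankings, not any particular
published figure. What they deliberately do not emulate: covariate-driven
heterogeneity between individuals, duration dependence within spells
(dynamics are first-order Markov), measurement error, and ragged entry.
Passing tests on these panels therefore show that the algorithms recover
the structures the generators contain; real panels can contain more.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in a few minutes while every stochastic assertion rests on
a comfortable number of trials: hazard recovery uses 20,000–40,000
sequences of length 20 (≥ 10⁵ in-gap steps for the continuation rate);
the oracle-calibration study uses 100 repetitions of a 300 × 15 panel with
M = 3 and a 200-replicate bootstrap; the seasonal MICT vs MICT-timing
contrast uses the monthly archetype at n = 300 with 20 repetitions, M = 3,
and the same PF1 predictor set for both algorithms so that the time-frame
restriction is the only difference being measured. Tolerances on stochastic
checks are stated in binomial standard errors of the quantity measured.
Master seeds derive per-imputation, per-stage, per-repetition sub-streams
through a fixed integer mixing function, so every result in the package is
exactly reproducible from one integer.

## Limitations

Time-varying covariates are not supported (fixed covariates are); the
training-window design stays purely sequence-based. Multichannel
trajectories, MNAR mechanisms, calendar-aware time frames (e.g. pooling
the same month across years), probability forests, and convergence
diagnostics for the chained-equations loop are out of scope. The
sequencing relative risk is one defensible definition among several; its
capped-infinity convention makes it unsuitable for averaging when the
denominator event is structurally absent, which is why capped values carry
a flag.
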