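---
title: "Modelling leadership in foraging pairs as a 12-state Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leadership in foraging pairs as a 12-state Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairlead)
```

## The behavioural system and the model

Two fish sharing a tank alternate between a safe refuge ("cover") and an
exposed foraging area.  The pair members are labelled *bold* and *shy* by
their temperament score — the ratio of an individual's intensity of leaving
cover to its intensity of returning, measured in isolation.  An observer
records, for each fish, the exact times of every departure from and return
to cover.

`pairlead` models the pair as a continuous-time Markov chain whose state
combines four binary variables:

* the **location** of the bold fish and of the shy fish (cover/exposed),
* two **status** variables: which fish *initiated* the current trip (the
  first to leave cover after both were in safety) and whether its partner
  has *joined* it.

Two rules make only 12 of the 16 combinations feasible: when both fish are
out, the partner has by definition joined; and an unjoined solo excursion
can only be the initiator's own.  Every state offers exactly two moves (one
per fish), giving 24 directed transitions.  The status variables update
deterministically with each move: a departure from a both-covered state
resets the initiator to the mover with `joined = FALSE`; a departure by the
non-initiator while the initiator is out sets `joined = TRUE`; all other
moves preserve the status.  `pair_state_space()` builds this object and
`transition_target()` applies the update rule.

The scientific question is whether the status variables matter at all: does
taking the initiative change how an animal responds to its partner for the
rest of the trip, beyond what current positions explain?

## Likelihood

Transition times are observed exactly, so the log-likelihood is the
standard fully-observed CTMC form: each sojourn of length $t$ in a state
with total exit intensity $\Lambda$ contributes $-\Lambda t$, and each
observed transition along an edge with intensity $q$ adds $\log q$.  The
final sojourn of a session is right-censored and contributes exposure only.

The interval before a session's first event is special: the status
variables are undefined there (nothing has been observed that would set
them).  `encode_pair()` emits this interval as a visit with *unknown*
state, which carries **zero likelihood exposure**; the first departure
defines the first initiator.  We preferred this to inventing a status for
unobserved history — the cost is at most one sojourn per session.

The sufficient statistics are, per transition class $c$ and pair $p$, the
event count $n_{cp}$ and the exposure $E_{cp}$ (total time spent in the
class's source states).  All estimation works from these matrices, which is
what makes the bootstrap and the simulation studies cheap.

## Model variants as parameter tying

Rather than building separate chains, the model family is expressed as
*tying schemes* that assign the 24 edges to shared rate classes
(`tying_scheme()`):

| scheme           | classes | rates may depend on                              |
|------------------|--------:|--------------------------------------------------|
| `full`           |      24 | locations, initiator identity, joined flag       |
| `initiator_only` |      16 | locations and initiator identity                 |
| `memory_free`    |       8 | locations only (mover, move, partner's location) |

These are nested, so `lrt()` compares them by likelihood ratio with
degrees of freedom equal to the class-count difference (16 and 8 against
the full model).  A separate, non-nested alternative bounds the *duration*
of status effects: the **one-step-memory** chain, whose 8 states pair each
location combination with the immediately preceding one
(`one_step_state_space()`, `project_one_step()`).  "Remembers only the
previous location configuration" admits exactly one topology under
single-mover dynamics — each location combination has exactly two
single-move predecessors, giving $4 \times 2 = 8$ states and 16 edges —
and that is the construction adopted.  Because it is not nested in the
full model, the comparison goes through AIC (`aic_compare()`).

## Covariates

Pair-level temperament scores enter the intensities log-linearly:
$q_{cp} = q_c \exp\{\beta_c (x_p - \bar x)\}$, with one coefficient per
(covariate, class) combination.  By default both scores (bold's and shy's)
may affect every class; `covariate_spec("own")` restricts each score to the
classes its own fish moves in, fixing partner effects at zero (24 fewer
parameters).  Two conventions the analyst must pick, and the package's
defaults:

* **Centering.**  Covariates are centered at their across-pair mean before
  entering the model — the convention of standard multistate software — so
  the baselines describe an average pair.  The offsets are stored in the
  fit; coefficients are invariant to the choice.
* **Transform.**  Raw scores by default; a `log` option exists because
  scores are rate ratios and right-skewed.

Because the likelihood separates by class, `mle_fit()` decomposes into
independent Newton optimizations of at most three parameters each —
formally a Poisson regression of $n_{cp}$ on the centered covariates with
offset $\log E_{cp}$.  Baselines are parameterized as $\log q_c$, so
positivity holds by construction.  Convergence requires the per-class
gradient norm to fall below $10^{-8}$ relative to the class's event count;
the unit tests verify agreement with the closed-form estimate
(`mle_closed_form()`, events/exposure) to $10^{-6}$ relative from arbitrary
starting points, and against `glm()` as an independent route for covariate
fits.  Degenerate designs (a covariate constant across pairs) are refused
rather than silently returning an unidentified coefficient.

Classes with exposure but no events estimate to intensity 0 and are
excluded from log-scale optimization; classes never at risk (zero exposure)
are reported as non-estimable `NA`.  Both are flagged in the fit.  The free
parameter count `k` deliberately counts *all* classes and requested
coefficients, so degrees of freedom of model comparisons reflect the model
structure rather than accidents of a small sample.

## Inference

Pairs are the independent sampling units, so the primary inference path is
a **nonparametric bootstrap over pairs** (`ctmc_bootstrap()`): resample
pairs with replacement, re-estimate, take percentile intervals.  For a
ratio of intensities (the natural scale for "is this transition faster than
that one"), the two-sided p-value is twice the smaller tail of the
replicate distribution around 1, floored at $2/B$.  Several bootstrap
units are defensible; resampling whole pairs (both sessions) is the choice
most consistent with a design whose replication unit is the pair, and a
parametric bootstrap (`parametric_bootstrap()`) is provided as a
sensitivity check.  Estimator failures on a replicate are recorded and the
replicate redrawn, with a retry bound.

Sessions of a pair are pooled into one likelihood unit by default
(`pool_sessions = TRUE` in `cli_fit()`), since the likelihood is additive
and the pair, not the session, is the replication unit; a flag keeps them
separate for sensitivity analyses.

## Sequence statistics

`initiation_sequence()` extracts one record per departure from safety, with
the initiator's identity and whether the partner joined before both
returned.  A trip unresolved at the censoring time keeps its exposure in
the likelihood but is dropped from sequence statistics (standard
right-censoring).  On the initiator labels, `runs_z_score()` computes the
Wald–Wolfowitz z (negative = clumping, i.e. streaks of initiations by the
same fish), and `sign_binomial_test()` gives the exact two-sided binomial
p-value for the across-pair count of negative scores.  Both successful and
failed initiations enter the sequence by default — the definition is "first
leaves cover after both fish have returned to safety", which does not
require success — and a flag (`include_failed`) computes the
successful-only variant.  `trip_position_changes()` counts, for each
completed joint trip, the location changes strictly between the join and
the final two returns: termination attempts and re-joinings, the "position
changes" over which leadership persists.

## The synthetic-study generator

No raw observations ship with the package, so `make_study()` generates
event logs with the statistical structure the analysis assumes: per-pair
temperament scores (two log-normal draws, larger = bold), per-pair edge
intensities through the same log-linear model the fitting code uses, and
exact Gillespie simulation of each session (`simulate_pair_session()`),
serialized to the same CSV dialect the readers consume.  One root seed
drives per-session derived streams, all recorded in the truth record.

The default configuration mirrors the motivating experimental design: 20
pairs, two one-hour transparent sessions each.  `default_pair_rates()`
holds illustrative per-minute intensities built to satisfy the qualitative
structure the model family targets (bold leaves faster/returns slower;
partner-out raises leave rates and lowers return rates; initiators are more
resolute; success breeds initiation, and failure deters only the shy fish),
scaled so the stationary expectation is ≈54 completed trips per fish per
hour with ≈0.8 position changes per joint trip.  They are package fixtures,
not estimates from any real data set.  Temperament scores are drawn from a
log-normal with `meanlog = -1`, `sdlog = 0.5` (median ≈0.37: fish spend
most time under cover), a spread comparable to what temperament assays of
this kind produce.

What the generator deliberately does **not** emulate: diurnal or
within-session non-stationarity, measurement error in event times,
behavioural lateralization or spatial structure, and any dependence between
pairs.  Tests passing on synthetic data therefore certify the *estimation
machinery* (encoding, likelihood, optimization, calibration of tests and
intervals under the model), not the biological adequacy of the Markov
assumption for real fish.

## Numerical and degenerate-input choices

* Simultaneous timestamps violate single-mover dynamics and are rejected;
  `read_session_logs(tie_epsilon=)` resolves digitisation ties by a
  deterministic forward shift.
* Times are seconds in logs and trajectories; intensities are reported per
  minute (readable magnitudes at ≈54 trips/hour).  Likelihood differences
  between models are invariant to the unit, and a test asserts it.
* The simulation starts each session in a both-covered state (state 1);
  the choice only affects the first sojourn's clock, which the encoder
  marks unknown anyway.
* `lrt()` clamps statistics in $[-10^{-6}, 0)$ to 0 (floating-point noise)
  and warns on anything more negative; non-nested inputs are refused with a
  dedicated condition class rather than returning a misleading p-value.

## Problem sizes used by the test-suite simulation studies

Calibration checks run at desk scale, chosen so each study still yields
tens of events per transition class: LRT null calibration uses 300 studies
of 6 pairs × 1 h under the memory-free model (the full-vs-memory-free
statistic is then compared to $\chi^2_{16}$ by a Kolmogorov-Smirnov test,
and the empirical type-I error at 0.05 must sit in [0.02, 0.09]); bootstrap
coverage for a covariate effect uses 100 replicates of the full 20-pair ×
2-h design with $B = 200$; oracle-equivalence and round-trip checks use 50
and 1000 small sessions respectively.

## Known limitations

* Exact observation times are assumed throughout; there is no
  interval-censored (panel) likelihood, and no hidden-state machinery.
* Wald intervals are not offered; inference is bootstrap-percentile only.
* The one-step-memory chain is the single-mover construction described
  above; a differently specified short-memory alternative would change the
  AIC comparison, though not the nested LRT results.
* Groups larger than two and spatially explicit designs (e.g. two
  alternative feeding sites) are out of scope.
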