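---
title: "Models of collective nest-site choice with heterogeneous acceptance thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of collective nest-site choice with heterogeneous acceptance thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestchoice)
```

## The scientific question

House-hunting ants such as *Temnothorax albipennis* choose a new nest
collectively: scouts assess candidate cavities, recruit nest-mates to sites
they accept, and the colony commits to a site once the number of ants there
reaches a quorum. One candidate mechanism for choosing the *better* of two
sites without any individual comparing them directly is heterogeneity in
acceptance thresholds: some workers are satisfied by any site
(*low-threshold* ants), others only by a good one (*high-threshold* ants).
This package implements a minimalist pair of models of that mechanism — a
deterministic mean-field model and its finite-population stochastic twin —
plus the experiment harness needed to ask when the mechanism produces
speed–accuracy trade-offs (slower decisions being more accurate) and
speed–cohesion trade-offs (faster emigrations splitting the colony).

## The mean-field model

The colony faces one good and one poor new site. Each ant is in one of nine
states, tracked as colony fractions:

| state      | meaning                                              |
|------------|------------------------------------------------------|
| `x_lc`, `x_hc`       | low-/high-threshold ants in the current nest |
| `x_lpcom`  | low-threshold ants committed to the poor site        |
| `x_hpvis`  | high-threshold ants *visiting* the poor site (never committing) |
| `x_lgcom`, `x_hgcom` | ants committed to the good site              |
| `x_lprec`  | low-threshold recruiters to the poor site            |
| `x_lgrec`, `x_hgrec` | recruiters to the good site                  |

With $H$ the high-threshold fraction ($L = 1 - H$), the dynamics combine
four processes, each a term in the nine coupled ODEs implemented in
`ode_rhs()`:

* **Recruitment** is mass-action: ants in the current nest are recruited at
  a rate equal to the fraction of recruiters, the per recruiter–recruitee
  pair rate being fixed at one — this choice *defines the time unit* of the
  model, and all other rates are expressed in it. Recruitment to the poor
  site is done by `x_lprec` only (high-threshold ants never recruit to a
  site they do not accept); recruitment to the good site by
  `x_lgrec + x_hgrec`.
* **Conversion**: committed ants become recruiters at rate $\alpha_p$ (poor
  site) or $\alpha_g$ (good site). The symmetric choice
  $\alpha \equiv \alpha_p = \alpha_g$ isolates the threshold mechanism from
  recruitment-latency effects; the two rates remain independently settable.
* **Switching**: a high-threshold ant recruited to the poor site is
  unsatisfied, lingers as a visitor, and moves to the good site at rate
  $\alpha_s$.
* **Leakage**: every ant away from the current nest returns to it at rate
  $\alpha_{leak}$, after which it can be recruited anew — the only way an
  ant can end up changing sites apart from the high-threshold switch.

Two exact constraints follow: the low-threshold compartments always sum to
$L$ and the high-threshold ones to $H$. The initial condition places a
fraction $z$ of the colony as scouts, split equally between the two sites
(low-threshold scouts commit, high-threshold scouts at the poor site only
visit); everyone else starts at home.

The *vote* for the good site is
$x_{lgcom} + x_{hgcom} + x_{lgrec} + x_{hgrec}$; the poor site's vote also
counts the visitors, $x_{lpcom} + x_{lprec} + x_{hpvis}$ — a deliberately
conservative counting, since visitors stand in the poor site without
endorsing it. In the deterministic model the good site's vote dominates the
poor site's at every $t > 0$ whenever $H > 0$; the test suite verifies this
dominance numerically over a 108-point parameter grid rather than
re-deriving the analytical proof.

### Numerical choices

Forward Euler with step `dt = 0.001` is the reference integrator
(`integrate_euler()`). The dynamics are smooth, bounded and contracting
toward equilibria, Euler at this step conserves the class sums to below
$10^{-6}$ over $10^3$ time units (asserted in the tests), and step-halving
moves the trajectory by less than $10^{-3}$; a fancier integrator would buy
nothing for these trajectories while complicating exact reproducibility.
The exact flow preserves positivity, so the integrator treats any excursion
below $-10^{-12}$ as evidence the step is too large and aborts; smaller
excursions are round-off and are clipped to zero on output. Stored
trajectories keep every 10th step by default; quorum detection
(`ode_quorum_time()`) always re-runs at full step resolution so the
reported crossing time does not depend on the storage stride.

A configuration whose quorum fraction is at or below the initial scout vote
$z/2$ would be "decided" at $t = 0$; such configurations are rejected
rather than reported, because a sweep containing them would silently
measure nothing (`allow_initial_quorum = TRUE` downgrades this to a
warning).

## The stochastic twin

`gillespie_run()` reinterprets every term of the ODEs as a Poisson event
channel for a colony of `N` ants — fifteen channels in all (four
recruitment, three conversion, one switch, seven leakage), each moving
exactly one ant, with per-capita rates identical to the mean-field terms
(recruitment is normalised by the total `N`, not by current nest
occupancy). Simulation is *exact* event-driven sampling: exponential
waiting times from the total rate, channels chosen proportionally to rate.
We chose the exact sampler as the reference engine because it removes the
step size as a confounder; the fixed-step description ("each transition
fires with probability rate × Δt") is implemented too
(`discrete_time_run()`) and the suite checks that the two agree on mean
time-to-quorum at `dt = 0.01`, which functions as a cross-validation of
both engines. In the discrete engine every per-ant per-step probability
must stay below 0.1, or the run aborts naming the offending channel.

Initial counts must scale the mean-field initial condition to whole ants
exactly; non-integer compartments are a configuration error, because silent
rounding would make the stochastic and deterministic models start from
different colonies. (An explicit largest-remainder mode exists for
exploratory work; no shipped experiment uses it.)

After every event the integer votes are compared with the quorum threshold
`quorum_fraction * N`. Because each event moves one ant, the two votes can
never first reach the threshold simultaneously, so no tie-break is needed.
A run ends in one of: `good_quorum`, `poor_quorum`, `unsuccessful` (total
rate zero — leakage returned every ant home, an absorbing state), or
`censored` at `t_max`. The default horizon `t_max = 1e5` exists only to
guarantee termination; censored runs are counted separately from
unsuccessful ones and surfaced with a warning, since silently folding them
into either category would bias the time statistics.

## Speed–accuracy experiments

`run_batch()` repeats the stochastic model and reports, over *quorate runs
only*, the mean time-to-quorum $T$ and the accuracy $P$ (fraction choosing
the good site); unsuccessful and censored runs are excluded from both and
reported as counts. The canonical replication is $10^4$ runs per parameter
set; the test suite uses 1 500–5 000 runs per point, sized so that the
Monte-Carlo standard errors are several times smaller than the trend gaps
being asserted. Per-run seeds derive from the master seed by an additive
counter, so any single run can be replayed from the batch manifest.

The default confidence half-width is the standard
$1.96\,\mathrm{sd}/\sqrt{n}$. Some published figure captions for this class
of experiment print $1.96\,\mathrm{sd}/n$ — dividing by $n$ rather than
$\sqrt{n}$ is almost certainly a typo, but `ci_halfwidth(..., "literal")`
reproduces it verbatim; the default never propagates it.

`sweep_param()` runs one batch per value of `H`, `z`, `quorum_fraction`,
`alpha_s` or a rate, and summarises the sweep by the Pearson correlation of
the per-value $(T, P)$ summary points — one point per value, unweighted,
because the diagnostic concerns how the *summaries* covary. A positive $r$
is a speed–accuracy trade-off; a negative $r$ means speed and accuracy
improve together. With fewer than three valid points, or a degenerate
coordinate, the correlation is reported as undefined rather than computed.
The default six-point `H` grid `{0, 0.2, 0.4, 0.6, 0.8, 1}` is the only
evenly spaced six-point grid that keeps every initial compartment integer
at `N = 100`, `z = 0.3`; it is a package inference, overridable wherever
the integrality constraint allows. Swept values that violate integrality
are reported per-value as errors, never silently dropped.

## Speed–cohesion experiments

When all `N_nest` candidate sites are equally good, accuracy is moot and
the interesting outcome is whether the colony stays together. Equal quality
is modelled by giving every ant the low threshold (`H = 0`) and disabling
switching (`alpha_s = 0`): a committed ant has no reason to move. The
engine (`cohesion_run()`) is the same event-driven scheme generalised to
`N_nest` committed/recruiter compartment pairs. Scouts are split equally —
`N z / N_nest` per site must be integer, which is why the canonical design
uses `z = 0.12` at `N = 100` (12 scouts divide evenly among 2, 4 or 6
sites). No quorum rule applies; a run *finishes* when 90% of the colony
(`finish_fraction = 0.9`) occupies the new sites, and reports the finish
time $T_f$ and the cohesion index

$$C = 1 - \frac{-\sum_i p_i \log p_i}{\log N_{nest}},$$

one minus the normalised Shannon entropy of the occupancy shares:
$C = 1$ when a single site holds everyone, $C = 0$ at a uniform split.
Terms with $p_i = 0$ contribute nothing, and the endpoint values are
clamped to be exactly 0 and 1 (the closed form hits them up to $10^{-16}$
round-off).

Two conventions here were genuinely open and are worth recording. First,
the shares $p_i$ are normalised over the ants *in new sites* at $T_f$, not
over `N`: the entropy formula presupposes a probability distribution, and
with the 0.9 N finish rule up to a tenth of the colony is still at home;
both the raw per-site counts and the shares are returned so either
normalisation can be inspected. Second, a site's occupancy counts its
committed *and* recruiting ants — recruiters belong to the site they
recruit for, exactly as in the two-site vote counting.

## What the simulations do and do not emulate

All experiments here are self-contained simulations of the model; there is
no external data. The stochastic engine emulates demographic noise in a
finite colony — the only stochasticity the model has. It does *not* emulate
spatial structure, travel times, per-ant memory or identity, tandem-running
mechanics, the rapid-transport phase that follows a real quorum, or
quality-assessment noise. Passing tests therefore show that the
*threshold-heterogeneity mechanism* behaves as claimed inside this model
family, not that real colonies are free of those other factors. The
`pratt` preset (`alpha = 0.5`, `alpha_s = 0.25`) rescales rate constants
estimated from Temnothorax emigration experiments by Pratt and colleagues
into this model's time unit, and sits in the parameter region where
varying `H` or `z` produces *no* speed–accuracy trade-off.

## Problem sizes and reproducibility

The shipped test-suite sizes are: $10^4$ runs for the headline accuracy
and correlation checks; 1 500–5 000 runs per point for monotone-trend
assertions; 30 replicate trajectories at $N = 10^4$ for the mean-field
limit check; and a 108-point grid for vote dominance. These sizes put
Monte-Carlo error well below every asserted margin while keeping the whole
suite under a minute on one core. Every stochastic result in the package is
a pure function of `(parameters, seed)`; batch outputs carry a manifest
(master seed, derivation scheme, parameter record) sufficient to replay
them bit-for-bit.

## Known limitations

* The mean-field model is seven-dimensional after the two class-sum
  constraints, but is integrated in all nine coordinates for clarity; the
  constraints are monitored, not eliminated.
* Forward Euler is first-order; the shipped step `0.001` is validated for
  the rate ranges exercised here (rates up to ~1). Much stiffer rates
  would need a smaller step, and the integrator will say so by detecting
  negativity rather than silently losing accuracy.
* The three-threshold / three-site generalisation and recruitment-latency
  experiments with $\alpha_g \neq \alpha_p$ are parameterisable but no
  shipped experiment exercises them.
* `unsuccessful` outcomes require leakage; at the standard rates they are
  rare, so their exclusion barely moves $T$ and $P$ — but the counts are
  always reported, so the effect is checkable.

## A worked example

```{r example}
base <- nest_preset("baseline")
b <- run_batch(base, n_runs = 2000, seed = 7)
b

sw <- sweep_param(base, "H", default_H_grid(), n_runs = 500, seed = 3)
sw$summaries[, c("value", "T_mean", "P")]
sw$pearson_r

cb <- cohesion_batch(cohesion_params(N_nest = 4, z = 0.12), n_runs = 500,
                     seed = 1)
cb
```
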