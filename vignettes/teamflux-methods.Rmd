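---
title: "Expression-constrained dynamic flux balance analysis with teamflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-constrained dynamic flux balance analysis with teamflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamflux)
```

## The problem

Batch cultures reroute metabolic flux as their environment changes:
substrates are consumed, partially oxidized intermediates (acetate,
pyruvate, formate) are secreted during fast growth and re-imported after
substrate exhaustion. Plain dynamic flux balance analysis (dFBA) — a chain
of static FBA solutions coupled by Euler updates of the extracellular
pools — predicts efficient, tidy substrate use and typically misses this
overflow metabolism entirely, because at every instant it routes carbon
through the highest-yield pathway.

`teamflux` constrains each step of a dFBA simulation with time-series gene
expression. Instead of maximizing growth, each step finds the flux
distribution *minimally inconsistent* with the transcriptional state:
reactions whose genes are expressed below a threshold are penalized in
proportion to the shortfall, and the linear program minimizes the total
penalized flux while still delivering the experimentally measured growth.
Repression of respiratory genes mid-course then forces flux through
low-yield, secreting pathways — overflow emerges from the data rather than
from ad hoc kinetic switches.

## The per-step optimization

At each time $t$ on the grid $0, \Delta t, 2\Delta t, \dots$ the engine
solves two LPs over the flux vector $V$ (mmol/hr, total units):

1. **Inconsistency minimization.**
   $\min \sum_i c_i(t)\,|V_i|$ subject to $S V = 0$ and
   $lb(t) \le V \le ub(t)$, where $c_i(t) \ge 0$ is the penalty of
   reaction $i$ at time $t$.
2. **Flux minimization at the locked optimum.**
   Among the usually many alternative optima,
   $\min \sum_i |V_i|$ subject to the same constraints plus
   $\sum_i c_i|V_i| \le z^* + \varepsilon$, with $z^*$ the stage-1
   optimum. This selects a parsimonious representative and removes futile
   cycles.

Bounds are rebuilt every step:

* **Media pools.** Uptake of metabolite $i$ is limited to the pool that
  one step can exhaust, $V_{\mathrm{exch},i} \ge -e_i(t)\,\mathrm{vol}/\Delta t$.
  Positive exchange flux is secretion. Clamped metabolites (e.g. dissolved
  oxygen under DO control) are reset to their clamp value every step.
* **Biomass scaling.** Specific bounds (mmol/gDW/hr) on biological
  reactions are multiplied by the current biomass to give total bounds.
* **Required growth.** With a measured growth curve, the biomass flux must
  reproduce observed net growth plus replacement of death losses,
  $(OD(t+\Delta t) - OD(t))/\Delta t + d\,BM(t)$, floored at 0, with death
  rate $d = 0.06\,\mathrm{hr^{-1}}$ by default. Without this floor the
  all-zero flux state would always be "perfectly consistent".

After each step, pools and biomass advance by forward Euler:
$e_i \mathrel{+}= V_{\mathrm{exch},i}\,\Delta t/\mathrm{vol}$ (floored at
0, flooring logged) and $BM \mathrel{+}= V_{BM}\Delta t - d\,BM\,\Delta t$.

### Growth as an imposed magnitude

A genuinely open design point is whether the observed growth enters as a
lower bound only or as an imposed value. We pin the biomass flux to the
observed value (`rmf_bound = "pin"`, the default in od_derived mode), for
two reasons. First, measured growth is a datum, not an aspiration: letting
the expression-blind baseline exceed it makes the baseline incomparable
with the expression-constrained run. Second, with a floor only, stage 2
drives the biomass flux down to the floor anyway — pinning makes this
explicit and puts `run_dfba()` (maximize growth, then minimize flux) and
`run_team()` with all-zero penalties on *identical* LPs, which the test
suite verifies at machine precision. The classic floor-only behavior
remains available (`rmf_bound = "floor"`), and is the default for
fraction-of-max mode, where the requirement is $p \cdot V_{BM}^{\max}$
with $p = 0.5$ by default. If the requirement exceeds what the model can
achieve (e.g. the substrate ran out earlier in simulation than in the
experiment), the step is *relaxed* to the achievable maximum and flagged,
rather than aborting; a hard-fail mode exists.

## From expression to penalties

Penalties are derived per gene and then propagated to reactions — this
ordering, rather than propagating expression first, lets each gene carry
its own notion of "low".

**Thresholds.** A reference compendium of arrays is pooled with the
experiment's own arrays, and a percentile $\theta$ is chosen:

* *Type 1 (global)*: one threshold, the $\theta$-th percentile of all
  values pooled across genes.
* *Type 2 (gene-specific)*: the $\theta$-th percentile of each gene's own
  pooled samples.
* *Type 3*: Type 2, with each gene's penalty divided by its standard
  deviation over the same pool.

Quantiles use the nearest-rank convention
(`sorted[ceiling(theta/100 * n)]`, $\theta = 0 \to$ min,
$\theta = 100 \to$ max); it is monotone in $\theta$, returns observed
values, and every oracle in the test suite uses the same convention. For
Type 3, near-constant genes get their standard deviation floored at
$10^{-3}$ times the median gene standard deviation to avoid division
blow-up; each flooring is reported.

**Penalties.** At time $t$, gene $g$ with expression $x_g(t)$ below its
threshold $\tau_g$ receives $p_g = \tau_g - x_g(t)$ (divided by
$\sigma_g$ for Type 3); at or above threshold, $p_g = 0$. Genes without
expression data are unpenalized — absence of evidence should not block
flux — and flagged by `validate_model()`.

**Propagation.** Boolean gene-to-reaction rules are evaluated with
AND $=$ max (the weakest subunit limits an enzyme complex) and
OR $=$ min (the best isoenzyme carries the flux); a reaction without a
rule gets $c_i = 0$. AND binds tighter than OR in rule text.

The experiment's own arrays are included in each gene's pooled
distribution by default (`include_experiment = TRUE`); this also
guarantees that at $\theta = 0$ no interpolated expression value can fall
below its threshold, so all penalties vanish and the run reduces exactly
to the baseline.

## Sensitivity analysis and validation readouts

Because $\theta$ is the method's one free parameter, `sweep_thresholds()`
re-runs the simulation for each $\theta$ on a grid (1–99 by default) and
summarizes each trajectory: total secreted concentration per
initially-absent metabolite (summed over grid time points, as heatmap
panels do; a carbon-atom-weighted mode is available since concentration
sums and carbon sums differ), extinction time of each nutrient (first
grid time at or below $10^{-6}$ mM), and residual sum of squares against
observed concentration series. `classify_zones()` labels each $\theta$ by
its secreted-metabolite set and reports maximal contiguous intervals — the
machinery for locating qualitatively distinct regimes and an optimal
threshold range.

For comparing thresholding strategies, the normalized inconsistency score
$IS = \sum_i c_i |V_i| \,/\, \mathrm{mean}_g(p_g)$ (0 when the numerator
is 0) is invariant under uniform penalty rescaling, so Types 1 and 2 can
be compared on one scale. `inconsistency_profile()` computes it per
$\theta$ from single static iterations in fraction-of-max mode.

## The synthetic scenario

All tests run without downloads on a generated scenario
(`make_scenario()`): a ~11-reaction toy model of central-carbon overflow
plus matched expression, compendium, growth and media inputs.

The model routes a lactate-like substrate through a pyruvate node to an
energy currency either via an efficient respiratory branch (3 ATP,
oxygen-dependent, gene `gTCA`) or via low-yield valves producing
secretable acetate-like (`POX`, 1 ATP) and formate-like (`PFL`, 1 ATP)
intermediates, both re-importable and consumable (`ACS`, `FDH`,
oxygen-dependent). Biomass is an energy-plus-oxygen demand — a
maintenance-energy abstraction that keeps the toy small while letting
re-imported acetate sustain the culture after substrate exhaustion. The
valves carry modest capacity (0.1 mmol/gDW/hr) so that overflow volumes
stay commensurate with what late-phase demand can re-consume.

Expression profiles are written in *quantile space*: each gene's
trajectory moves through the quantiles of its own stationary (lognormal)
distribution, so a gene sitting at quantile $q$ at time $t$ crosses below
its Type-2 threshold exactly when $\theta > 100q$. The respiratory gene
dips to its 6th percentile during hours 14–26; the acetate-consumption
gene stays near its 3rd percentile until hour 28 and rises after; the
valve genes dip to the 60th (`gPOX`) and 6th (`gPFL`) percentiles. Gene
means span 0.9 to 220 — over two orders of magnitude — with the essential
lactate-dehydrogenase-like gene at the bottom, which reconstructs the
case for gene-specific thresholds: a pooled threshold reads that gene as
permanently off and penalizes an unavoidable flux, while per-gene
thresholds track its own regulation.

The growth curve is lag–exponential–plateau,
$OD(t) = OD_0 + A/(1+e^{-r(t-t_m)})$ with $OD_0 = 0.25$, $A = 5$,
$r = 0.3\,\mathrm{hr^{-1}}$, $t_m = 18$ hr, sitting below the model's
capacity so that penalties have room to reroute flux. Media: 14 mM
substrate, oxygen clamped at 10 mM. Horizon 50 hr at $\Delta t = 1$ hr;
the experiment contributes 19 array time points; the reference compendium
holds 60 samples with 5% multiplicative measurement noise. These sizes
keep a 99-point threshold sweep comfortably interactive while leaving all
qualitative structure intact.

What the generator does *not* emulate: probe-level microarray artifacts
and normalization, genome-scale network redundancy (hundreds of
alternative pathways), transcription–translation delays, and kinetic
(Michaelis–Menten) uptake. Passing tests therefore demonstrate that the
algorithm recovers designed regulatory structure through a metabolic
network, not that it would quantitatively reproduce any particular
organism's measurements.

## Numerical choices

* **LP solver.** A dense two-phase tableau simplex with Bland's
  anti-cycling rule, row equilibration, and explicit artificial-variable
  elimination lives in the package; problem sizes here are tens of
  variables, where a dense tableau is fast (milliseconds) and exactly
  reproducible. Absolute values are linearized by splitting fluxes into
  nonnegative forward/reverse parts; only reactions whose current lower
  bound is negative get a reverse part. The test suite cross-checks
  optima against an independent LP solver on randomized networks.
* **Lock slack.** Stage 2 holds stage 1's optimum within a relative
  $\varepsilon = 10^{-9}$; LP degeneracy makes the stage-2 feasible set
  tolerance-sensitive, so the slack is explicit and configurable.
* **Ties.** Beyond stage 2 no further tie-breaking is applied; the
  simplex is deterministic, so trajectories are reproducible per solver,
  but alternative optima with equal inconsistency *and* equal total flux
  are resolved arbitrarily.
* **Euler overshoot.** Concentrations are floored at 0 after each update
  and flooring events are recorded; the uptake bound makes the final
  drawdown land exactly on 0 rather than below it.
* **Degenerate inputs.** Zero-length horizons return the initial state;
  empty media start all pools at 0; genes absent from compendium or
  expression input are unpenalized with a warning; infeasible growth
  requirements relax with a flagged status by default.

## Limitations

Single-compartment models only; no kinetic uptake laws, pH or temperature
effects, and no regulatory network mechanisms beyond the expression
penalties themselves. OD-to-biomass conversion is an identity scale by
default (`od_scale`), so biomass units are OD units unless a calibration
factor is supplied. The dynamics are history-dependent: small early
differences in secretion can change which pathways are available later,
so trajectory details — unlike the step-level optima — should be read as
one consistent scenario rather than a unique prediction.
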