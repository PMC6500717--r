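---
title: "Planning stable-stage releases with reintroplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning stable-stage releases with reintroplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reintroplan)
```

## The model

`reintroplan` plans reintroductions for iteroparous species whose female
life cycle is summarized by a stage-structured projection matrix
$\mathbf{L}$ with $m \in \{2,\dots,5\}$ stages. Row 1 holds fertilities
(average female offspring per female per time unit, unbounded above,
zero allowed); every other nonzero entry is a transition probability in
$[0,1]$ — stasis on the diagonal, growth below it. The deterministic
projection is

$$\mathbf{n}_{t+1} = \mathbf{L}\,\mathbf{n}_t
  \quad\Longrightarrow\quad
  \mathbf{n}_T = \mathbf{L}^T \mathbf{n}_0 .$$

Provided $\mathbf{L}$ is *primitive* (nonnegative, irreducible,
aperiodic), Perron–Frobenius theory gives a unique dominant eigenvalue
$\lambda_1 > 0$ — the asymptotic per-step growth rate — with strictly
positive right eigenvector $\mathbf{w}$, normalized here to sum to 1:
the stable stage proportions (SSP). On the ray
$\{c\,\mathbf{w} : c > 0\}$ the matrix acts as the scalar $\lambda_1$,
so a release placed in stable proportions needs no matrix algebra at
all to forecast: abundances at time $t$ are $\lambda_1^t$ times the
release.

The planning step inverts this. A management goal is a pair $(T, B)$: a
timeline of $T$ discrete time units and a desired abundance of $B$
*breeding females* — females in stages whose fertility is strictly
positive (the package derives the breeding set from the matrix; in the
bundled ungulate example, stages 2 and 3). The target population is the
point on the SSP ray whose breeding-stage total is exactly $B$,

$$\mathbf{n}_T = \frac{B}{\sum_{i \in \text{breeding}} w_i}\,\mathbf{w},$$

and the stable-stage-aligned release is the back-projection

$$\mathbf{n}_0 = \lambda_1^{-T}\,\mathbf{n}_T .$$

Both vectors lie on the SSP ray, which is what makes the scalar
inversion legitimate: releases off the ray excite subdominant
eigenmodes, and $\mathbf{n}_T$ would then depend on the whole spectrum,
not on $\lambda_1$ alone.

## Model assumptions

Everything is deterministic, density-independent, female-only, and
time-invariant: no environmental or demographic stochasticity, no Allee
effects, no two-sex structure, no vital-rate change over the timeline.
These are deliberate non-goals; the package supplies illustrative
trajectories, not a population viability verdict, and the user decides
which transient behavior is acceptable.

## Parameters that matter

* **`T`** (positive integer) — timeline in the matrix's own time unit;
  no calendar semantics are attached ("7 years" is 7 units for an
  annual matrix).
* **`B`** (positive real) — breeding females desired at `T`. Abundances
  are carried as continuous reals throughout; whole-animal numbers are
  a display convention (below).
* **`x`** (positive integer, default 1) — rows in the candidate-model
  table: the user's matrix plus the `x − 1` cheapest alternatives.
* **`pool_size`** (default 2000) — candidate matrices simulated before
  ranking; thousands are cheap at these matrix sizes.
* **survival tolerance** `1e-9` — per-column transition sums may exceed
  1 by at most this much, absorbing decimal round-off in user input.

## Display convention: truncation

All user-facing integers and short decimals are *truncated*, not
rounded: a growth rate of 0.90494 displays as 0.904, a stage proportion
of 6.72% as 6%, a target abundance of 88.17 females as 88. Truncation
toward zero is the conservative choice for whole animals (you cannot
release 0.7 of a female), and the package applies it uniformly via
`trunc_dec()`, with a 1e-9 guard absorbing binary floating-point
representation error. Machine-readable outputs (JSON, CSV) always carry
full precision alongside any `_display` field, so the convention can
never contaminate downstream computation.

## Validation and numerical choices

* **Primitivity** is checked exactly on the zero/nonzero pattern by
  raising it to the Wielandt exponent $m^2 - 2m + 2$ (at most 17 for
  $m = 5$) and demanding positivity. Entries are classified zero at 0
  exactly — users enter literal zeros for impossible transitions, and
  an epsilon would misclassify deliberately tiny rates.
* **Survival budget**: the transition entries of each column (rows
  2..m) must sum to at most 1 — an individual survives into at most one
  stage. This is an error, not a warning: a matrix violating it is not
  a probability model. Sparsity is otherwise unconstrained; any
  primitive pattern of probabilities is accepted.
* **Eigenanalysis** uses LAPACK via `eigen()`; the dominant eigenpair
  is selected by maximal modulus, required to be numerically real, and
  the eigenvector is sign-corrected and normalized to sum 1. The test
  suite cross-checks $\lambda_1$ against an independent power-iteration
  oracle run to convergence.
* **Schedules** are computed as $\mathbf{n}_0 \lambda_1^t$ rather than
  by repeated matrix multiplication: on the SSP ray the two are equal
  (the suite verifies this to 1e-8 over hundreds of random life
  histories), and the scalar form accumulates no matrix round-off.
* **Candidate sampling** perturbs every nonzero entry independently and
  uniformly within ±0.5 of the user's value, clamped to $[0,\infty)$
  for fertilities and $[0,1]$ for transitions, preserving the zero
  pattern ("identical life history structure"). Uniform-in-box is the
  declared choice — the ±0.5 neighborhood is the constraint, and with
  no reason to prefer any region of it, the flat law is the natural
  default. Draws violating the survival budget or primitivity are
  rejected and redrawn (cap 1000, then an error signals an infeasible
  neighborhood). An optional `freeze` mask pins entries that biology
  fixes (e.g. fertilities). Ranking ties on total release break toward
  higher $\lambda_1$, then generation order, so reruns are stable.
* **Attenuation/amplification flags** formalize a qualitative notion:
  step $t$ of a transient trajectory is attenuating (amplifying) when
  its total falls below (rises above) the launch total scaled by
  $\lambda_1^t$ — the trajectory an equal-sized stable-stage release
  would follow — with relative tolerance 1e-9.

## The synthetic life-history generator

Property tests run on seeded random matrices from
`random_life_history()`: fertilities uniform on $[0, 2]$ (magnitudes of
a large-mammal example; overridable), one uniform survival draw per
stage within `survival_budget` (default 1) split uniformly between
stasis and growth, stage-1 survival routed entirely to growth (the
top-left cell belongs to the fertility row), and rejection until full
validation passes. Every generated matrix is therefore a valid,
primitive Lefkovitch life history, and generation is reproducible per
seed.

What the generator does *not* emulate: correlated vital rates,
senescence structure, taxon-specific trade-offs, or sampling error in
estimated rates. Passing property tests therefore demonstrates the
algebra — projection, back-projection, ranking, convergence — over a
broad class of plausible matrices, not calibration to any real
population.

One consequence of the generator's breadth is worth stating honestly:
because the stasis/growth split is uniform, a small fraction of draws
put nearly all survival into stasis, yielding almost-reducible matrices
whose damping ratio $\rho = |\lambda_2|/\lambda_1$ approaches 1. For
such life histories transient stage proportions converge to the SSP
only like $\rho^t$, so a fixed-horizon check (say, error $< 10^{-6}$ at
$t = 50$) fails for roughly 5% of draws even though convergence itself
is guaranteed. The suite therefore also verifies convergence at a
damping-aware horizon ($t$ with $\rho^t \le 10^{-8}$), which holds for
every draw; a fixed-horizon variant is retained as a documented
stricter check and is expected to fail on slow-damping draws.

## Problem sizes in the test suite

The suite uses 100 random life histories per stage count (400 total)
for the eigenvalue-oracle and round-trip checks, 10,000 draws for the
uniformity test of candidate sampling, pools of a few hundred matrices
for ranking properties, and horizons of 50–5000 steps for convergence —
sizes at which every check is exact to its stated tolerance while the
whole suite stays fast on a single CPU.

## Known limitations

* Deterministic only: no stochastic envelopes or extinction risk.
* Breeding females are defined by positive fertility; species where
  non-reproducing stages should count toward the goal need the target
  built by hand (`ssd_target_vector` is one line to replace).
* The ±0.5 candidate neighborhood is absolute, which is wide for small
  vital rates (a 0.1 juvenile survival may move to 0.6); use `freeze`
  or rescale judgement accordingly.
* All quantities are female-only; two-sex release budgets must be
  scaled by the user.
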