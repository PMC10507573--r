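---
title: "State-dependent models of juvenile play as practice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent models of juvenile play as practice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decision problem

`playsdp` implements a finite-horizon stochastic dynamic programming model of
how a juvenile mammal should allocate its discretionary time among three
activities — foraging, play, and rest — when play has no immediate benefit but
acts as low-risk practice for a "serious" adult skill. The individual is
described by two integer state variables, energy reserves $x \in \{0,\dots,X\}$
and ability $a \in \{0,\dots,A\}$, and makes one choice per timestep over
$t = 0,\dots,T-1$. Reserves at zero mean death by starvation; at the horizon
$T$ the individual is rewarded only if its reserves have reached a critical
level $x_{\mathrm{crit}}$ (interpreted as the energetic requirement for
reproduction at maturity).

Each activity carries an energy cost per bout ($c_f, c_p, c_r$), a
per-timestep predation risk ($m_f, m_p, m_r$), and, for foraging and play, a
probability ($s_f$, $s_p$) of incrementing ability by one. Foraging is the
only activity that brings in energy ($+y_e$ with probability $y_z$). During
the dependent phase, decision epochs $t < \tau$, the individual additionally
receives parental provisioning ($+w_e$ with probability $w_z$) regardless of
its activity. The intended regime is $c_r < c_f \le c_p$ and
$m_r < m_p < m_f$: play costs at least as much energy as foraging and trains
ability more slowly than foraging ($s_p < s_f$), but is much safer. The
constructor warns (rather than errors) when a parameterisation leaves this
regime, since the sensitivity analysis deliberately explores such corners.

The value function
$$U^*(x,a,t) = \max_{\beta \in \{f,p,r\}} \; (1-m_\beta(a)) \,
  \mathbb{E}\left[\, U^*(x', a', t+1)\,\right]$$
is computed by exact backward induction from the terminal condition
$U^*(x,a,T) = \mathbf{1}\{x \ge x_{\mathrm{crit}}\}\,(x/X)^q\,\rho(a)$, where
the expectation runs over the joint outcome tree (foraging yield,
provisioning, ability increment, energy update capped at $X$, starvation on
$x' \le 0$). Death contributes zero value, so no separate discounting is
applied. The factor $\rho(a)$ is 1 in the first two variants and the
reproduction probability $\omega_z(a)$ in the third.

## The four variants

Ability is an *instrumental* skill; what it improves defines the variant:

* **model1 — antipredator ability.** Foraging predation risk declines
  linearly from $m_f(0) = 0.005$ to $m_f(A) = m_p$. Representative of a
  grazing ungulate whose locomotor play trains escape skills.
* **model2 — foraging success.** The success probability rises linearly,
  $y_z(0) = 0.1$ to $y_z(A) = 0.9$; predation risk while foraging is constant.
  Representative of a predator whose object play trains prey capture.
* **model3a — reproductive ability, play-only practice.** The terminal
  payoff is multiplied by $\omega_z(a)$, rising linearly from 0.1 to 0.9, and
  foraging offers no practice ($s_f = 0$): play is the only route to ability.
  Representative of a solitary-foraging, socially playing rodent.
* **model3b — reproductive ability, foraging better practice.** As 3a but
  $s_f = 0.8 > s_p = 0.5$, as for cooperative hunters whose foraging itself
  exercises social skill.

All ability-dependent rates use the same convex-combination interpolation
`linear_ability_map()`, which is exact at both endpoints — several
equalities in the model (e.g. $m_f(A) = m_p$) are meant to hold to the last
bit, and the naive `v0 + (vA - v0) * a/A` form does not achieve that.

## Numerical choices

**Within-timestep event order.** Predation is resolved first as a survival
factor $(1-m)$; survivors then pay the activity cost, collect stochastic
gains, are capped at $X$, and finally face the starvation check
($x' \le 0$). Because death yields zero value regardless of cause, this
ordering affects only the bookkeeping of death causes, which the forward
model reports separately. Provisioning is received in every epoch with
$t < \tau$ (half-open), independent of activity, and a provisioning gain can
rescue an individual that would otherwise starve in the same step. Ability
increments are independent of foraging success ("with each foraging
session", not "with each successful one"), and both state variables cap
without carryover.

**Terminal shape.** The exponent $q$ enters as $g(x) = (x/X)^q$, so the
default $q = 0$ reproduces the binary payoff and larger $q$ makes surplus
reserves increasingly valuable. Any monotone shape with $g \equiv 1$ at
$q = 0$ is equivalent for the default analyses; the power form was chosen as
the simplest one-parameter family on $[0,1]$.

**Tie-breaking.** This is the one genuinely consequential numerical choice.
In the reproductive-ability variants the *timing* of a play bout is almost
value-neutral: activity mortalities do not depend on the state, so total
survival depends on how many bouts of each activity a life contains, hardly
on their order, and the play-versus-forage action values agree to $10^{-16}$
over broad regions of the state space. `solve_policy()` therefore uses a
strict argmax (`tie_tol = 0`), breaking exact ties toward foraging, then
play, then rest. Sub-machine-epsilon value differences then decide the
near-tie region, which produces the characteristic forage-early/play-late
ontogeny and a persistent mixture of foraging and play through mid-life in
model 3a. Setting `tie_tol` to, say, `1e-12` instead treats the whole
near-tie region as equal and hands it wholesale to the preferred activity:
policy maps become cleaner, but the mid-life play of the
reproductive-ability variants collapses to whichever activity is preferred —
an instructive illustration that in this model family some headline outputs
live on a value plateau rather than at a strict optimum.

**Zero-value states.** States from which $x_{\mathrm{crit}}$ is unreachable
have $U^* = 0$ exactly (products of non-negative terms with an exactly zero
terminal slice), so the policy code `none` is assigned by an exact test, not
a tolerance.

## Forward model and conventions

`forward_propagate()` pushes a point mass at $(x_{\mathrm{start}},
a_{\mathrm{start}})$ through the kernel of the prescribed activity. At each
epoch, mass in `none` states is first absorbed into the no-payoff class;
predation and starvation mass accumulate in their own classes. Conservation
(active + absorbed = 1) holds to $10^{-10}$ at every epoch and is asserted in
the tests. Two normalisations are exposed deliberately:

* `activity_timecourse()` reports proportions of the *initial* cohort (the
  stacked-figure convention), with the cumulative no-payoff class making
  rows sum to one;
* `lifetime_budget()` normalises by *acting* mass only; the 5 %-of-lifetime
  play criterion of the sensitivity analysis uses this convention.

Headline statistics (`trajectory_summary()`) use a mass floor of $10^{-9}$:
an activity is "absent" at an epoch if its mass is below the floor. The
deterministic propagation retains arbitrarily small minority masses (e.g. a
$10^{-8}$–$10^{-4}$ trickle of foragers late in the dependent phase of
model 1, or sub-$10^{-3}$ residues of working low-ability stragglers at the
end of model 3b), so floor-based run lengths such as the play-only prefix
are conservative relative to what a stacked-area plot appears to show —
plots cannot display such masses at all.

The figure-style runs start at $x = 100, a = 0$; the sensitivity analysis
starts at $x = 50, a = 0$. Both conventions appear in the documented
defaults of the corresponding functions.

## Monte-Carlo verification

`simulate_individuals()` is an independent individual-based implementation
of the same policy and outcome tree, used as a stochastic oracle for the
deterministic propagation. Sampling is vectorized across individuals with a
single generator seeded once per run; results are reproducible for a fixed
`(seed, n)`. (Per-individual substreams would make `n` extensible without
reshuffling, but R's generator API offers no cheap substream mechanism and a
scalar per-individual loop is prohibitively slow in pure R; the synchronous
vectorized design was chosen instead.)

The agreement checks compare ~600 per-timestep binomial proportions per
variant against the deterministic values at $n = 10^5$. A 3-standard-error
band is expected to be exceeded about 1.6 times per variant by chance alone,
so the test suite asserts the band family-wise: at most 8 exceedances of
$3\,\mathrm{SE} + 3/n$ per variant and none beyond $4.5\,\mathrm{SE} + 3/n$
(the $3/n$ term is a discreteness allowance where $p(1-p)/n$ underestimates
the Poisson tail near proportions of 0 or 1). The mean terminal payoff is
asserted within 3 SE of $U^*(x_{\mathrm{start}}, a_{\mathrm{start}}, 0)$
directly.

A second, non-stochastic oracle guards the solver itself:
`recursive_value_oracle()` recomputes $U^*$ by plain per-state depth-first
recursion over the enumerated outcome tree, sharing no vectorized code with
`solve_policy()`. On a miniature instance ($X = 20$, $A = 3$, $T = 10$) the
two agree to $10^{-10}$ (observed: $10^{-16}$).

## Sensitivity analysis

`oat_sweep()` varies one parameter across a grid, re-solving and
re-propagating at each value with every other parameter at the variant's
defaults. Couplings are re-derived per value through `set_parameter()`
(changing $m_p$ in model 1 moves $m_f(A)$ with it unless the endpoint was
pinned explicitly), and the three constant-form aliases `m_f`, `y_z`,
`omega_z` follow each variant's convention for which endpoint they mean.
`qualifying_range()` reports maximal runs of qualifying grid values as
closed intervals, so split ranges (play viable for very poor *and* very
good alternatives, as happens when sweeping $s_f$ in model 2) are
representable. `default_sweep_grid()` provides 21-point grids over the
conventional spans; reported interval endpoints are grid-resolution
approximations by construction.

## Problem sizes used in the tests

The default grid ($301 \times 101$ states, 200 epochs, three actions, up to
eight branches) solves in roughly two seconds in vectorized R, so the test
suite solves each of the four default variants once (cached across test
files) and propagates them exactly. Monte-Carlo checks use $n = 10^5$
individuals per variant; exhaustive-recursion and property checks run on the
miniature instance above. A full 21-point sweep re-solves the model once per
grid value and is exercised on the miniature instance, plus two full-size
solves for the qualifying-range check.

## Known limitations

* Energy and ability are integers with unit increments; there is no
  interpolation, no body-size state, and no infinite-horizon variant.
* The model describes discretionary ("free-time") behaviour on top of an
  unmodelled subsistence baseline; absolute time budgets should be read in
  that light.
* Near-tie regions mean some time-course outputs (notably in models 3a/3b)
  are decided by floating-point-scale value differences; they are
  deterministic and reproducible for this implementation, but their fine
  structure should not be over-interpreted, and any reimplementation with a
  different summation order will dither them differently.
* The synthetic cohorts emulate the model's own stochasticity, not real
  behavioural data: passing tests demonstrate internal correctness
  (solver–oracle and deterministic–stochastic agreement), not empirical
  adequacy of the play-as-practice hypothesis.
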