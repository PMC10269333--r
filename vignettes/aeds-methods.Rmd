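---
title: "Methods: accelerated enveloping distribution sampling on toy systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerated enveloping distribution sampling on toy systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Sampling chunks are not executed at build time; the outputs quoted in the
# prose were recorded from seeded runs of the released code and are
# reproduced bit-exactly by the same seeds.
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(aedskit)
```

# 1. The model

## 1.1 End states and the toy family

Every system in `aedskit` is a member of one parametric family with a probe
coordinate $x$ (the "water") and an optional ligand coordinate $y$. End
state $i$ at coupling parameter $\lambda$ has the potential

$$
H_i(x, y; \lambda) \;=\;
\underbrace{\tfrac12 k_i (x - x^0_i)^2}_{\text{probe well}}
\;+\; c_i(\lambda)
\;-\; g_i(\lambda)\, e^{-x^2 / 2w^2}
\;+\; \underbrace{\tfrac12 K(\lambda)\, x^2}_{\text{restraint}}
\;+\; \underbrace{\tfrac12 k_L \big(y - \lambda d_L\big)^2 + \lambda\, \Delta E_L}_{\text{ligand}}
$$

with $c_i(\lambda)$ and $g_i(\lambda)$ linear in $\lambda$. The Gaussian term
of depth $g_i$ and width $w$ is the "site attraction" — the analog of the
favorable interactions a water molecule feels in a hydration site. A
**coupled** state has $g_i > 0$; a **dummy** state has $g_i = 0$ and only
feels the restraint, exactly like a non-interacting dummy water that is kept
near the site by a position restraint so that the standard-state correction
stays well defined.

Because every term is a one-dimensional closed form, all equilibrium
properties of any member of the family — partition functions, free-energy
differences, state occupancies, $\langle \partial H/\partial\lambda \rangle$
— are available from adaptive quadrature (`quadrature_free_energy()`,
`toy_occupancy_quadrature()`, `toy_state_free_energy()`). These quadrature
values are the *oracles*: every stochastic estimator in the package is
tested against them to stated tolerances. This is the reason for synthetic
data throughout: a real MD trajectory has no exact answer attached, so it
can only support regression tests, whereas the toy family supports genuine
correctness tests of every estimator.

## 1.2 The reference Hamiltonian

The enveloping reference state over $N$ end states with offsets
$\Delta F_i$ is

$$
E_R(x) \;=\; -RT \,\ln \sum_{i=1}^{N} \exp\!\big(-(H_i(x) - \Delta F_i)/RT\big),
$$

computed with a stable log-sum-exp (`reference_energy()`). $E_R$ lies at or
below $\min_i (H_i - \Delta F_i)$ and within $RT\ln N$ of it; both bounds
are asserted in the tests. The per-frame Boltzmann weights

$$
w_i(x) \;=\; \frac{e^{-(H_i - \Delta F_i)/RT}}{\sum_j e^{-(H_j - \Delta F_j)/RT}}
$$

(`state_weights()`) define the soft state assignment; offsets are
gauge-fixed so that $\min_i \Delta F_i = 0$, since a common shift of all
offsets only shifts $E_R$ by a constant. For studies with several probed
sites, `combinatorial_reference()` builds the $2^n$ coupled/dummy
combination states (capped, because the state count is exponential).

## 1.3 The acceleration (boost)

Offsets equalize the *minima* of the end states but leave the *barriers*
between them. The accelerated variant applies a harmonic boost to $E_R$
between two levels $E_{\min} < E_{\max}$ (`aeds_boost()`,
`accel_params()`):

$$
E_R^*(E_R) =
\begin{cases}
E_R & E_R \le E_{\min}\\[2pt]
E_R - \dfrac{(E_R - E_{\min})^2}{2\,(E_{\max} - E_{\min})} & E_{\min} < E_R < E_{\max}\\[6pt]
\tfrac12 (E_{\min} + E_{\max}) & E_R \ge E_{\max}
\end{cases}
$$

This is $C^1$, monotone, with slope in $[0, 1]$ — properties the test suite
asserts directly, and which matter because the slope multiplies the forces
and the TI integrand. Two consequences shape everything downstream:

* the boosted landscape can never be flattened *below*
  $(E_{\min}+E_{\max})/2$: a barrier much higher than $E_{\max}$ retains a
  residual of roughly half its excess, so acceleration helps kinetics but
  does not abolish rare-event behavior;
* above $E_{\max}$ the landscape is exactly flat **everywhere**, so an
  unconfined system with a boosted reference is non-normalizable. Physical
  systems are confined by their condensed-phase environment; the toy
  systems carry an explicit restraint for the same reason, and fixtures
  used with acceleration always include one.

# 2. Sampling

Trajectories are generated by compiled kernels (`run_sampler()`) in one of
two modes:

* **Metropolis** random-walk Monte Carlo, the default. Exact detailed
  balance with respect to $e^{-(H_S + V_r + E_R^*)/RT}$ (verified on an
  explicit transition-kernel matrix in the tests); the step size is tuned
  to a 30–50 % acceptance *during burn-in only*, so the production chain is
  strictly Markovian with fixed parameters.
* **Overdamped Langevin** (Euler–Maruyama), which exercises the analytic
  force (and hence the boost slope) but carries the usual $O(\Delta t)$
  discretization bias.

All randomness flows through R's RNG, so a `seed` in
`simulation_config()` reproduces a trajectory bit-exactly across runs and
platforms with the same R version. Frames record $x$, $y$, every $H_i$,
$E_R$, $E_R^*$, the weights and the restraint energy; this energy series is
the single interchange object of the package (a tibble with class
`aeds_series`, written/read loss-free by `write_energy_series()` /
`read_energy_series()`).

The acceptance test for the sampler is distributional, not moment-based: a
two-sided Kolmogorov–Smirnov statistic of $10^5$ retained frames against
the quadrature CDF of the boosted, restrained double-well density must not
exceed 0.02.

# 3. Searching the AEDS parameters

`search_run()` implements the adaptive search for offsets and boost levels.
The simulation is processed in blocks; after each block the estimates are
refreshed with a *memory window* that grows linearly from 500 steps at the
start to 500,000 steps at saturation (`memory_length()`), so early — badly
parameterized — history is forgotten quickly while late history accumulates.

* **Visited state** of a frame: $\arg\min_i (H_i - \Delta F_i)$ under the
  *live* offsets, ties to the lowest index (`assign_visited_state()`).
* **Offsets**: per-state free energies from memory-decayed exponential
  averaging of $e^{-(H_i - E_R^*)/RT}$, re-gauged to $\min = 0$
  (`update_offsets()`). On a pure energy-shift pair (identical wells
  displaced in energy by 6 kJ/mol) this recovers the shift to $10^{-9}$.
* **$E_{\max}$**: the maximum $E_R$ observed at visited-state *change*
  frames inside the window — the lowest level the reference actually needs
  to reach to cross.
* **$E_{\min}$**: $\max_i (\bar E_R^{(i)} + s_{E_R}^{(i)})$ over states
  with enough frames, clamped to $\le E_{\max}$ (clamping raises a single
  aggregated warning).
* Before the first crossing is seen, a bootstrap acceleration
  ($E_{\min} = $ mean, $E_{\max} = $ max $+\,RT$) keeps the chain moving.

On the displaced pair with a designed 4 kJ/mol gap, a $4\times10^5$-step
search recovers the gap within 0.5 kJ/mol and the resulting parameters keep
both states above 10 % occupancy in production — both asserted as
acceptance checks.

# 4. Occupancy and one-step perturbation

From a production series, `occupancy_fractions()` reports per-state
fractions either from the mean Boltzmann weights (default; lower variance)
or from the visited-state argmin (coarser, matches how crossing statistics
are counted), with a running-average convergence trail and censored dwell
times (`state_lifetimes()`; the first and last dwell are incomplete and
never counted).

The free energy of *fixing* a state is estimated by one-step (Zwanzig)
perturbation from the reference ensemble:

$$
\Delta F_{R^* \to i} \;=\; -RT \ln \big\langle e^{-(H_i - E_R^*)/RT} \big\rangle_{R^*},
$$

with a block-averaged error (`block_error()`) and a reliability flag: a
state whose weight fraction is below 1 % never overlaps the reference
ensemble well enough for the exponential average to be trusted, so
`osp_free_energy()` marks it unreliable rather than reporting a number that
merely looks precise.

# 5. TI–AEDS

## 5.1 The $\lambda$-path

For the alchemical morph the total Hamiltonian at window $\lambda$ is
$H(\lambda) = H_S(\lambda) + V_r(\lambda) + E_R^*(\lambda)$, where the
offsets inside $E_R$ are interpolated linearly between the endpoint
searches: `build_offset_schedule()` stores, per state, an intercept
$b_i = \Delta F_i(0)$ and slope $S_i = \Delta F_i(1) - \Delta F_i(0)$. The
TI integrand is then

$$
\frac{\partial H}{\partial \lambda}
= \frac{\partial H_S}{\partial \lambda}
+ \frac{\partial V_r}{\partial \lambda}
+ E_R^{*\prime}(E_R)\sum_i w_i \Big(\frac{\partial H_i}{\partial \lambda} - S_i\Big),
$$

i.e. the boost slope times the weight-averaged state derivatives, each
corrected by its offset slope (`dhdl_frame()`). The tests verify this
expression against central finite differences of the *total*
$\lambda$-Hamiltonian, so the schedule and boost terms cannot silently drop
out. `ti_integrate()` applies the trapezoid rule over the windows;
`run_ti_aeds()` drives the per-window simulations and reports the
forward/backward hysteresis when both directions are run. On a pure
energy-shift morph the estimate is exact to $10^{-9}$ with zero hysteresis;
on a displaced-harmonic morph with exact answer 7.5 kJ/mol, a
41-window × $10^5$-step run lands within 0.05 kJ/mol.

## 5.2 Reweighted fixed-state paths

From the *same* reference-path trajectories, the fixed-state profiles are
recovered by exponential reweighting of the fixed-state integrand with
weights $e^{-(H_i - E_R^*)/RT}$ per window (`reweighted_profile()`), with a
Kish effective-sample-size diagnostic; windows whose weights are degenerate
are flagged rather than averaged. This is what makes one reference
simulation yield three edges of the thermodynamic cycle.

## 5.3 Endpoint legs

`endpoint_legs()` evaluates the four one-step-perturbation legs
$R^*(\lambda{=}0) \to$ coupled/dummy and $R^*(\lambda{=}1) \to$
coupled/dummy, closing the cycle at the endpoints.

# 6. Corrections and cycle bookkeeping

* **Restraint release**: for an isotropic harmonic restraint of force
  constant $K$ on a dummy particle,
  $\Delta G = -RT\ln\big[(2\pi RT/K)^{3/2} / V_{\text{site}}\big]$
  (`restraint_release_correction()`; defaults $K = 1500$ kJ mol$^{-1}$
  nm$^{-2}$, $T = 300$ K, $V_{\text{site}} = 3.0777\times10^{-2}$ nm$^3$,
  the volume of one water in bulk). The closed form is validated against a
  radial quadrature $\int_0^\infty 4\pi r^2 e^{-Kr^2/2RT}\,dr$ to $10^{-6}$
  relative.
* **Bulk transfer**: `bulk_transfer_term()` supplies the per-water
  excess-chemical-potential term for moving a water between the site and
  bulk when assembling absolute numbers
  (`assemble_relative_binding()` itemizes every contribution).
* **Cycles**: the six states (ligand A/B × water coupled, reference,
  dummy) and seven measured edges form a graph; `cycle_report()` /
  `cycle_closure()` compute the three independent closures from a BFS
  spanning tree plus chords, combine quadrature errors along each cycle,
  and can exclude unreliable edges. A synthetic edge set derived from an
  exact potential closes at $<10^{-12}$; the simulated pocket study closes
  at 0.02–0.08 kJ/mol against a 3 kJ/mol quality bound.

`run_cycle_study()` chains all of the above — endpoint searches, schedules,
TI–AEDS, reweighted paths, endpoint legs, closures — from a single seed.

# 7. Parameter and problem-size choices

The problem sizes are the package's own choices, set to the smallest
budgets at which each estimator's statistical error is comfortably below
its test tolerance on one CPU:

| Quantity | Choice | Rationale |
| --- | --- | --- |
| Temperature | 300 K ($RT = 2.4944$ kJ/mol) | standard condensed-phase conditions |
| Pocket fixture | $g_A = 15$, $g_B = 2$, $w = 0.12$, $K = 200$; ligand $(400, 0.3, 25)$ | site attractions of a few–several $RT$, the regime where occupancy actually switches between ligands |
| Search budget | $2\times10^5$–$4\times10^5$ steps | offsets converge well before the window saturates |
| TI protocol | 41 windows × $2\times10^4$ steps, 2 000 equilibration | trapezoid bias and per-window noise both $\ll$ closure bound |
| Sampler acceptance | KS $\le 0.02$ at $10^6$ steps | discriminates a correct chain from subtle boost/restraint bugs |
| Memory window | 500 → 500 000 steps, linear | fast forgetting early, stability late |
| Reliability threshold | 1 % weight fraction | below this, the Zwanzig exponential average is dominated by unseen tails |

Defaults are the study conditions: the seeded runs in the tests and in
`scripts/acceptance.R` use these values as-is.

# 8. Limitations

* **Toy scale.** One probe coordinate and one ligand coordinate stand in
  for a solvated protein. The estimators, bookkeeping and failure modes
  (trapped states, weight degeneracy, unreliable legs) transfer; absolute
  numbers and time scales do not.
* **Metropolis is not MD.** Dwell "lifetimes" are in units of the chain's
  own relaxation, not physical picoseconds; only their relative ordering is
  meaningful.
* **Langevin bias.** The Euler–Maruyama integrator has $O(\Delta t)$
  systematic error; the distributional acceptance test therefore targets
  the Metropolis mode.
* **Boost flattening is global.** Above $E_{\max}$ the boosted surface is
  flat everywhere, so acceleration is only meaningful for confined systems;
  the package's fixtures always carry a restraint, and users building their
  own systems must do the same.
* **Residual barriers.** The boost can at most halve the part of a barrier
  above $E_{\max}$; systems with barriers of many tens of $RT$ remain
  kinetically limited even when accelerated.
* **One-step perturbation needs overlap.** The reliability flag is a
  necessary, not sufficient, condition; strongly non-overlapping target
  states require staged paths (which is what TI–AEDS provides).
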