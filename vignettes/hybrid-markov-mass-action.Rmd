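---
title: "Hybrid Markov-mass-action modelling of calcium-triggered vesicular release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Markov-mass-action modelling of calcium-triggered vesicular release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vesicular release at a presynaptic terminal is triggered when a handful of
calcium ions (threshold `T = 5` here) accumulate on a tiny molecular sensor
— a ribbon of height $\varepsilon = 1\,$nm at the base of a 20-nm vesicle.
The ions arrive by two routes with wildly different time scales: directly
from voltage-gated channels during the few milliseconds of an action
potential, and, much later, by diffusion of ions that were lost to the
$\sim 1\,\mu\text{m}^3$ bulk of the terminal, where they also bind mobile
buffers and eventually escape through the neck.  A brute-force spatial
simulation of this system is wasteful: almost all of the computational
effort would go into the bulk, where nothing decision-relevant happens.

The package couples the two regimes: the bulk is described by deterministic
mass-action equations for the free (`N_f`) and buffer-bound (`N_b`) ion
counts, while each vesicle's sensor carries a pure-birth Markov chain for
the probability $\Pr^i\{k,t\}$ that $k$ ions are bound.  Everything is
validated against an exact Gillespie simulation of the same reaction
network.

## Calcium influx

The action-potential-evoked current is produced by a reduced
excitable-membrane model (`simulate_hh()`):

$$C\dot V = I_{app}(t) - g_{Na}\,p_\infty^3(V)\,(0.89-1.1n)(V-E_{Na})
 - g_K n^4 (V-E_K) - g_L(V-E_L) - I_{Ca},$$

with the classical voltage-dependent rate functions for the potassium gate
$n$ and the (instantaneous) sodium activation $p_\infty$; sodium
inactivation is slaved to $n$ through the standard reduction
$h_{Na} = 0.89 - 1.1\,n$.  The resting state of this system is the default
initial condition, so an unstimulated membrane stays put (this is checked
by a test).  The calcium current is a high-threshold current

$$I_{Ca} = g_{Ca}\, m^3 h \,(V - E_{Ca}),\qquad
\dot m = \frac{m_\infty(V)-m}{\tau_m},\quad
\dot h = \frac{h_\infty(V)-h}{\tau_h},$$

with Boltzmann steady states: $m$ activates at $\theta_m = +37$ mV with a
1-mV slope — essentially only the spike tip opens the channel — and $h$
closes slowly ($\tau_h = 10$ ms) above $-41$ mV.  The cubic activation
gate gives the current its sharply peaked shape: the decay rate of $m^3$
is three times that of $m$, which is what produces a transient whose
integral-to-peak ratio is $\sim 0.7$ ms inside a 1-percent width of
$\sim 2.75$ ms.  With the default parameters the simulated transient
reproduces the reference signature of this synapse — peak 36.2 on the
display scale, 2.75 ms duration, 80 ions per channel — to within 2 percent
(the acceptance tests compute all three).

**Units.**  Conductances are stated in mS/cm² and potentials in mV, so the
current numeric is on a µA scale; with the single-terminal calcium
conductance of $14.5\times10^{-9}$ the physical single-channel current is
of femtoampere magnitude.  The current column is labelled `I_Ca_nA`
following the display convention in which its peak reads 36.2; the charge
conversion `Q_fC = 1e-3 * integral(|I| dt)` is the one consistent
interpretation, under which the transient carries 0.026 fC = 81 calcium
ions per channel (one display-nA equals one femtoampere).  The influx rate
used downstream is $J(t) = |I_{Ca}|/(2e)$ in ions/ms (`influx_profile()`),
interpolated monotonically and clamped to zero outside the simulated
window.

The stimulus is a rectangular additive forcing of amplitude 50 (mV/ms) for
1 ms in the voltage equation; amplitude, onset and duration are exposed in
`stimulus_protocol()`.  The transient duration is operationalized as the
time during which $|I_{Ca}|$ exceeds 1 percent of its peak (threshold
exposed in `transient_width()`).

## Geometry and transport rates

Eight vesicles sit on a 4 x 2 square lattice of spacing $2H = 140$ nm on
the active zone; the terminal head is a ball of radius 0.6 µm (volume
0.905 µm³).  The printed one-digit "1 µm³" found in standard parameter
tables for this system is the rounding of that ball volume; the package
uses the exact ball volume because it, and only it, reproduces all the
tabulated mean times below simultaneously.  All rates are Poissonian
because every elementary event is a narrow-escape event — a Brownian
particle finding a target much smaller than the domain:

* buffer binding, both species mobile:
  $\tau_B = |\Omega| / (4\pi (D + D_B) r_B) = 1.80$ s, forward rate per
  site $k_0 = 1/\tau_B$;
* arrival at one ribbon (capture capacitance $\varepsilon$):
  $\tau_T = |\Omega| / (4\pi D \varepsilon) = 3.60$ s, $k_T = 1/\tau_T$;
* escape through the neck (radius 0.1 µm, length 0.15 µm), dominated by
  the flux through the neck cross-section:
  $\tau_{es} = |\Omega| l / (r_{neck}^2 D) + l^2/(2D) = 0.68$ s.

`rate_set(use_printed_rates = TRUE)` substitutes the conventional rounded
values $k_0 = 0.6$, $k_T = 0.3$, $k_{es} = 1.5$ s⁻¹ used by the reference
release simulations; the buffer-sweep experiments default to these so that
the release-time structure is computed under the tabulated conditions,
while the rate module itself reports the formula-exact values.  The buffer
unbinding rate is $k_{-1} = 0.5$ s⁻¹ by default (mean bound time 2 s); a
faster published alternative (2 s⁻¹, mean 500 ms) can be set through
`transport_params(k_minus_1 = )`.

## Splitting between targets and bulk

An ion entering at membrane position $x$ either reaches a ribbon first
(probability $p_s(x)$) or is lost to the bulk.  The package evaluates
$p_s$ with the interpolation formula

$$p_s(\rho) = \frac{1}{1 + \rho^2 / (A\,\varepsilon^{3/2}\sqrt{r})},
\qquad A = 9.8,$$

where $\rho$ is the distance to the nearest vesicle centre.  The
$\varepsilon^{3/2}\sqrt{r}$ scale is an empirical calibration against
Brownian-dynamics simulations of the lattice-cell geometry (sphere on a
reflecting plane, absorbing ribbon below $\varepsilon$, absorbing plane at
$z = 2r$ marking entry into the bulk, reflecting lateral walls): across
$\rho \in [0.015, 0.07]\ \mu$m the formula tracks the simulated splitting
to within two Monte-Carlo standard errors at $10^4$ trajectories.  Known
limitation: for sources closer than $\sim 3\varepsilon$-equivalent
($\rho \lesssim 0.012\ \mu$m, about 4 percent of a uniformly placed
channel population) the formula underestimates the simulated value by up
to 0.05 absolute; since such channels sit almost on top of a vesicle and
release there is nearly saturated anyway, the effect on release statistics
is small.

Conditional on reaching a ribbon, the allocation $q(x, i)$ among the four
nearest targets (anything farther is truncated and the remainder
renormalized) is estimated by `estimate_q()`: Brownian trajectories
launched from a polar grid of blocks covering the fundamental sub-triangle
(octant) of one lattice square, 200 runs per block by default, extended to
the full square by the 8-fold dihedral symmetry and transferred to other
squares by nearest-target rank.  The Euler-Maruyama step is adapted to the
distance from the nearest surface but capped at $\varepsilon/5$ next to a
sphere so the ribbon cannot be stepped over; trajectories that exhaust the
step budget are counted and more than 1 percent of them aborts the
estimate (in practice none are censored).  Far blocks that record no
ribbon hit inherit the allocation of the preceding radial block — their
direct flux is negligible.  For edge vesicles of the finite lattice the
rank-based transfer is an approximation (their neighbourhoods are not
symmetric); the bulk of the direct flux goes to near targets where the
approximation is good.

## The hybrid system

With direct-flux weights $w_i = \sum_x p_s(x) q(x, i)$ over the channels,
each target's arrival rate is $\lambda_i(t) = J(t) w_i + k_T N_f(t)$, and

$$\dot{\Pr}^i\{0\} = -\lambda_i \Pr^i\{0\},\qquad
\dot{\Pr}^i\{k\} = \lambda_i(\Pr^i\{k{-}1\} - \Pr^i\{k\}),\qquad
\dot{\Pr}^i\{T\} = \lambda_i \Pr^i\{T{-}1\},$$

an absorbing chain (bound ions never unbind from the sensor).  The bulk
obeys

$$\dot N_f = k_{-1} N_b - k_0 N_f (S_{tot} - N_b)
 + J(t)\Big(\textstyle\sum_x (1 - p_s(x)) + \sum_i w_i \Pr^i\{T\}\Big)
 - \big(k_{es} + k_T \textstyle\sum_i (1 - \Pr^i\{T\})\big) N_f
 + T \textstyle\sum_i \lambda_i \Pr^i\{T{-}1\},$$

$$\dot N_b = k_0 N_f (S_{tot} - N_b) - k_{-1} N_b.$$

Reading: reversible buffering; the bulk share of the influx, including the
flux aimed at targets that have already released (those ions physically
enter the terminal and join the bulk — the matching rule is applied in the
stochastic simulator, and omitting it on either side produces a visible
drift between the two models); escape and capture by still-free targets,
the latter weighted by each target's probability of being free (a
`free_target_sum = FALSE` switch reproduces the simpler fixed-$N_T$
variant for sensitivity checks); and the re-injection jump of $T$ ions per
activation, evaluated analytically as $T\sum_i \lambda_i \Pr^i\{T-1\}$,
never by numerical differentiation.  After activation a target is retired
for good — no vesicle replenishment.

`solve_hybrid()` integrates the coupled system with `lsoda` (rtol $10^{-8}$,
atol $10^{-10}$) on an output grid of 0.1 ms up to 20 ms and 1 ms beyond —
the influx acts on millisecond scales, the bulk on 0.3–2 s⁻¹ scales, so
the integrator must be stiffness-aware.  $J(t)$ is interpolated
monotone-cubically from the influx table rather than re-solving the
membrane model inside the right-hand side.  Because the chain is pure
birth with a level-independent rate, the occupancy has a closed cascade
solution — a truncated Poisson in the cumulative intensity
$\Lambda_i(t)$ — which `cascade_probabilities()` evaluates from the exact
cumulative influx; agreement with the coupled ODE solution (checked in the
tests) validates the integration.  The release density is
$f_i = \lambda_i \Pr^i\{T-1\} = \mathrm{d}\Pr^i\{T\}/\mathrm{d}t$; the
aggregate density sums targets and is normalized by the expected number of
releases.  `mean_release_time()` integrates $t f_i$ and flags targets
whose cumulative release probability has not reached 0.999 by the end of
the window, reporting the conditional mean instead.

`monte_carlo_release()` averages over uniform channel placements (150 by
default); only channel positions are resampled — buffers enter the model
through a well-mixed rate, so there is nothing else to resample.

## Stochastic validation

`ssa_release()` runs the exact jump process: buffer binding at
$k_0 N_f (S_{tot} - N_b)$, release at $k_{-1} N_b$, escape at
$k_{es} N_f$, binding to each free target at $k_T N_f$ (the first-binding
rate for $N_f$ independent particles), all with integer bookkeeping that
must balance exactly at every event (tested).  The time-inhomogeneous
influx is handled by pre-sampling: each channel's ion count is Poisson
with mean $\int J\,dt \approx 81$ and the arrival times invert the
cumulative intensity — exact for a tabulated rate and simpler than
thinning inside the loop.  Each injected ion is routed instantly to target
$i$ with probability $p_s q_i$ or to the bulk, matching the hybrid flux
term; ions aimed at a retired target join the bulk.

For hybrid-vs-stochastic comparisons the run count is a multiple of the
number of placements and the placements are cycled, so both families
average over exactly the same placement ensemble.  The comparison
(`compare_distributions()`) uses the Kolmogorov-Smirnov distance between
the conditional release-time CDFs; the hybrid CDF is taken from the
absorbing-state occupancy itself (not from quadrature of the density,
whose error on the near-vertical early rise would dominate the statistic).
Because release times within a run are correlated, the conventional
critical value is evaluated at the ensemble size $10^4$ rather than at the
(larger) pooled sample count.

The residual distance (0.007–0.013 under the study conditions) is partly
sampling noise and partly a genuine hybrid limitation: the mean-field
$N_f$ slightly underestimates rare bulk-driven activations in deeply
sub-threshold configurations (Jensen's inequality — the activation
probability is convex in the cumulative intensity), visible as a
percent-level deficit in the far tail of heavily buffered runs.

## Experiment driver and summary criteria

`run_experiment()` wires the pipeline end to end for a buffer sweep
(default 0, 100, 400 sites): influx, rates, allocation table, hybrid
Monte-Carlo and matched Gillespie ensembles per sweep point, comparison
metrics, and CSV/JSON outputs stamped with an MD5 hash of the
configuration.  All stage seeds derive deterministically from the master
seed; rerunning a configuration reproduces the summary byte for byte.

Mode structure is quantified with a fixed, recorded criterion: Gaussian
kernel smoothing with a 2-ms bandwidth on a 0.5-ms grid over 0–500 ms,
modes are local maxima with topographic prominence of at least 5 percent
of the global maximum, and each mode's mass is the integral over its
basin.  Histograms use 2-ms bins on 0–300 ms, and "late" mass is mass in
modes beyond 20 ms within that window.  Under the default conditions the
zero-buffer density is bimodal (first mode $\sim$2 ms, late mode
$\sim$57 ms); 100 buffer sites are saturated by the $\sim$240 entering
ions, which delays and flattens the late mode; 400 sites remove it
entirely, leaving only the direct-flux mode and rare releases in the tail.

## Problem sizes and reproducibility

The test-suite and acceptance computations use: 4001-point influx traces;
allocation tables of 10 radial x 5 angular blocks at 200 runs per block;
150 channel placements for placement averages; $10^4$ stochastic runs
(19 350 for the 400-buffer comparison, so that at least $10^4$ release
times are pooled); 1-second solution windows.  These sizes were chosen so
that Monte-Carlo error sits well below the effect sizes being checked
while the whole suite runs in a few minutes on one core.

## Known limitations

* The bulk is well mixed by assumption: no spatial calcium gradients or
  microdomain coupling beyond the splitting step at entry.
* Mean-field `N_f` underestimates rare-event activation in deeply
  sub-threshold (heavily buffered) regimes by a few percent of the tail
  mass.
* The splitting formula loses accuracy within ~12 nm of a vesicle centre
  (see above).
* Rank-based transfer of the allocation table to edge vesicles ignores
  their asymmetric neighbourhoods.
* No vesicle replenishment, facilitation, or multi-spike protocols: one
  action potential, one pool of eight vesicles.
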