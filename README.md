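# presynaptic

Hybrid Markov–mass-action modelling of calcium-triggered vesicular release
at a presynaptic terminal.

## The problem

Neurotransmitter release is gated by a rare molecular event: a handful of
calcium ions (threshold *T* = 5) must accumulate on a nanometre-scale
ribbon sensor underneath a vesicle.  Ions arrive either directly from
voltage-gated channels during the ~3 ms of an action potential, or much
later from the bulk of the terminal, where they meanwhile bind mobile
buffers and leak out through the neck.  Simulating every ion spatially is
wasteful; treating everything with mass action erases the rare-event
statistics that actually decide release.

This package is for modellers who want both regimes at once:

* a **deterministic bulk** — mass-action ODEs for the free and
  buffer-bound ion counts, with Poissonian narrow-escape rates
  (`rate_set()`), and
* **stochastic sensors** — one pure-birth Markov chain per vesicle for the
  probability that *k* ions are bound, absorbing at *k = T*,

coupled through the per-target arrival rate

```
lambda_i(t) = J(t) * sum_x p_s(x) q(x, i)  +  k_T * N_f(t)
```

where `J(t)` is the per-channel influx from a simplified Hodgkin–Huxley
model (`simulate_hh()`), `p_s(x)` the probability that an ion entering at
channel position `x` reaches a ribbon before the bulk
(`splitting_probability()`), `q(x, i)` its Brownian-estimated allocation
among the four nearest vesicles (`estimate_q()`), and `k_T N_f` the
Poissonian return flux from the bulk.  The release-time density of target
*i* is `f_i(t) = lambda_i(t) Pr_i{T-1, t}`.  An exact Gillespie simulator
of the same network (`ssa_release()`) validates the hybrid model.

The headline prediction: with no buffers the release-time distribution is
**bimodal** — a fast mode driven by the direct channel flux and a late
mode near 60 ms from ions returning out of the bulk — and adding buffer
sites selectively abolishes the late mode.

## Worked example

```r
library(presynaptic)

trace <- simulate_hh()              # action-potential calcium current
trace
#> Calcium current trace: 4001 points over 40 ms
#>   peak |I_Ca| 36.19 nA, 1%-width 2.703 ms, total charge 0.026 fC

geom <- synapse_geometry()          # 8-vesicle lattice, 0.6-um head
rate_set(geom, transport_params())  # narrow-escape transport rates
#> Transport rates (formula reciprocals):
#>   buffer binding  k_0  = 0.5556 /s  (tau_B  = 1.8 s, per site)
#>   target arrival  k_T  = 0.2778 /s  (tau_T  = 3.6 s, per ribbon)
#>   neck escape     k_es = 1.472 /s  (tau_es = 0.6791 s)
#>   buffer release  k_-1 = 0.5 /s

qt <- estimate_q(geom, seed = 11)   # Brownian target-allocation table
pars <- transport_params(S_tot = 0) # no buffers
rts <- rate_set(geom, pars, use_printed_rates = TRUE)
mc <- monte_carlo_release(geom, pars, rts, influx_profile(trace), qt,
                          n_realizations = 150, seed = 2)
detect_modes(mc$t, mc$density)
#>   location      height  prominence       mass
#> 1        2 0.008847487 0.007139387 0.04703949
#> 2       57 0.011374247 0.011374247 0.94378219
```

Reading the output: the current transient peaks at 36.2 on the nA display
scale, lasts 2.70 ms above 1 % of peak, and delivers 0.026 fC ≈ 81
calcium ions per channel.  Averaged over 150 uniform channel placements
the zero-buffer release-time density has exactly two modes: a direct-flux
mode at ~2 ms holding ~5 % of the release mass, and the late,
bulk-driven mode at ~57 ms holding the rest.  Re-running with
`transport_params(S_tot = 400)` removes the late mode.

The full buffer sweep with matched Gillespie validation is one call:

```r
res <- run_experiment(experiment_config(seed = 1), outdir = "results")
res   # per sweep point: mode locations, masses, KS distance vs the SSA
```

or from the shell,
`Rscript inst/scripts/run_experiment.R --config sweep.yaml --out results/`.

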