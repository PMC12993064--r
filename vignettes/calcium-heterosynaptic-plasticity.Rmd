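---
title: "Modelling calcium-mediated heterosynaptic plasticity with calplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium-mediated heterosynaptic plasticity with calplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`calplast` models a single unbranched dendrite as a cylinder of radius
$r_d$ divided into segments of length $dx$, with free calcium
$C_d(x,t)$ (µM) diffusing along it, leaking with time constant
$\tau_{decay}$, and exchanging with spine heads through first-order
fluxes whose rates are inverse mean first passage times across the spine
neck:

$$k_d = \frac{4 D a_s}{V_d}, \qquad
  k_s = \frac{1}{\tau'}, \quad
  \tau' = \frac{V_s}{4 D a_s} + \frac{l_n^2}{2D}.$$

A presynaptic spike injects an exponentially decaying electrical current
$I_0 e^{-t/\tau_d}$ into the synapse; a fixed fraction $\gamma$ of it is
carried by Ca²⁺ ions, giving the spine influx
$J_{syn} = \gamma I / (z F V_s)$. The synaptic weight of each spine
follows the calcium hypothesis: calcium above a low threshold
$\theta_d$ drives depression at rate $\gamma_d$, calcium above the higher
threshold $\theta_p$ additionally drives potentiation at rate
$\gamma_p$, so the weight relaxes towards
$\gamma_p/(\gamma_p+\gamma_d)$ whenever $C_s > \theta_p$ and decays
exponentially in the band $(\theta_d, \theta_p]$.

Deliberate simplifications: calcium entry is through a single
representative channel (no NMDAR/VDCC kinetics, no voltage dependence);
buffering and extrusion are lumped into the single $\tau_{decay}$; there
are no calcium stores, no back-propagating action potentials, no
dendritic spikes, and no branching. These keep every heterosynaptic
effect attributable to one mechanism — diffusion of free calcium through
the shaft.

## Physical parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| `D` | Ca²⁺ diffusion coefficient | 220 | µm²/s |
| `tau_decay` | calcium leak time constant | 0.08 | s |
| `l_n`, `a_s` | spine neck length, radius | 0.5, 0.1 | µm |
| `r_s` | spine head radius | 0.34 | µm |
| `r_d` | dendrite radius | 1 | µm |
| `gamma` | current-to-calcium fraction | 0.11 | – |
| `I0`, `tau_d` | synaptic current amplitude, decay | 0.1, 10⁻³ | pA, s |

All are literature-derived physical constants. Internally everything is
in seconds, micrometres and micromolar; the single unit conversion
(pA and µm³ to µM/s, a factor 10⁹ on $\gamma I/(zFV_s)$) is isolated in
`current_to_flux_coef()` and covered by a test against independent
SI-unit arithmetic.

## Flux bookkeeping across the spine neck

The model equations apply the neck fluxes $k_d C_d$ and $k_s C_s$ with
identical magnitude, in concentration units, to both compartments. Since
$V_d \neq V_s$, the moles removed from one compartment then differ from
the moles added to the other: the printed exchange amplifies
spine-to-dendrite transfer by $V_d/V_s \approx 9.5$ at $dx=0.5$ µm. This
is intentional in the default `flux_mode = "paper"`: it is the regime in
which heterosynaptic calcium at 1 µm distance reaches the $10^{-3}$ µM
threshold scale that the two-spine presets use. An optional
`flux_mode = "volume-corrected"` scales the dendrite-side terms by
$V_s/V_d$, which makes the exchange strictly mole-conserving (verified by
a conservation test) at the cost of roughly tenfold weaker heterosynaptic
coupling.

## Numerics

* **Scheme.** Backward Euler on the coupled field: diffusion, leak and
  both neck fluxes are implicit; $J_{syn}$ is evaluated at the step start
  (semi-implicit), keeping the linear system constant over a run. The
  spine equations are eliminated algebraically into the dendritic
  tridiagonal system (a Schur complement), so each step is one Thomas
  solve of size `n_segments`, with elimination factors precomputed once.
  The implicit matrix is an M-matrix, so concentrations can never become
  negative, and the no-flux Laplacian conserves total calcium exactly (to
  rounding) when the leak is off.
* **Boundaries.** No-flux (reflecting) at both cable ends: mass
  conserving, and the natural choice for an isolated branch segment.
* **Resolution.** Defaults `dx = 0.5` µm and `dt = 0.05` ms resolve the
  1 µm inter-spine distances and the 1 ms synaptic transient; the solver
  refuses `dt > tau_d/5`. A convergence test halves `dt` and requires
  final weights to agree to $10^{-3}$ relative.
* **Weights.** Explicit Euler with the same `dt`, then a clamp to
  $[0,1]$ that is a no-op whenever $dt(\gamma_p+\gamma_d) < 1$ (enforced
  as a precondition). The Heaviside is strict at equality,
  $\Theta(0)=0$ — a measure-zero convention fixed once.
* **Synaptic current.** The per-spine current state is advanced by the
  exact exponential recursion, with each spike's contribution added with
  its exact phase, so the drive has no accumulation error.
* **Exact mirror symmetry.** Floating-point summation is not invariant
  under reversing a cable, so a naive solver reflects results only to
  rounding error. `simulate_calcium()` therefore canonicalizes the cable
  orientation (if the mirrored spine layout sorts lexicographically
  before the original, the problem is flipped, integrated, and flipped
  back). Simulating a mirrored arrangement with a mirrored protocol then
  returns the bitwise mirror of the original result, by construction.

## The arrangement generator

`generate_arrangement()` emulates the multi-spine study conditions: an
80 µm dendrite with 16 spines; a 7 µm cluster section placed uniformly at
random (subject to flank feasibility) containing exactly 7 stimulated
(`Stim`) and 3 unstimulated (`Un_in`) spines — about 1.4 spines/µm — and
6 outer spines (`Un_out`) split at least 3 per flank. Initial weights are
drawn uniformly from $[0.3, 0.7]$: the distribution is unreported in the
source experiments, and a symmetric band around ½ leaves headroom for
both LTP and LTD; it stands in for the spread of initial spine sizes.
Whether `Stim` spines are contiguous inside the cluster is configurable
(`stim_contiguous`), defaulting to a random subset. The generator is
deterministic given its seed and restores the caller's RNG state.

What it does *not* emulate: realistic spine-density gradients, spine-size
correlations with position, branching, or any experiment-specific
uncaging geometry. Passing tests on these synthetic arrangements show the
model's internal consistency under the stated geometry, not agreement
with any particular reconstructed dendrite.

## Plasticity presets and calibration

Only the two-spine thresholds are printed quantities
(θ_d = 2·10⁻³ µM, θ_p = 4·10⁻³ µM, preset `"fig2"`). Every rate constant,
the `"fig3"` thresholds, the burst shape and the numeric low/medium/high
rates are **calibrated**: they are not experimentally constrained, and
were chosen once so that the simulated sign patterns reproduce the
qualitative experimental regimes. They live in
`inst/extdata/presets.yaml` and `frequency_presets()`.

* **`fig2`** (θ_d = 2e-3, θ_p = 4e-3, γ_p = 480/s, γ_d = 24.8/s). With
  these low thresholds, a stimulated spine's own transient, its decaying
  tail and the neighbour's diffusive contribution all cross the
  thresholds, and each presentation ends with a stretch in the depression
  band. The rates are fast enough that the weight substantially relaxes
  within each supra-threshold window, which makes the *order* of the
  potentiation/depression windows matter: the spine whose
  supra-$\theta_p$ window closes earlier spends longer in the trailing
  depression band and ends lower. That is what reverses the outcome of
  the +15 ms pairing (first spine depressed, second potentiated) while a
  single input still yields competition and a 40 Hz spike pair yields
  cooperation. The resulting net changes in the pairing regime are small
  by construction — the low thresholds are exactly the regime that makes
  subtle timing effects visible.
* **`fig3`** (θ_d = 0.03, θ_p = 0.2 µM, γ_p = 28/s, γ_d = 0.4/s). Here
  θ_p sits just above the isolated single-spike spine peak (~0.19 µM).
  At 0.5 Hz the dendritic field resets between pulses, spikes never cross
  θ_p, and stimulated spines only depress; at 40 Hz the accumulated
  dendritic baseline lifts the spike peaks across θ_p (homosynaptic LTP)
  while unstimulated in-cluster spines sit in the depression band; the
  250 Hz train drives a standing cluster plateau above θ_p that
  potentiates `Stim` and `Un_in` alike while its spatial skirt puts the
  nearer `Un_out` spines into the depression band. Reducing `D` to
  1 µm²/s confines calcium to the stimulated spines (which then
  potentiate at every frequency) and abolishes all heterosynaptic change.
* **`fig4-grid`** (fig2 thresholds, γ_p = 0.1/s, γ_d = 2.5/s), the
  default for `timing_sweep()`: a slow, depression-dominated regime in
  which the heterosynaptic influence measured by
  `heterosynaptic_magnitude()` — the largest deviation of the
  timing-window curve from the isolated-spine outcome — decreases
  monotonically over 1, 2, 3 µm spacings. Sweeping γ_p and γ_d around
  this preset is how the timing-window taxonomy (P, D, DP, DPD, …)
  is explored; `classify_window()` applies a ±0.01 dead band,
  run-length-compresses the signs and drops no-change runs.

Frequency presets: low = 0.5 Hz × 15 pulses, medium = 40 Hz × 15,
high = 250 Hz × 100, spanning the three regimes of dendritic summation
relative to $\tau_{decay} = 80$ ms (none / partial / strong). Protocol
presentations default to 5 repetitions 1 s apart, so calcium fully resets
between presentations; the interval is configurable.

## Multi-spine statistics

`multi_spine_experiment()` derives per-configuration seeds from the
master seed by a counter, so extending the number of configurations never
changes earlier ones. The matching error counts one instance per
(configuration × frequency × group): the sign of that configuration's
group-mean weight change, with a ±0.01 "no significant change" dead band,
is compared against the expected pattern
(low: −,0,0; medium: +,−,0; high: +,+,−), and the error is the mismatch
fraction in $[0,1]$. Counting per configuration (rather than per group
mean) is one consistent reading of "instances"; it is exposed through the
returned per-configuration errors. The packaged checks run 5
configurations per cell and the diffusion grid {1, 220, 440} µm²/s; the
full 10-value grid with 20 configurations is a single
`diffusion_sweep()` call away.

## The voltage cable and sequence selectivity

The source model specifies only the somatic integrator
($u_{rest} = -70$ mV, $\tau = 22$ ms, $R_{soma}/R_{s,axial} = 5$); the
dendritic voltage dynamics are a package design: leaky compartments with
membrane time constant equal to the somatic $\tau$, nearest-neighbour
axial coupling parameterized by a steady-state space constant (default
50 µm), and synaptic electrical current injected at spine segments
*scaled by the spine's weight* — weights must influence the somatic
response for learning to be read out, whereas calcium influx remains
weight-independent as modelled. The soma reads the terminal compartment
one-way; the voltage gain `c_syn` (default 2.5·10⁷ mV/s per pA) and the
spike-threshold line (−56.9 mV) are tuned only so that the passive
response stays subthreshold and learned responses are separable; there
are no spike dynamics.

`sequence_experiment()` places two spines 1 µm apart about 5 µm from the
soma (positions snap to segment centres, so 5.25 and 6.25 µm). On a
passive cable the inward order (distal spine first, proximal last) always
yields the larger somatic peak, because the later, less-attenuated input
rides on the earlier one's tail. During learning (5 presentations,
plasticity on, `fig2` preset) the pairing rule potentiates the
later-activated spine and depresses the earlier one, shifting synaptic
strength toward the spine that fires last in the trained order; at test
time the stronger synapse arriving last collects the other's residual,
so the learned order wins for either direction. The default inter-input
interval is 40 ms: near the cable end the reflected calcium field biases
depression toward the proximal spine, and at short intervals that bias
can mask the timing asymmetry; by 20–40 ms the timing effect dominates
for both orders, with the widest margin around 40 ms. The reported ratio
is peak depolarization (peak − rest) of the learned order over the
non-learned order, defined as 1 when both are zero.

## Known limitations

* The default flux bookkeeping is not mole-conserving across the neck
  (see above); cross-compartment amounts are interpretable as coupling
  strengths rather than ion counts.
* In `"paper"` mode the dendritic *local* field scales with `dx` (the
  deposit is a concentration source in one segment), while spine-to-spine
  coupling is `dx`-invariant; analyses should compare runs at a fixed
  `dx`.
* The `fig2` pairing reversal and the `fig3` medium-frequency regime are
  deliberately near-threshold phenomena; their signs are stable under the
  packaged defaults (including a halved `dt`), but magnitudes there are
  small and not calibrated to any measured effect size.
* Weight changes saturate at the rule's fixed points; no late-phase
  consolidation, tagging, or weight-dependent calcium feedback is
  modelled.
* Voltage and calcium are integrated on the same grid with one-way
  coupling (calcium → weights → voltage); electrical effects on calcium
  influx are outside the model.
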