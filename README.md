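# calplast

Calcium diffusion and threshold-based heterosynaptic plasticity in
dendrites.

`calplast` is a biophysical simulator for neuroscientists studying how
synaptic plasticity at one dendritic spine spills over to its neighbours.
It implements a reaction–diffusion model of free Ca²⁺ in an unbranched
dendritic shaft coupled to spine heads, and a two-threshold calcium rule
for the synaptic weights, so that homosynaptic (stimulated spine) and
heterosynaptic (neighbouring spine) potentiation and depression both emerge
from the same calcium field.

## Model

Dendritic calcium `C_d(x,t)` (µM) obeys a 1-D diffusion–leak equation with
per-spine exchange fluxes at spine-bearing segments:

    ∂C_d/∂t = D ∂²C_d/∂x² − J_ds + J_sd − C_d/τ_decay
    J_ds = k_d C_d,   J_sd = k_s C_s

The exchange rates are inverse mean first passage times across the spine
neck, `k_d = 4 D a_s / V_d` and `k_s = 1/τ'` with
`τ' = V_s/(4 D a_s) + l_n²/(2D)`, where `V_d = π r_d² dx` is the segment
volume and `V_s = 4/3 π r_s³` the spine-head volume. Spine calcium follows

    ∂C_s/∂t = J_syn + J_ds − J_sd − C_s/τ_decay,
    J_syn = γ I_ext / (z F V_s),
    I_ext(t) = Σ_i I₀ exp(−(t−t_i)/τ_d) Θ(t−t_i)

with presynaptic spike times `t_i`. Each synaptic weight `w ∈ [0,1]`
follows the calcium hypothesis with two thresholds
(θ_d < θ_p, Heaviside Θ strict at equality):

    dw/dt = (1−w) γ_p Θ[C_s−θ_p] − w γ_d Θ[C_s−θ_d]

The coupled system is integrated with an implicit backward-Euler scheme
(synaptic influx held at its step-start value), which preserves
non-negativity and conserves mass under the no-flux boundaries. For
input-sequence selectivity, a passive voltage cable plus a somatic
integrator `du_soma/dt = (1/τ)[(u_rest−u_soma) + R(u_dend(x₀)−u_soma)]`
reads out the dendrite; there is no feedback from the soma.

Default physical constants: `D = 220 µm²/s`, `τ_decay = 0.08 s`,
`l_n = 0.5 µm`, `a_s = 0.1 µm`, `r_s = 0.34 µm`, `r_d = 1 µm`, `γ = 0.11`,
`I₀ = 0.1 pA`, `τ_d = 1 ms`. Plasticity thresholds/rates come from named
presets (`"fig2"`, `"fig3"`, `"fig4-grid"`); the rate constants are
calibrated quantities (see the methods vignette).

## Worked example

Stimulate one of two spines 1 µm apart with five single spikes
(the two-spine preset):

```r
library(calplast)
params <- default_parameters("fig2")
params
#> Calcium/plasticity model parameters (preset "fig2")
#>   D = 220 um^2/s, tau_decay = 0.08 s
#>   spine: r_s = 0.34 um, neck 0.5 x 0.1 um; dendrite r_d = 1 um
#>   influx: gamma = 0.11, I0 = 0.1 pA, tau_d = 0.001 s
#>   plasticity: theta_d = 0.002, theta_p = 0.004 uM; gamma_p = 480, gamma_d = 24.8 1/s

arr <- two_spine_arrangement(distance = 1)
sim <- simulate_calcium(single_spike(1), arr, params, T = 4.6)
sim
#> Calcium simulation: 2001 frames, 2 spines, t in [0, 4.6] s
#>   final weight change per spine:
#>   plain   plain
#>  0.1785 -0.4764
```

The stimulated spine potentiates (+0.18) while calcium diffusing through
the shaft depresses its unstimulated neighbour (−0.48): synaptic
competition. `burst(1)` instead potentiates both spines (cooperation), and
`paired_timing(1, 2, 0.015)` — a second input 15 ms later at the
neighbour — reverses the pattern, depressing the first spine.

Random multi-spine arrangements reproduce the reported cluster geometry:

```r
arr16 <- generate_arrangement(seed = 1)
arr16
#> Spine arrangement: 16 spines on a 80 um cable (dx = 0.5 um)
#>   groups: Stim=7, Un_in=3, Un_out=6, plain=0
#>   cluster section: 7 um starting at 35 um
round(cluster_density(arr16), 1)
#> [1] 1.4   # spines/um in the stimulated section
```

Sequence learning at the soma:

```r
sequence_experiment("outward")
#> Sequence-selectivity report (learned: outward, 5 presentations)
#>   weights after learning: proximal 0.489, distal 0.525
#>   test peaks: inward -57.226 mV, outward -56.887 mV
#>   learned/non-learned depolarization ratio: 1.027
#>   crosses threshold (-56.9 mV): inward FALSE, outward TRUE
```

After learning the outward sequence the soma responds more strongly to the
outward than to the inward presentation — the opposite of the passive
cable's intrinsic inward preference.

Higher-level drivers: `timing_sweep()` (input-timing plasticity windows and
their P/D classification via `classify_window()`),
`multi_spine_experiment()` (group outcomes over random arrangements),
`diffusion_sweep()` (matching error against the expected sign patterns
across diffusion constants). A thin command-line wrapper with subcommands
`simulate`, `timing-sweep`, `multi-spine`, `diffusion-sweep`, `sequence`
and `generate-arrangement` is installed at `inst/cli/calplast.R`.

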