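---
title: "Balanced networks, plasticity, and orientation selectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced networks, plasticity, and orientation selectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`balnet` models a square patch of V1 layer 2/3 as two populations of leaky
integrate-and-fire neurons — N_E excitatory and N_I inhibitory cells on
square grids — driven by orientation-tuned feed-forward input and operating
in the balanced state. This vignette documents the model and its
assumptions, every tunable parameter, the numerical choices, the design
decisions taken where the problem was genuinely open, and what the package's
reduced-size test experiments do and do not establish.

## The network model

**Units.** The whole package works in {mV, ms, nA, MΩ}, so `r_m * I` is in
mV and all default values can be used verbatim. Angles facing the user are
degrees; orientations live on [0°, 180°) and all differences use the
double-angle (half-circle) metric.

**Single neurons.** Membrane dynamics
`tau dV/dt = -V + R_m (I_L4 + I_rec + I_back)` with `tau = 20` ms,
`R_m = 38.3` MΩ, threshold `v_t = 30` mV and reset `v_reset = 0` mV. No
refractory period is modelled: at the low rates of the balanced state
(2–10 Hz) refractoriness is irrelevant, and adding one would only matter
near rate saturation.

**Feed-forward input.** Each neuron has a preferred feed-forward angle
θ_i — from the continuous pinwheel map
`arctan(sin(2πy/m)/sin(2πx/m))/2 + π/2 + (π/2)·[sin(2πx/m) < 0]`
(`mode = "map"`) or i.i.d. uniform (`mode = "random"`, salt-and-pepper).
A grating at angle θ delivers the constant current
`g_AL · K_AL · fr_L · (1 + 2ρ cos 2(θ − θ_i))` with `g_AL = 1.65` nA ms,
`K_AL = 250` synapses, `fr_L = 15` Hz and modulation `ρ = 0.06` (the input's
own OSI; it must stay ≤ 0.5 for the drive to remain nonnegative). The drive
is deterministic — it represents the mean of many layer 4 afferents, not a
spiking ensemble — so all response variability is generated recurrently.
One boundary convention is worth noting: the map formula's ±π/2 correction
term is keyed to the sign of `sin(2πx/m)` rather than to `sign(x/m − 1/2)`.
The two agree everywhere except exactly on the columns x ∈ {0, m/2}, which
are grid columns for even lattice sizes; the sine-based form is the reading
under which the map is continuous (mod π) across those columns, leaving only
the four genuine pinwheel points where both sines vanish.

**Recurrent connectivity.** Each ordered pair is connected independently
with probability `Z · G(Δx, σ) · G(Δy, σ)` where `G` is an m-periodic
Gaussian (truncated at `k_max = 5` images; the truncation remainder is below
e⁻³⁰⁰ for σ ≤ 0.2 m) and `Z` normalizes so that the expected in-degree from
each presynaptic population is exactly `k = 500` for every postsynaptic
neuron, with the excluded self-pair removed from the normalizing sum.
Probabilities that exceed 1 (possible when σ is small relative to the
presynaptic grid spacing) are clamped and counted, and a warning reports the
maximum; the realized in-degree check in the test suite guards against
silent distortion. Couplings are `G_AB/√K` with `G_EE = 32`, `G_EI = −96`,
`G_IE = 96`, `G_II = −128` — the 1/√K balanced scaling. Synapses are
exponential currents with `tau_syn_e = 25` ms (a long constant folding NMDA
into the AMPA kernel) and `tau_syn_i = 4` ms. The background drive is
`√K · 0.12` nA per population, i.e. K unmodelled excitatory afferents of
strength 1/√K each.

**Scaling K.** The defaults tie the feed-forward synapse count to the
recurrent one (`k_al = k/2`). `scale_connectivity()` preserves this
operating point when K is varied: it sets `k_al = k/2` and scales
`g_al = G_AL/√k_al` with `G_AL = 1.65·√250` fixed. Under this convention
all three input components (feed-forward, recurrent, background) grow as √K
while the leading-order balanced rates are K-independent, which is the
regime in which "inputs grow, rates don't" comparisons are meaningful. With
`g_al` and `k_al` held fixed instead, the feed-forward component would be
K-independent and the comparison would conflate scaling with a change of
operating point.

## Plasticity

**STDP.** The multiplicative pair rule acts on every synapse with an
excitatory presynaptic neuron (both E→E and E→I):
`Δw = a₊ e^(−Δt/τ₊)(2 − w)` for post-after-pre, `Δw = a₋ e^(Δt/τ₋) w` for
pre-after-post, with `a₊ = 0.0128`, `a₋ = −0.0045`, `τ₊ = 30` ms,
`τ₋ = 40` ms. Inhibitory-presynaptic weights are fixed at 1. Pairing is
all-to-all — every pre/post pair in the history contributes — implemented
online with one presynaptic and one postsynaptic exponential trace per
neuron, which is exact for exponential windows (the test suite checks
agreement with the explicit double sum to 10⁻¹⁰). The multiplicative
factors use the weight current at the triggering spike; exactly simultaneous
spikes contribute nothing (both branches require a strict time difference);
weights are clipped to [0, 2]. The window integral
`α = a₊τ₊ + a₋τ₋ = 0.204 ms > 0` makes uncorrelated activity potentiating
on average, with drift `α ν_pre ν_post` per unit time at w = 1.

**Training protocol.** `apply_plasticity()` runs the network at a single
training orientation (0° by default) with STDP on for `t_plastic`
(13.33 s by default, two thirds of a 20 s session), then freezes the
weights. Tuning is measured afterwards by running the full 9-angle protocol
on the frozen graph. The alternative — a plastic phase per measurement
angle — is available by calling `apply_plasticity()` per angle; the
single-orientation default is justified by the protocol-independence of the
stimulus-averaged drift (shuffling the presentation order leaves the binned
weight-change curve statistically unchanged, a property the suite checks by
Monte-Carlo). Updates are applied once per time step on step-quantized
spike times; no sub-step interpolation.

**Reconnection.** Given measured preferred orientations, the whole graph is
resampled with the distance-dependent probability multiplied by
`1 + ε_cB cos 2(PO_pre − PO_post)`, with the modulation depending only on
the presynaptic population. Resampling (rather than local rewiring) is the
operative reading of generating "a new connectivity matrix"; weights reset
to 1 because reconnection is studied without STDP history. With uniformly
distributed POs the expected in-degree — and hence, in the balanced state,
the mean rates — is unchanged.

## Tuning analysis

Rates are spike counts over half-open windows `[t_start, t_end)` (making
counts additive across windows), by default excluding a 100 ms transient.
The OSI is the ratio of first to zeroth Fourier components of the tuning
curve over the 9 equispaced angles 0°, 20°, …, 160°; the preferred
orientation is the population-vector angle. Both are exact on cosine tuning
curves sampled at equispaced angles (discrete harmonic orthogonality), which
the suite verifies to 10⁻¹². Neurons with zero rate at every angle have
undefined OSI/PO; they are excluded from population means by default and
counted (`include_silent = TRUE` scores them as OSI 0). The
functional-connectivity fit averages per-edge efficacies in 10° bins of
wrapped PO difference over [0°, 90°] and fits `a₀ + 2a₁ cos(πx/90°)` by
unweighted least squares on the bin means; empty bins are dropped with a
warning.

## The reduced ring model

The analytic counterpart maps each neuron to its preferred orientation on a
ring coordinate θ ∈ (0, 1]. Connection profiles from presynaptic population
B are `C_B(θ) = 1 + ε_cB cos 2πθ` (flat = salt-and-pepper); interactions
are `J̃_AB(n) = G_AB C̃_B(n)`, stored as magnitudes with the E/I sign
structure applied inside the balance equations (signed inputs are converted
on construction; this is the single conversion point). In the large-K limit
the net input must vanish mode by mode, giving a 2×2 linear system per
Fourier mode whose solution yields `ν̃(1)/ν̃(0) = ρ J̃(0)/J̃(1)` — selectivity
inversely proportional to the connectivity modulation, the central
counterintuitive property of the balanced state. Up to `n_max = 8` modes
are retained; all built-in profiles live on modes {0, 1}. Degenerate cases
are signalled rather than returned: a mode where the interaction vanishes
but the input does not (the salt-and-pepper limit, where selectivity is
fluctuation-controlled and the mean-field ratio diverges) raises an error
naming the mechanism, as does an infeasible mean-input configuration.
Stability is assessed per mode from the eigenvalues of
`[[J̃_EE, −J̃_EI], [J̃_IE, −J̃_II]]`; modes whose matrix vanishes (flat
profiles, n ≥ 1) have zero eigenvalues and are reported stable. The
reconnection boundary `eps_ci_min` is found numerically (uniroot on the
leading eigenvalue real part at mode 1, tolerance 10⁻¹²) rather than from
the closed form ε_cE·G_EE/|G_II|, and the suite cross-checks the two. The
finite-K ring as a spiking network is deliberately not simulated: the
analytic solution is the deliverable and the 2-D network is the simulation
check.

## Numerical choices

* Forward Euler, `dt = 0.05` ms. Within a step: decay synaptic traces;
  compute currents from previous spikes; update V; threshold and reset;
  apply STDP updates (old traces, so Δt = 0 pairs are inert); bump traces;
  propagate this step's spikes. Spike transmission therefore carries a
  one-step (0.05 ms) latency — an accepted discretization, as no axonal
  delay is modelled. Halving dt changes population rates by under 5 % at
  the sizes tested.
* Recurrent currents use two aggregated exponential traces per neuron (one
  per presynaptic population), mathematically identical to the explicit
  spike-kernel sum at O(N + spikes·out-degree) cost per step; the suite
  checks a single synapse against the closed-form kernel to 10⁻⁹.
* Initial membrane potentials are uniform on [v_reset, v_t) from the run
  seed, avoiding artificial synchrony; the 100 ms transient washes the
  choice out. Every run's seed is derived deterministically from a master
  seed and the stimulus index, so identical seeds give identical rasters.
* Weight jumps at presynaptic spikes use the weight value at spike time.

## The generators as study conditions

`build_geometry()`/`assign_orientations()`/`sample_connectivity()` are the
synthetic-structure generators that make every downstream analysis testable
without data. Their defaults *are* the study conditions: N_E = 8100,
N_I = 2025, m = 1 mm, K = 500, σ = 0.2 m, ρ = 0.06, 20 s runs at 9 angles.
They emulate (i) a periodic pinwheel map or salt-and-pepper layout, (ii)
distance-dependent sparse connectivity with controlled in-degree, and (iii)
PO-modulated functional reconnection. They do not emulate distance-dependent
synaptic *strength*, axonal/dendritic morphology, feed-forward spiking
noise, or any spatial correlation between the salt-and-pepper layout and
position — so passing tests establish the internal consistency of the
balanced-state mechanism, not a fit to biological data.

## Test problem sizes and what the experiments show

The suite runs three tiers, sized so the whole run takes minutes:

* **Analytic/oracle tier** (instant): stability boundary, STDP trace/double-
  sum equivalence, OSI/PO closed forms, dense-grid mean-field checks.
* **Desk tier**: a reduced network (N_E = 1600, N_I = 400, K = 100 with
  `scale_connectivity()`, 5 s per angle, 3 seeds) for directional claims —
  salt-and-pepper is more selective than a map; STDP (α > 0) raises mean
  OSI in both layouts. The √K-scaling experiment uses N_E = 6400,
  N_I = 1600 with K ∈ {100, 400}: a 400-neuron inhibitory population cannot
  supply 400 synapses per target (and the Gaussian footprint caps realized
  in-degree near 0.25·N_I at σ = 0.2 m), so the inhibitory population is
  sized to keep K = 400 feasible.
* **Full tier** (one realization of the default network): preferred
  orientations track the feed-forward angles (circular correlation ≈ 0.89),
  and the reconnection grid ε_cE ∈ {0, 0.22, 0.44} at ε_cI = 0.22 lowers
  excitatory OSI monotonically while leaving mean rates within 5 % — the
  stable-balanced-state prediction. This claim needs the full-size network:
  at desk scale the fluctuation-driven OSI (≈ 0.28) already sits at the
  mean-field bound 2ρ/ε_cE, and PO-measurement noise attenuates the
  imprinted modulation, so there is no room for a visible decrease.

## Known limitations

* **Inhibitory √K scaling is imperfect.** The inhibitory input component
  equals √K·G_EI·ν_I (times kernel factors), so it doubles under K×4 only
  if ν_I is K-independent. Finite-K corrections lower ν_I substantially
  between K = 100 and K = 400 (≈ −39 % at the desk sizes; smaller but
  nonzero at larger K), so the measured inhibitory ratio is ≈ 1.2–1.5
  rather than 2. The excitatory component, dominated by the exactly-scaled
  feed-forward and background terms, does double within 15 %. The
  corresponding acceptance assertions are left strict and fail honestly.
* **PO conservation under reconnection is partial.** Resampling the graph
  re-randomizes the realization-specific component of each neuron's
  preference; only the θ-locked component survives. With 20 s measurements
  on the default network the before/after circular correlation is ≈ 0.79
  for a pure resample (the square of the PO~θ correlation), ≈ 0.68 at
  ε = (0.22, 0.11), and collapses at the strong stable pair (0.44, 0.22)
  because the functional modulation cancels precisely the θ-locked input —
  the same mechanism that reduces OSI. The invariant test asserts the
  robust part (PO~θ > 0.8; positive conservation in the mild regime).
* Mean OSI values at reduced sizes are not comparable to full-scale values
  (selectivity is partly fluctuation-driven and K- and N-dependent);
  desk-tier results are directional only.
* The O(1/√K) theory of connectivity-fluctuation contributions to
  salt-and-pepper selectivity is out of scope; it is retained only as the
  qualitative statement that the flat-profile mean-field ratio diverges and
  fluctuations take over.
* Conductance-based synapses, NMDA voltage dependence, transmission delays,
  inhibitory plasticity and homeostatic scaling are not modelled.
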