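---
title: "prcsync: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prcsync: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prcsync` simulates how firing frequency reshapes neuronal phase response
curves (PRCs) and, through them, the synchronization of excitatory
networks. This vignette is the package's own account of the science it
implements: the models and their assumptions, the protocols, the tunable
parameters, what the synthetic inputs emulate, and the places where the
design was genuinely open and we had to choose.

## The two neuron models

**Morris-Lecar (ML).** A two-variable conductance model, `(V, w)`, with an
instantaneous inward calcium current and an outward potassium current
gated by `w`:

$$C \dot V = I - g_L (V{-}E_L) - g_{Ca}\, m_\infty(V) (V{-}E_{Ca})
           - g_K\, w (V{-}E_K), \qquad
  \dot w = \phi_w \,\frac{w_\infty(V) - w}{\tau_w(V)},$$

with sigmoidal steady states and $\tau_w(V) = 1/\cosh((V-V_3)/(2V_4))$.
Units are mV, ms, µA/cm² and µF/cm² throughout the package. Two parameter
regimes are shipped (`ml_type1`, `ml_type2`): the Type I set loses its
rest state through a saddle-node bifurcation on an invariant circle
(firing at arbitrarily low frequency, rheobase near 40 µA/cm²), the Type
II set through a subcritical Hopf (a finite-frequency jump, onset near
94 µA/cm² at about 11 Hz). `phi_w` is a pure multiplicative factor on the
`w` relaxation rate; increasing it speeds up the delay-producing
potassium current.

**Cortical pyramidal cell.** A single-compartment Hodgkin-Huxley-type
model, `(V, h, n, z)`: fast sodium with instantaneous activation
($m_\infty^3 h$), a delayed rectifier ($n^4$), leak, and a slow,
low-threshold, muscarine-sensitive potassium current (M-type) gated by
`z` with conductance $g_{Ks}$ and $\tau_z = 75$ ms. Setting $g_{Ks} =
1.5$ mS/cm² yields a Type II cell; $g_{Ks} = 0$ — modelling full
cholinergic suppression of the M-current — yields a Type I cell. The
gating multipliers `r_h` and `r_z` (default 1, as in all network
simulations) scale the relaxation rates of `h` and `z` and are the knobs
of the gating-rate experiments.

All numeric parameter values live in one shipped JSON file
(`inst/extdata/model_parameters.json`); code reads them from there and
tests assert the file is the single source of truth. The source text this
package was built from redacts every numeric value in its methods, so the
parameter sets were transcribed from the publications it cites as its
sources (the classical ML excitability study and the cholinergic
PRC-switching model). The transcription is validated by the one numeric
anchor available: the Type II pyramidal cell's f-I threshold frequency,
which bisection reproduces at ≈ 8 Hz.

## PRC protocol

A synaptically isolated neuron is driven with constant current until its
spike-peak-to-spike-peak period stabilizes (three successive periods
within 0.01%; this tolerance matches the 100-phase resolution of the
protocol). Phase zero is anchored at the spike peak. A square current
pulse (ML: 100 µA/cm² for 0.50 ms; pyramidal Type I: 3.0, Type II: 10.0,
for 0.06 ms) is delivered at each of 100 equally spaced phases in
separate runs, and the shift at phase $\varphi$ is $(T_0 -
T_{pert}(\varphi))/T_0$ — the first-order PRC, using only the period of
the cycle containing the pulse. We verified on the ML Type II cell that
cumulative five-cycle shifts agree with the first-cycle measure, so no
higher-order correction is needed. Advances are positive. Shifts are
approximately linear in pulse amplitude (halving the amplitude halves the
PRC within 20%), i.e. the protocol operates in the weak-perturbation
regime.

**Delay depth and the early-phase exclusion.** The delay depth is the
absolute value of the most negative PRC value after excluding phases at
which the *unperturbed* voltage is still above the −20 mV spike
threshold. A pulse landing on the action potential itself produces small
spurious delays; in the ML model the spike occupies a large fraction of
the interspike interval and this exclusion is essential, while in the
pyramidal model it removes only the first phase or two. We apply it to
both models: without it, the 1-3 intra-spike phases of the pyramidal
Type I PRC carry shifts of −0.002 to −0.004 that would misclassify an
otherwise strictly advance-only curve. In the ML model a small negative
residue (≤ 0.003) persists slightly past the threshold re-crossing,
through the downstroke to the afterhyperpolarization trough; beyond the
trough the Type I ML PRC is strictly positive, and the Type I acceptance
property reads the spike-dominated "early region" as extending to that
trough. The Type II delay trough always lies beyond it, so this reading
never touches a genuine delay region.

**Calibration.** `calibrate_rate_for_depth()` bisects one gating-rate
knob (geometric midpoints, since rates act multiplicatively) until the
recomputed PRC's delay depth hits a target within 1e-3. Two caveats found
empirically, both documented as red acceptance outcomes rather than
worked around: with our transcribed parameter sets the ML delay depth
saturates near 0.012 before faster `phi_w` kills the oscillation, so the
historical target of 0.04 is unattainable; and the pyramidal depth is
non-monotone in `r_z` (faster z raises the firing rate, and frequency
attenuation dominates the faster gating response), so only `r_h`-based
and fixed-point calibrations are demonstrated green.

## Network simulations

Networks have N = 200 neurons on a directed Watts-Strogatz graph: a ring
with periodic boundaries, each neuron coupled to its k = 4 nearest
neighbours per side (out-degree 2k; a `mode = "total"` reading of the
connectivity radius is also available), each edge independently rewired
with probability `p` to a uniform random target, never creating
self-loops or duplicates and never changing the edge count.

Synapses are excitatory and current-based. A presynaptic spike is
registered when the membrane voltage breaches −20 mV (upward crossing
with re-arming) and delivers, one integration step later, an alpha-kernel
current $s\,(t/\tau)\,e^{1-t/\tau}$ with $\tau = 2$ ms and peak `s`
µA/cm² to every target; overlapping inputs sum linearly. The kernel
expression is redacted in the source text; the alpha form follows the
closely related network studies the source builds on, and the kernel is a
pluggable interface with this single shipped implementation. Integration
is fixed-step RK4 (0.05 ms pyramidal, 0.10 ms ML; halving the step
changes single-neuron periods by < 0.1%), events are bound to the grid,
and identical seeds give bit-identical rasters.

Two drive regimes emulate the studies' inputs:

* **Constant-Gaussian.** Per-neuron constant currents drawn from a
  Gaussian whose SD is calibrated through the local f-I slope so the
  intrinsic-frequency SD is 1 Hz (verified by uncoupled simulation,
  ±10%). This prevents trivial synchronization of identical oscillators.
  Near a Type II threshold the current Gaussian inevitably leaves a small
  sub-rheobase fraction silent; measures exclude the resulting undefined
  pairs and report their count.
* **Poisson pulses.** Square pulses of 30 µA/cm² and 0.2 ms delivered as
  independent per-neuron Poisson trains at rate `f_noise`, on a constant
  sub-threshold baseline (0.0 µA/cm² Type I, 0.5 µA/cm² Type II). The
  baselines are calibrated to the stated excitability property — a single
  pulse never fires a resting cell, two back-to-back pulses do — because
  their numeric values are redacted in the source text.

Default initial conditions place every neuron at the rest state of its
own drive current, nudged +1 mV: supra-threshold drive leaves only an
unstable fixed point, which is exactly invariant under the integrator,
so un-nudged networks would sit silent forever. The time-to-sync
experiment instead randomizes voltages uniformly on [−70, −50] mV with
gating variables at their equilibria.

## Synchrony measures

**Mean phase coherence (MPC).** Each spike of a probe train gets a phase
from its linear position between the bracketing reference spikes (left
bracket strictly earlier; a coincident spike gets phase zero); the pair
MPC is the modulus of the mean unit phasor over usable probe spikes — 1
for locking at any common phase, ~0 for unrelated trains — and is
asymmetric in its arguments. The network MPC averages all ordered pairs;
pairs with fewer than two reference spikes or no usable probe spikes are
excluded and counted rather than zero-filled, which would bias
sparse-firing regimes.

**Bursting measure B.** From the pooled, time-ordered spike list of all
neurons, with $\tau_i$ the successive pooled intervals,
$B = \big(\sqrt{\langle\tau^2\rangle - \langle\tau\rangle^2}\,/\,
\langle\tau\rangle - 1\big)/\sqrt{N}$. Pooled intervals of a synchronous
raster are far more dispersed than those of an asynchronous one: B ≈ 0
for Poisson spiking and approaches 1 for perfect phase-zero locking as
spike and neuron counts grow (10,000 identical trains give 0.995). The
printed form of this measure is redacted in the source text; the
implementation follows the burst-synchrony statistic of the work it
cites, and both stated limits are verified by test. Unless noted, both
measures use spikes in [3000, 10000] ms.

**Time to synchronization** evaluates B on 500 ms windows stepped by
100 ms from t = 0 and reports the end of the first window with B ≥ 0.6;
runs that never breach are censored and counted, never averaged
silently. The 500/100 ms windowing is our declared choice — the source
does not specify its online window.

## The synthetic fixture generator

`fixture_raster()` blends a jittered periodic template (kept per neuron
with probability `sync_fraction`, Gaussian jitter `jitter_sd`) with
independent Poisson background at the complementary rate. It gives the
measures a dial with known ground truth: B and MPC decrease monotonically
in jitter and increase in sync fraction. It emulates the *statistics* a
synchronous network produces, not its dynamics — a green measure test
establishes the measures, not the simulator.

## Scales, budgets and stated-world choices

The drive levels and synaptic-weight ranges of the network studies are
redacted in the source text. We define them relative to computed
rheobases, once: ML Type II networks are driven at 95 (low) vs 120 (high)
µA/cm² with s = 15, where the network crosses its synchronization
transition; pyramidal Type II networks at 1.5 vs 2.5 µA/cm² with s in
0.2-0.8, whose upper range is the high-coupling regime used for
time-to-sync; stochastic runs use `f_noise` 100 vs 200 Hz (Type II),
mapping to roughly 9 vs 16 Hz firing. Test-suite sweeps are scaled down
(coarser grids, replicates ≤ 5, horizons of 6-7 s instead of 10 s) and
say so; the full 10 s horizon with 3 s discard remains the default of
every user-facing function.

## Known limitations

* The figure-level network claims are encoded as sign/ordering
  properties at reduced scale, not value matches; replicate counts in
  the source are unstated except for time-to-sync.
* In our transcribed parameter world the pyramidal constant-drive
  frequency contrast reverses below the high-coupling regime (B can
  increase with drive at small s or low p); the stated direction holds
  at p ≥ ~0.5 with s ≥ 0.5, and that regime is what the acceptance
  property pins.
* Current-based synapses make effective coupling grow with firing rate;
  conductance-based synapses, inhibition, gap junctions and dendritic
  PRC effects are out of scope.
* Type I pyramidal networks are extremely excitable (rheobase
  ~0.08 µA/cm²); at the weights that synchronize Type II networks they
  settle into high-rate asynchronous firing, which is why the Type I
  acceptance property asserts insensitivity of B to drive rather than an
  absolute synchrony level.
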