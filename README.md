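# prcsync

Phase response curves and synchronization of excitatory neuronal
networks: a simulation-and-analysis pipeline for studying how firing
frequency differentially reshapes the dynamics of Type I versus Type II
model neurons and, through them, the synchrony of the excitatory networks
they form.

## The scientific problem

A periodically firing neuron responds to a brief input with a shift of
its next spike; the shift as a function of the stimulus phase is the
**phase response curve (PRC)**. Excitable cells fall into two classes:
**Type I** cells respond to excitation only with phase advances and fire
at arbitrarily low rates at their current threshold, while **Type II**
cells also show phase *delays* at early phases and jump to a finite
frequency at threshold. The delay region of a Type II PRC is what lets
excitatory coupling pull spike times together, so Type II networks
synchronize far more readily.

PRCs are not static: raising the firing rate attenuates them, and it
attenuates the Type II delay region much more strongly than the advance
region, because the slow hyperpolarizing current that produces the delays
(the potassium recovery current in the Morris-Lecar model, the
muscarine-sensitive M-current `g_Ks` in a cortical pyramidal cell) has
fixed kinetics while the interspike interval shrinks. The network-level
consequence, which this package reproduces as testable properties, is
that **driving a Type II network harder makes it markedly less
synchronous, while Type I networks barely care**.

The package implements, as separately tested modules:

* `models` — Morris-Lecar (Type I/II parameter sets) and a
  Hodgkin-Huxley-type cortical pyramidal cell whose PRC class is switched
  by the M-type conductance `g_Ks` (cholinergic modulation), with all
  constants in one shipped JSON file;
* `simulate` — fixed-step RK4 integration (0.05/0.10 ms), online −20 mV
  spike detection, grid-bound alpha-kernel synapses;
* `prc` — f-I curves, rheobase bisection, the 100-phase brief-pulse PRC
  protocol, delay depth, gating-rate calibration;
* `netgen` — directed Watts-Strogatz graphs, drive generators
  (constant-Gaussian calibrated to a 1 Hz intrinsic-frequency spread;
  Poisson square-pulse trains), synthetic fixture rasters;
* `measures` — pairwise/network mean phase coherence (Eqs. of the pair
  bracketing kind; asymmetric) and the pooled-interval bursting measure
  `B = (CV(pooled ISIs) − 1)/√N`;
* `experiments` — PRC-frequency families, gating-rate scans, network
  sweeps over re-wiring × drive × weight, difference heatmaps,
  time-to-synchronization;
* `cli_io` — JSON run configs, CSV round-tripping, and a CLI
  (`inst/cli/prcsync`) with subcommands `fi-curve`, `prc`, `measure`,
  `fixtures`, `sweep-constant`, `sweep-stochastic`, `heatmap`,
  `time-to-sync`.

## Worked example

```r
library(prcsync)

## f-I threshold of the Type II pyramidal cell (the package's quantitative
## anchor): bisection on constant current
q2 <- neuron_params("pyr_type2")
rb <- rheobase(q2, i_range = c(0, 10), tol = 1e-3)
round(c(rheobase = rb$rheobase, onset_Hz = rb$onset_frequency), 3)
#> rheobase onset_Hz
#>    1.468    8.000

## PRCs of the same cell at increasing drive: the delay region collapses
fam <- prc_frequency_family(q2, c(1.5, 2, 3))
fam$summary
#>   current frequency max_advance delay_depth
#> 1     1.5  8.237095  0.04268732 0.018714373
#> 2     2.0 11.293579  0.03425978 0.006518792
#> 3     3.0 16.587642  0.03394927 0.004550626

## A Type II Morris-Lecar network, driven gently vs hard
sw <- constant_drive_sweep("ml_type2", p_values = 0.6,
                           mean_currents = c(95, 120), s = 15,
                           seed = 1, t_end = 7000,
                           window = c(2500, 7000))
sw[, c("p", "drive", "frequency", "B", "mpc")]
#>     p drive frequency         B       mpc
#> 1 0.6    95  12.86111 0.6805783 0.9970299
#> 2 0.6   120  15.33444 0.3067563 0.9090226
```

The first block reproduces the ≈ 8 Hz threshold-frequency jump that marks
the pyramidal cell as Type II. The second shows the asymmetric PRC
attenuation (delay depth falls four-fold while the advances lose ~20%).
The third is the headline network effect: raising the mean drive of a
synchronizing Type II small-world network (re-wiring p = 0.6, synaptic
weight 15 µA/cm² peak) increases its rate but *decreases* both its
phase-zero synchrony B and its mean phase coherence.

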