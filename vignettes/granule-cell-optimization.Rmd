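---
title: "Conductance optimization for cerebellar granule cell models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance optimization for cerebellar granule cell models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grcopt)
```

# The modelling problem

The cerebellar granule cell (GrC) is one of the smallest neurons of the brain
and is electrotonically compact (electrotonic length around 0.04), which has
allowed its ionic currents to be measured directly under voltage clamp. Its
canonical electroresponsiveness is well characterized: a resting potential
near -65 mV kept in place by a leak and an inward-rectifier potassium current
(Kir), rapid repetitive firing above roughly 10 pA of injected current with a
steep, nearly linear frequency/current relation (~7 spikes s^-1 per pA),
first-spike delays that collapse from tens of milliseconds to a few
milliseconds as the current grows (an A-type potassium, KA, signature), two
after-hyperpolarization phases carried by a calcium-dependent potassium
current (KCa) and a slow M-like potassium current (Kslow), and theta-band
(~4-5 Hz) resonance shaped by the interaction of Kslow with the persistent
sodium current (Nap).

Given the channel complement, the free parameters of a conductance-based
model are the maximum specific conductances `G_i-max` (mS/cm^2). This package
implements the full loop for estimating them from firing patterns:

1. **Cell models** (`granule_model()`): a mono-compartment sphere
   (radius 9.76 um) carrying Na, Nap, Nar, KV, KA, Kslow, Kir, KCa, Ca-HVA
   and a leak; and a multi-compartment cell (four 15 x 0.75 um dendrites,
   a 5.8 x 5.6 um cylindrical soma, a 2.5 x 1.5 um axon initial segment, and
   a 70 x 0.3 um ascending axon split into 15 segments) in which sodium
   channels live only in the AIS and axon as a 13-state Markov scheme with
   resurgent gating, Kir/Kslow/KA on the soma, and KCa/Ca-HVA plus a calcium
   shell on the dendrites.
2. **Simulation** (`simulate_model()`): the membrane equation
   `dV/dt = -1/Cm (sum_i g_i (V - E_i) + I_axial - I_inj)` on the compartment
   tree under current-clamp steps, ZAP chirps and voltage-clamp steps.
3. **Features and objectives** (`extract_features()`, `objective_scores()`):
   ten electrophysiological features per stimulus (resting voltage, spike
   height/width/half-width, fast and slow AHP depth, time to first spike,
   mean frequency, adaptation index, ISI coefficient of variation), each
   turned into one objective `|feature - mean| / sd` against a template.
4. **Optimization** (`run_optimization()`): an indicator-based evolutionary
   algorithm (IBEA, additive-epsilon indicator) over `G_i-max` vectors.
5. **Validation** (`fi_curve()`, `inward_rectification()`, `zap_resonance()`,
   `near_threshold_oscillations()`, `conduction_metrics()`,
   `input_resistance()`): emergent properties that were never used as
   objectives.
6. **Synthetic ground truth** (`sample_ground_truth()`, `make_templates()`,
   `parameter_recovery()`): recovery experiments in which the optimizer must
   re-find a known conductance vector from features alone — the package's
   principal correctness probe, since no experimental recordings are shipped.

# Units and conventions

Voltages in mV, time in ms, specific conductances in mS/cm^2 (absolute
conductances in uS internally), currents injected in pA, current densities in
mA/cm^2, concentrations in mM, geometry in um, axial resistivity in Ohm cm,
specific capacitance in uF/cm^2. Currents are positive outward. All gating
kinetics are taken as already normalized to 30 C; no Q10 machinery runs at
simulation time.

# The kinetics set

The admissible conductance ranges, reversal potentials, and channel placement
are tabulated data shipped with the package (`granule_channel_table()`); the
gate rate functions are not tabulated anywhere and are therefore configuration
data: a versioned *kinetics set* (`kinetics_set("grc2017")`,
`inst/extdata/kinetics-grc2017.yaml`). Its functional forms are the ones used
throughout the GrC model family — sigmoid steady states with bell-shaped time
constants (or exp/sigmoid/linoid alpha-beta rates), a calcium- and
voltage-dependent BK-type KCa gate of the Gabbiani form, a first-order
calcium shell with a dynamic Nernst reversal (z = 2; with [Ca]o = 2 mM and
[Ca]rest = 1e-4 mM at 30 C the resting calcium reversal is 129.3 mV), and a
13-state Markov sodium scheme (five closed states, open, open-blocked, six
inactivated states; allosteric factors `a = (Oon/Con)^(1/4)`,
`b = (Ooff/Coff)^(1/4)`).

The numeric rate constants of `grc2017` were calibrated, once, so that the
*reference models* — every conductance at the midpoint of its admissible
range — reproduce the canonical behaviors that define a GrC model:

```{r}
mono <- granule_model("mono")
fi_curve(mono, amplitudes = c(10, 16, 22))$slope   # ~7.1 spikes s^-1 / pA
input_resistance(mono)                              # ~1.30 GOhm
zap_resonance(mono)$peak_hz                         # ~4.4 Hz
multi <- granule_model("multi")
input_resistance(multi)                             # ~2.10 GOhm
conduction_metrics(multi)$speed_mm_ms               # ~0.24 mm/ms
```

This mirrors how such models are built in practice: kinetics are inherited
from previously fitted models of the same cell and the conductances are the
only free parameters. Within this package the kinetics set is *fixed
configuration*: the optimizer never touches it, and the recovery experiments
measure the optimizer against the same kinetics used to generate the
templates.

Two defaults deserve explanation:

* **Leak reversals in the multi model.** Only the dendritic leak reversal
  (-16.5 mV) is tabulated; the somatic, AIS and axonal leak reversals are
  part of the kinetics configuration (-80.5 mV). Together with Kir this
  places the multi model's rest near -78 mV and its input resistance at
  2.10 GOhm.
* **Calcium decay ("Calc").** The decay rate of the calcium shell is a
  per-model parameter (it is itself one of the optimizable genes). The mono
  model uses 1.5 /ms. The multi model uses 0.1 /ms for its dendritic shells:
  with a fast decay the dendritic Ca-KCa loop equilibrates instantaneously
  and the model possesses a stable depolarized fixed point (depolarization
  block) at the stronger test currents; the slower shell turns that loop into
  a delayed negative feedback that sustains repetitive firing.

# Numerical scheme

The hot loop is compiled (Rcpp). Voltages advance by a theta-method
(Crank-Nicolson by default) solved directly on the compartment tree in
Hines order; Hodgkin-Huxley gates advance by Rush-Larsen exponential updates
whose steady states and exponential factors are pre-tabulated on a 0.05 mV
grid; the two updates are staggered leapfrog-fashion (gates live on
half-steps), which makes the scheme second-order in the smooth regime. The
Markov scheme advances by an implicit backward-Euler solve of the master
equation, `(I - dt Q^T) P' = P`: because `Q`'s rows sum to zero and its
off-diagonal entries are non-negative, this update conserves total occupancy
exactly and preserves non-negativity for *any* step size (M-matrix
argument) — the occupancy error over a full simulation stays below 1e-9.
The calcium shell uses the exact solution of its linear equation over each
step, with a 1e-6 mM floor guarding the logarithm in the Nernst potential.

Default step: 0.025 ms (0.0125 ms for propagation measurements, where peak
times are refined by parabolic interpolation). Before every protocol the
model is initialized with gates at steady state at `v_init` and settled for
500 ms without input, so results do not depend on the nominal initial
voltage. Accuracy was checked two ways: against closed forms (passive RC
charging matches to <0.5%; see the test suite) and against an independent
adaptive solver (`deSolve::lsoda` at rtol 1e-7 over a pure-R restatement of
the same equations), which reproduces the resting state to ~1e-4 mV and
early spike times to <0.1 ms. One caveat is documented honestly: over a
1-second 57-Hz spike train, timing phase accumulates, so late spike times
shift by ~1 ms when the step is halved; mean frequency changes by <2%. All
quantities this package reports are either early-spike properties, rates, or
steady states, which are stable under refinement.

# The optimizer

IBEA with the additive-epsilon indicator: objectives are normalized to
[0, 1] per dimension over the current population; fitness is
`F(x) = sum_{y != x} -exp(-I(y, x)/(c * kappa))` with `c = max |I|` and
`kappa = 0.05`; environmental selection iteratively removes the worst
individual and restores its contribution to the survivors. Mating is binary
tournament; variation applies, per pair, gene swaps with probability 0.25
under an individual recombination probability of 0.5, and bounded
polynomial mutation (eta = 20) under an individual mutation probability of
0.5. Population defaults are 150 (mono) / 200 (multi), 50 generations per
cycle, 10 cycles. Between cycles the admissible range of each gene is reset
to the span of the top decile of the final generation, widened by 10% of the
initial width and clipped to the initial envelope, and the population is
re-seeded around the carried-over top decile. Where the procedure was
under-determined we chose: kappa and the per-generation normalization are
standard IBEA defaults; fitness ties break by stable population index
(earlier individuals retained) for exact reproducibility; evaluations are
cached on the genome so clones are never re-simulated; simulation failures
score the 250-per-objective penalty rather than aborting the run. A
non-spiking individual also scores 250 on every spike-dependent objective,
which dominates any realistic z-score and reproduces the biological-validity
pressure; `filter_valid()` applies the hard criterion afterwards (spikes at
all three test amplitudes).

# Synthetic data and what the tests show

No experimental recordings are shipped or consumed. The synthetic-data
module plays the role of the recordings: a ground-truth conductance vector
is drawn uniformly inside the admissible ranges with a 5% margin per gene
(so recovery is never a boundary artifact) and accepted only if its model
spikes at all three template amplitudes with every feature defined. Template
means are the ground-truth model's own features (optionally perturbed by
Gaussian noise); template standard deviations are the shipped experimental
ones, so objective scales match the real optimization problem. Noise-free
templates are the default acceptance surface: they isolate algorithmic
correctness (can the optimizer invert features back to conductances?) from
noise robustness. What passing recovery tests do *not* show: that real
recordings constrain the conductances equally well — real data add
measurement noise, trial-to-trial variability and model misspecification,
none of which the generator emulates.

Desk-scale budgets are used throughout the shipped analyses and tests
(mono recovery: population 30, 15 generations, 2 cycles, 2-s traces;
multi recovery: population 12, 6 generations, 1 cycle, 1.5-s traces), about
two orders of magnitude below the full protocol; the recovery accuracies
reported by `analysis/03_parameter_recovery.R` are computed at these sizes.

# Validation analyses

* **f/I curve**: mean frequency and first-spike delay per step over
  10-34 pA (6 pA increments), least-squares slope over spiking amplitudes.
* **Inward rectification**: -3 to -9 pA steps; the rectification index is
  the chord conductance at -9 pA over that at -3 pA; a passive membrane
  gives exactly 1, Kir pushes it above 1.
* **ZAP resonance**: `A sin(B t^2)` chirp (A = 10 pA) sweeping 0-10 Hz over
  30 s (>= 2 s per 1-Hz band) on top of a tonic offset at rheobase + 2 pA so
  the cell fires throughout; instantaneous frequency per adjacent spike
  pair, averaged within each chirp cycle (cycles with fewer than 3 pairs are
  excluded as degenerate); the peak of that curve is the resonance
  frequency. Averaging the raw ISI instead is available as an option.
* **Near-threshold spectra**: hold 1 pA below rheobase (rheobase located by
  bisection to 0.5 pA) for 5 s; Hann-windowed, zero-padded FFT of the
  detrended voltage; report the dominant component above 1 Hz.
* **Propagation**: somatic 16 pA step; per-compartment spike peak times with
  parabolic sub-step refinement; conduction speed between two proximal
  axonal sites (the sealed distal end of the 70 um axon is near-isopotential
  and would bias the estimate toward infinite speed); back-propagation delay
  as the absolute AIS-to-dendrite peak-time difference.
* **Input resistance**: voltage-clamp at rest, -10 mV step for 100 ms,
  resistance from the steady-state clamp-current change.

# Known limitations

* **Near-threshold oscillations are damped.** The calibrated kinetics yield
  a stable (damped) subthreshold fixed point below rheobase; the voltage
  rings near the resonance frequency after a perturbation but does not
  oscillate indefinitely, unlike the sustained 4-6 Hz oscillations of real
  GrCs. The spectral analysis reports the dominant component of whatever
  transient is present.
* **Dendritic back-propagation is effectively instantaneous.** With the
  tabulated morphology the soma-dendrite coupling conductance (~0.06 uS)
  against ~0.35 pF of dendritic capacitance gives microsecond-scale peak
  lags; we measure ~0.009 ms. A 0.2 ms peak-to-peak lag is not reachable in
  this electrotonically compact geometry — consistent, in fact, with the
  <2% somatodendritic attenuation the same cell is known for.
* **The multi model is more excitable than its mono sibling** (it fires
  faster at matched currents), its spike heights shrink at the strongest
  validation currents, and its ZAP response peaks at the low end of the swept
  band rather than in the theta band (the somatic Kslow conductance is ~17x
  smaller in absolute terms than in the mono model, so the resonance
  mechanism is weak there).
* Axon discretization defaults to 15 uniform segments; doubling it changes
  the conduction estimate by well under the reported precision.
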