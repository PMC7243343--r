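---
title: "Model and methods: multisensory integration in a collicular network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multisensory integration in a collicular network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msinet)
```

## The model

`msinet` simulates a population of multisensory neurons of the deep superior
colliculus (SC) as a one-dimensional array of `N = 20` channels covering
azimuthal locations `0 .. N-1`. Eight coupled populations interact through
first-order conductance-based rate dynamics, integrated with forward Euler
(`dt = 0.001`, 4000 steps per stimulus presentation, all membranes starting
at rest):

* `r` — the SC output neurons. Their membrane obeys a shunting equation:
  excitation `(beta_d - r) * EX * (1 + lambda * MOD)` saturates at `beta_d`,
  and inhibition `kappa_r * r * INH` is divisive. `EX = S^a + S^v` is the
  pointwise sum of the sensory fields — deliberately without a spatial
  kernel, which is what localizes excitation while inhibition spreads.
* `p_sen` — a feedforward coincidence detector driven by the *product*
  `S^a * S^v`; it is active only where both modalities stimulate the same
  location, and feeds the SC inhibition through a rectifier with slope 2.
* `p_pool` — a normalization pool driven by the kernel-weighted SC rates
  `sum_j K_ij h(r_j)`, feeding back divisively; together with `p_sen` it
  keeps population energy bounded across intensities.
* `q_m` — modulatory interneurons representing descending cortical feedback.
  They are excited by the cortical fields `(C^a + C^v)` (saturation
  `beta_m = 2`) and vetoed by a cross-modal inhibition circuit.
* `q_S1a/q_S1v/q_S2a/q_S2v` — the veto circuit. Each `S1` population copies
  its modality's cortical field; each `S2` population is excited by its own
  modality and inhibited by the *other* modality's `S1`. An `S2` population
  therefore detects "my modality is active here and the other is not", and
  its activity suppresses `q_m`. Modulation survives only where **both**
  cortical fields are active — the gate that restricts multisensory
  enhancement to genuinely bimodal stimulation.

Rates are read from membranes through `g(x) = clip(k*x, 0, 1)` (slope `k = 2`
for the coincidence pathway, 1 elsewhere) and, for the SC output, through the
sigmoid `h(r) = 2/(1 + exp(-(3.4 r)^2)) - 1` with negative membranes
rectified to zero. The squared exponent makes `h` expansive near rest;
rectification keeps hyperpolarization silent. Stimuli are Gaussian fields
`I * exp(-(i - x)^2 / (2 sigma_z^2))` evaluated at the integer channels with
real-valued centers.

## Design choices where the design was open

**Response readout.** All scalar response metrics (the bimodal response `M`
and unimodal responses `V`, `A`) are read as the *equilibrium membrane
potential* of the readout neuron, which the conductance dynamics keep in
`[0, beta_d]`. The alternative — reading responses through the expansive
sigmoid `h` — makes any summed input super-additive at low intensity simply
because `h` grows quadratically near rest; that nonlinearity then dominates
the additivity index and the cortical-ablation control ceases to be
sub-additive. With the membrane readout the saturating excitation provides
the sub-additive baseline and super-additivity appears only where the
feedback factor `(1 + lambda * MOD)` supplies it, which is the intended
interpretation of the circuit. `h` remains the firing-rate output: it drives
the normalization pool and the `sc_rate` profile used for peak counting.

**Kernel amplitudes.** The lateral interactions (pool normalization,
coincidence inhibition, and the `S1 -> S2` veto) use the normalized Gaussian
kernel `K_ij = exp(-((i-j)/sigma)^2/2) / (sigma sqrt(2 pi))` with
`sigma = 1`. The two kernels of the cortical feedback path — the modulatory
projection `q_m -> SC` and the cross-modal veto `S2 -> q_m` — are Gaussian
with `sigma_m = 3` at *unit peak amplitude* (equivalently: their gain does
not shrink with their width). This is a deliberate modeling decision with a
functional rationale. With area normalization the broad feedback kernels
deliver at most a few percent of multiplicative gain, so no parameter setting
of `lambda` near its default produces enhancement at all; and a *narrow*
strong veto cannot silence modulation generated between two stimuli three
widths apart. Unit amplitude on both feedback kernels simultaneously yields
strong aligned enhancement, the loss of enhancement by three-sigma offsets,
and clean decoupling at five sigma, with every lateral computation untouched.
`make_kernel(..., normalize = FALSE)` exposes the variant.

**Coincidence-detector constants.** The `p_sen` equation's time constant and
leak are not separately specified anywhere in the parameter set; they default
to the shared membrane constants (`tau = alpha = 1`).

**Unused constant.** The SC parameter block carries `l = 3.6` which no state
equation references; `msi_params()` stores it as `l_unused` for completeness
and never reads it.

**Boundaries, updates, convergence.** The azimuthal array is finite, not
circular: kernels are evaluated in full with zero padding, so border channels
receive less lateral input. All eight populations are updated synchronously
from the same pre-step snapshot, making results independent of update order.
Convergence is quantified by the *residual* — the maximum absolute
single-step state change at the final step — reported in every
`simulate()` result; at the defaults it is below `1e-4` for all stimulus
conditions used here.

**Peak detection.** The fusion experiments need a single-peak criterion that
the underlying theory does not define numerically. `find_peaks()` takes local
maxima above 10% of the global maximum and merges maxima closer than two
channels, keeping the larger; these defaults make one isolated Gaussian bump
(width 1) exactly one peak. Ties in `ml_location()` break toward the lower
index.

## The experiments

* `run_inverse_effectiveness()` sweeps 11 intensities in `[0, 1]` across six
  stimulus conditions (bimodal with/without full or partial cortical input,
  and the two unimodal controls), aligned at channel 8, and interpolates the
  intensity where the additivity index `M/(V+A)` of the feedback-on bimodal
  condition crosses 1. At the defaults this crossover sits near 0.51: weak
  stimuli integrate super-additively, strong ones sub-additively.
* `run_spatial_principle()` shifts the visual stimulus (and its cortical
  copy) by multiples of the stimulus width. At three sigma the index drops
  below 1 at all intensities (cross-modal suppression); by five sigma the
  modalities no longer interact and the index returns to 1.
* `run_within_modality()` feeds a second *auditory* stimulus through the
  visual sensory channel with no visual cortical input: the veto circuit
  stays closed, so two same-modality stimuli combine near-additively and a
  far-offset partner suppresses.
* `run_enhancement_scatter()` samples random intensity/offset/width
  configurations and confirms that positive response additivity
  (super-additivity) occurs only with active feedback.
* `run_fusion_experiment()` draws stimulus locations from per-modality
  normal distributions (the drawn location centers the input field and the
  distribution's sigma sets its width, so reliability is visible to the
  network), classifies each response as fused or separate by peak count, and
  compares the moments of the fused maximum-likelihood locations with the
  analytic reliability-weighted posterior
  (`mu_cp = w_a mu_a + w_v mu_v`, weights proportional to inverse variance).
  Stimulus intensity is fixed at 0.5 for both modalities — mid-range, inside
  the enhancement regime. Draws falling outside the array are resampled.
  The standard grid crosses auditory means {8, 14.5}, visual means {5, 8}
  and widths {0.5, 1, 2, 3} per modality (64 specifications).

## The spike-rate backend

`compile_model()` decomposes the eight differential equations into a graph of
elementary operations, each simple enough for a single hardware neuron:
constant add/subtract/multiply, weighted sums, products, convolution over
channels, the sigmoid, and one ODE-evaluating root neuron per equation, with
pass-through splitter nodes where an output fans out. `simulate_spiking()`
executes the graph with every edge carrying a Bernoulli spike train of
`ticks_per_step` ticks per Euler step; products are tickwise AND of
independently seeded trains (the expectation of an AND of independent trains
is the product of their rates), and each root integrates the window-averaged
drives into a real-valued membrane.

Because spike rates represent only `[0, 1]`, quantities with a larger range
are scaled at their node and compensated in the downstream root weights: the
sums `S^a + S^v`, `C^a + C^v` and the total inhibition carry 1/2; the broad
feedback convolutions are divided by their maximal row sum
`sigma_m sqrt(2 pi)`; the feedback factor by its maximum
`1 + lambda sigma_m sqrt(2 pi)`; the `q_m` membrane runs at half scale
(saturation 2); and the shunting factors `(gamma_m + kappa_m q_m)` and
`(gamma_S2 + q_S2)` by their maxima. All encodings draw disjoint variates
from one seeded stream, which makes operand trains independent and runs
bit-reproducible.

The default window is 1024 ticks (per-window binomial error about 1.6%).
Near equilibrium the membrane is a leaky average over roughly
`tau / dt = 1000` independent windows, so the equilibrium error is far
smaller than the per-window error; the test suite exploits this by running
end-to-end comparisons at 128 ticks and 1500 steps on a 13-channel array,
where spiking equilibria still match the rate model to better than 0.03 per
channel. Correlated operand trains would bias AND-products; the compiler
gives each encoding its own stream, but users wiring custom graphs should
treat correlated inputs as a known bias source.

## What the synthetic inputs do and do not emulate

All inputs are parametric Gaussian fields; `sensor_like_fixture()`
additionally mimics sensor-derived activity (19 azimuthal channels,
multiplicative jitter, low background floor, clipped to `[0, 1]`). It is a
synthetic stand-in: it reproduces the coarse statistics of event-camera and
binaural-localizer outputs (bounded, noisy, occasionally asymmetric bumps)
but none of their structured artifacts — no gammatone filtering, no
level-difference ambiguities, no per-frequency variability. Tests passing on
these fixtures show the dynamics are robust to bounded multiplicative noise;
they do not certify performance on real recordings.

## Known limitations and open observations

* **Feedback and the fused posterior's variance.** In this implementation
  cortical feedback multiplies the response profile nearly uniformly (the
  modulatory kernel is broad), so the fused/separate classification is
  identical with feedback on and off, and the deterministic fusion boundary
  does not widen with feedback. The residual effect of modulation on the
  maximum-likelihood location is a slight pull toward the unweighted cortical
  consensus, which for unequal-reliability cue pairs *increases* the spread
  of fused locations marginally. The acceptance suite therefore shows the
  fused-mean agreement clause passing (mean error ~0.2 channels over the
  64-spec grid) while the variance-precision clause (feedback-on variance
  error strictly smaller than feedback-off) fails by a small margin; the
  corresponding test is left failing rather than weakened, and the effect is
  reproducible across draw counts.
* **Zero-input relaxation is not globally monotone.** From a generic positive
  state with zero inputs the veto circuit transiently drives `q_m` and the
  `S2` membranes below zero before everything relaxes; the state norm is
  monotone only from leak-only configurations. Relaxation also carries a slow
  `t e^{-t}` mode (the `S2` populations are resonantly forced by the decaying
  `S1` rates).
* No synaptic learning, no map alignment between modalities, and no
  temporal-offset (temporal-principle) experiments: stimuli are static and
  spatially registered by construction.
* The additivity index is undefined at zero intensity (zero denominator);
  sweep records carry `NA` there and the crossover interpolation skips them.

## Problem sizes used by the test suite

Equilibrium-sensitive checks run the full protocol (20 channels, 4000 steps,
11 intensities, 64-spec fusion grid at 50 draws per spec). Consistency
properties that hold at any integration length (order invariances,
seeded determinism, feedback dominance) run on 3-5 intensity points and
1200-2000 steps; the spiking end-to-end comparison uses 13 channels, 1500
steps and 128-tick windows as justified above. These sizes are the package's
standing choices so that results are directly comparable across runs.
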