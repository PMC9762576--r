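---
title: "Methods: population coding analysis of simulated tactile afferents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population coding analysis of simulated tactile afferents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tactilepop` implements a complete in-silico experiment on tactile
population coding: it simulates SA1, RA and PC afferent populations
responding to probe indentations, reduces the population spike trains to a
small set of non-negative spatiotemporal modules, decodes the stimulus
features from the module activations, and quantifies the resulting
information and its dependence on innervation density and on spatial versus
temporal spike-train structure. This vignette documents the model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot tell you.

## Stimuli

Each trial is a circular probe indented with a ramp-and-hold profile: a
linear ramp over `ramp_time_s` (0.01–0.05 s) up to `ramp_amplitude_mm`
(0.3–1.2 mm), a hold, and a mirrored linear ramp down at the trial end.
Once the plateau is reached, a sinusoid of frequency `frequency_hz`
(0–200 Hz) is superimposed. The full factorial design
(`build_design()`) crosses 4 probe sizes × 4 ramp amplitudes × 5 ramp
times × 10 frequencies = 800 conditions, ordered size-major,
frequency-minor.

Motor noise (`motor_noise()`) jitters, independently and uniformly on every
trial, the probe location (±0.3 mm), the sine amplitude (±0.05 mm) and the
ramp amplitude (±0.1 mm).

Several rendering constants are not dictated by the experimental design and
are package choices:

* **Trial duration 0.5 s** (`duration_s`), with the ramp-down mirroring the
  ramp-up. This leaves at least 0.4 s of hold, enough cycles for frequency
  estimation down to 10 Hz while keeping simulation cost low.
* **Base sine amplitude 0.1 mm** (`sine_amplitude_mm`), comparable in
  magnitude to its own ±0.05 mm jitter; a jittered amplitude that would go
  negative is clamped at zero and flagged (`clamped_sine`).
* **Probe "size" is the radius in mm.** Only the edge position
  `center + size/10` cm enters the model, so a diameter reading would
  amount to a relabeling of the same four levels.
* **Sine phase starts at 0** at plateau onset; depth is clipped at 0 mm.
* **Simulation step 0.1 ms** (`dt_s`), resolving 200 Hz locking (50
  samples/cycle) well below the 2-ms analysis binning.

## Afferent populations and spiking

Afferents terminate along a line radiating from the stimulation site: 1 cm
for SA1 and RA, 5 cm for PC, whose receptive fields extend much further.
Areal innervation density (1–140 afferents/cm², spanning estimates for the
human hand: palm SA1/RA/PC = 10/25/10, finger = 30/40/10, fingertip =
70/140/25, `density_presets()`) is converted to a line count through a
1-cm-wide strip, `N = round(density × line_length)`. Afferents are evenly
spaced with a seeded dither below a quarter of the spacing — the regular
backbone makes density the only systematic difference between populations,
while the dither avoids artificial lattice alignment between densities.

The spiking model is deliberately phenomenological. The drive of afferent
*i* is

$$d_i(t) = e^{-x_i/\lambda}\,\big[g_s\, z(t) + g_v\, |z'(t)| + g_a\,
z''(t)\big]_+,$$

where $z(t)$ is indentation depth, $x_i$ is the distance from the afferent
to the probe *edge* for SA1/RA and to the probe *center* for PC (making PC
insensitive to probe size by construction), and $\lambda$ is the class
receptive-field length constant. Velocity enters unsigned so that RA-type
units burst at both ramp onset and offset; acceleration enters signed and
is rectified with the rest, which produces one response lobe per vibration
cycle and hence 1:1 phase locking of PC units (an unsigned acceleration
term would lock at twice the stimulus frequency). Spikes are generated by a
leaky integrate-and-fire unit (time constant `membrane_tau_s`) whose
threshold is redrawn after every spike as
`threshold + threshold_noise_sd · N(0,1)`, with an absolute refractory
period; threshold noise is the only neural noise source, motor noise lives
entirely in the stimulus.

Class defaults (`afferent_params()`) are calibration constants chosen so
that the qualitative class signatures hold at plausible firing rates; they
are not fitted claims about real fibers:

| parameter | SA1 | RA | PC | units |
|---|---|---|---|---|
| $\lambda$ (rf length constant) | 0.15 | 0.7 | 3 | cm |
| static gain $g_s$ | 2.0 | 0 | 0 | 1/mm |
| velocity gain $g_v$ | 0.02 | 0.06 | 0 | s/mm |
| acceleration gain $g_a$ | 0 | 0 | 2.5e-4 | s²/mm |
| membrane τ | 10 | 5 | 1 | ms |
| refractory | 5 | 5 | 3 | ms |
| threshold (noise SD) | 1 (0.1) | 1 (0.1) | 1 (0.1) | — |

Two of these deserve comment. The PC refractory period is 3 ms because a
2-ms value is incommensurate with the 5-ms cycle at 200 Hz: units then
re-fire mid-cycle and their spike times walk through phase instead of
locking. The RA length constant is 0.7 cm — wide relative to SA1 —
because RA spatial acuity must be coarser than SA1's for the size code to
be SA1-led, as it is in real skin; with a sharper RA field the velocity
burst inherits an SA1-like spatial gradient.

All randomness derives from a single master seed through a hierarchical
scheme indexed by condition, trial, class, afferent and analysis stage
(`derive_seed()` internally), so any stage reruns bit-identically.

## Decomposition

Spike trains are binned into 2-ms counts, giving the matrix
$R \in \mathbb{R}^{M \times TN}$ with trials in rows and the
(time, afferent) axis flattened **afferent-major, time-minor** (column
$(n-1)T + t$); the convention is arbitrary but fixed and recorded on the
object. Non-negative matrix factorization $R = HW$ + residuals is solved
by HALS block coordinate descent on the Frobenius loss (`fit_nmf()`),
seeded uniform random initialization, max 500 iterations, relative
loss-change tolerance 1e-4 checked every 10 iterations. Explained variance
is $1 - \|R - HW\|_F^2 / \|R\|_F^2$ — a Frobenius definition, reported
alongside all results. An all-zero matrix is represented exactly by zero
coefficients and reported as explained variance 1 (documented degenerate
convention).

The module count is selected on a 25% split, stratified by the full
condition id so every condition appears in both halves: per density, K is
increased until the explained-variance gain of one more module falls below
1 percentage point (the saturation level); saturation levels are averaged
across the densities of a class and the final K per density is the minimal
K reaching that class threshold. Densities that cannot reach the threshold
are flagged and use their own saturation K. The remaining 75% is projected
onto the fixed modules by non-negative least squares (Lawson–Hanson on the
reduced normal equations; deterministic). Because the NMF initialization
is random, the whole decomposition–decoding chain is repeated over several
instantiations (50 at full scale, 5–10 at desk scale) and every information
value is reported as mean ± SD across instantiations — SD, not SEM,
everywhere.

A purely spatial control factorization (`spatial_nmf()`) factorizes
whole-trial counts into spatial modules and then projects each time bin on
them, yielding K × T coefficients per trial.

## Decoding and information

Each stimulus feature is decoded separately with a softmax multinomial
logistic model with L2 penalty (via `nnet::multinom`, a quasi-Newton
fit; the softmax parameterization is equivalent to the reference-category
formulation and makes tie handling explicit: argmax with lowest-index
tie-break). Activations are standardized per column before fitting. The
75% analysis set is split 50/50 into training and test, stratified by
condition; the inverse regularization strength C is chosen from 7
log-spaced values 1e-3…1e3 by minimal mean cross-entropy over stratified
5-fold cross-validation within the training half, and the final model is
refit on the full training half.

Information is the plugin mutual information of the test-set confusion
matrix, with $0\log 0 = 0$ and no bias correction — the decoder-confusion
construction is itself the bias-control strategy, and the result is
documented as a lower bound on the information in the population response.
Values are normalized by the stimulus entropy $H(S) = \log_2 S_n$. Note
the plugin estimator is positively biased at finite test-set size by
roughly $(S_n-1)^2 / (2 N \ln 2)$ bits; "zero information" in practice
means "at or below this bias floor", which is how the package's tests
operationalize the statement that PC populations carry no probe-size
information.

Multi-class sets are decoded from the trial-wise concatenation of the
per-class activation vectors, the only reading consistent with fitting the
NMF separately per class; the 25/75 and train/test splits are shared across
classes so no trial ever crosses from training to test between class sets.
Complementary and redundant information follow
$I_{comp} = I_{all} - I_{others}$ and
$I_{red} = I_{ref} + I_{others} - I_{all}$, which satisfy
$I_{comp} + I_{red} = I_{ref}$ exactly.

The saturation density of an information-vs-density curve is the smallest
density whose mean information reaches the top-density asymptote within a
tolerance; no tolerance being inherent to the definition, the package uses
max(SD across instantiations at the top density, 2% of H(S)).

## Perturbations

Spatial structure is destroyed by drawing one random permutation of
afferent identity per trial and applying it to all time bins of that trial
(whole afferent blocks move as units, so per-bin population counts are
conserved). Temporal structure is destroyed by shifting every spike by an
independent uniform draw in ±2, ±5 or ±10 ms *before* binning; spikes
leaving the trial window are discarded rather than reflected or wrapped,
which would inject artificial periodic structure, and refractory
violations are permitted after jittering. Perturbed responses are
projected onto the modules fitted on intact data and decoded with the
decoder trained on intact activations; small apparent information
*increases* under perturbation are estimation noise and are not
interpreted.

## Scale profiles

The full-scale conditions (800 conditions × 40 trials, 16 log-spaced
densities per class, 50 NMF instantiations) are the package defaults in
`experiment_config()` and are long-running. The test-suite and acceptance
analyses use a desk profile chosen to finish in minutes on one CPU while
preserving every qualitative contrast: per decoded feature a reduced
factorial of 8–10 conditions varying that feature (all 4 sizes × 2
frequencies for size; all 10 frequencies at fixed size for frequency),
2–3 densities spanning 3–30 afferents/cm², 20 trials per condition, 5 NMF
instantiations, and a module-count cap of 8. The vignetted numbers in the
README come from exactly these runs.

## What the synthetic data does and does not show

The simulator reproduces the qualitative response taxonomy — SA1 sustained
responses with small receptive fields and edge (size) sensitivity; RA
onset/offset and flutter responses with no static response; PC
high-frequency 1:1 phase locking, size- and depth-insensitive — and the
coding consequences that follow from it (class orderings per feature,
density saturation, the spatial-vs-temporal division of labor under
perturbation). It does **not** reproduce fitted firing-rate or
spike-timing accuracy of real afferents, 2-D hand geometry, SA2 fibers,
shear forces, moving or textured stimuli, or surface-wave propagation
between receptors. Passing tests therefore validate the *pipeline* and the
*qualitative* population-coding structure, not quantitative predictions
about human afferents; headline percentages obtained on fitted
biomechanical simulators are expected to differ numerically.

## Known limitations

* The line geometry makes "density" a count along one dimension; areal
  effects (lateral probe displacement, 2-D receptive-field overlap) are
  out of scope.
* The plugin information bound becomes loose when the activation
  representation cannot be categorically binned into as many values as
  stimuli; with very small test sets the bias floor dominates.
* HALS NMF converges to local optima; all dispersion bands reflect
  instantiation-to-instantiation variability and should be reported with
  the point estimates.
* `nnet::multinom` can fail to converge for pathological regularization
  values; the chosen-C refit surfaces its convergence flag in
  `glance()`.
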