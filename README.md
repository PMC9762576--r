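# tactilepop

Population coding analysis of simulated tactile afferents.

`tactilepop` asks how the three mechanoreceptive afferent classes of the
human glabrous skin — slowly adapting type 1 (SA1), rapidly adapting (RA)
and Pacinian (PC) fibers — jointly encode the features of a probe indented
into the skin, and how that code depends on innervation density and on the
spatial and temporal structure of the population spike trains. It is aimed
at computational neuroscientists and biostatisticians who want a fully
reproducible, end-to-end pipeline from spiking simulation to
information-theoretic summaries.

## The pipeline

1. **Stimuli.** A factorial ramp-and-hold design: probe size (1–4 mm),
   ramp amplitude (0.3–1.2 mm), ramp-up time (0.01–0.05 s) and a
   superimposed vibration (0–200 Hz), 4 × 4 × 5 × 10 = 800 conditions,
   with per-trial motor-noise jitter of probe location (±0.3 mm), sine
   amplitude (±0.05 mm) and ramp amplitude (±0.1 mm).
2. **Afferents.** Populations placed along a line radiating from the probe
   (1 cm for SA1/RA, 5 cm for PC) at innervation densities of 1–140
   afferents/cm²; a phenomenological drive model (depth, velocity and
   acceleration terms with exponential receptive-field attenuation) feeds a
   noisy-threshold leaky integrate-and-fire spike generator.
3. **Decomposition.** Spike trains are binned at 2 ms into a trials ×
   (time · afferents) matrix *R* and factorized with non-negative matrix
   factorization, *R = HW* + residuals, where the rows of *W* are
   spatiotemporal modules and *H* holds per-trial activation coefficients.
   The module count is chosen on a stratified 25% split by a
   variance-saturation rule and the remaining 75% is projected onto the
   fixed modules.
4. **Decoding.** An L2-regularized multinomial logistic decoder predicts
   each stimulus feature from the activation coefficients (stratified
   5-fold cross-validated choice of the regularization strength), yielding
   a confusion matrix on held-out trials.
5. **Information.** The plugin mutual information of the confusion matrix,
   I(S; Ŝ) = Σ p(s, ŝ) log₂ [p(s, ŝ) / (p(s) p(ŝ))], a lower bound on the
   information in the population response, normalized by the stimulus
   entropy H(S) = log₂ Sₙ. Complementary and redundant information between
   class sets follow I_comp(S, ref) = I(S, all) − I(S, others) and
   I_red(S, ref) = I(S, ref) + I(S, others) − I(S, all).
6. **Perturbations.** Spatial structure is destroyed by permuting afferent
   identity per trial; temporal structure by jittering each spike uniformly
   within ±2, ±5 or ±10 ms. Perturbed responses are projected onto the
   *original* modules and decoded with the *original* decoder, measuring
   how much information each kind of structure carries.

## Worked example

A desk-scale run: decode vibration frequency (10 levels) from all three
classes at two innervation densities, with temporal jitter perturbations.

```r
library(tactilepop)

cfg <- experiment_config(
  features = "frequency_hz",
  designs  = build_design(size_mm = 2, ramp_amplitude_mm = 0.6,
                          ramp_time_s = 0.02,
                          frequency_hz = c(0, 10, 20, 40, 60, 80, 100, 130, 160, 200)),
  classes  = c("SA1", "RA", "PC"),
  densities = c(5, 20),          # afferents per square cm
  n_trials = 20, n_instantiations = 5, K_max = 8,
  perturbations = c("spatial_shuffle", "temporal_jitter_10"),
  master_seed = 42
)
res <- run_experiment(cfg)
subset(summarize_information(res),
       density_index == 2 & perturbation == "none",
       select = c(class_set, info_mean, info_sd, norm_mean))
#>   class_set info_mean    info_sd norm_mean
#>   PC             2.98     0.0532     0.896
#>   RA             2.21     0.0952     0.666
#>   SA1            1.24     0.1120     0.373
```

PC populations recover ~0.90 of the 3.32-bit stimulus entropy at 20
afferents/cm², well above RA and SA1 — the Pacinian channel dominates
vibration-frequency coding. In the same run,
`subset(summarize_information(res), class_set == "PC" & density_index == 2)`
shows that ±10 ms spike jitter collapses PC information to 0.78 bits while
afferent shuffling leaves 2.91 bits: the PC frequency code lives in spike
timing, not in which afferent fires. `plot_info_curves(res)` and
`plot_perturbation(res)` draw these summaries.

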