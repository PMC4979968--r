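# tcdsim

Simulation and spectral analysis of stroke-induced thalamo-cortical
dysrhythmia (TCD).

After acute ischaemic stroke, resting-state EEG shows a slowed dominant
alpha peak, elevated delta/theta power with ipsi-lesional emphasis, and
broadly reduced beta power — the signature of TCD, in which hyperpolarised
thalamic neurons de-inactivate T-type calcium channels, switch from tonic
firing to low-threshold calcium-spike bursting, and entrain cortex at low
frequencies. `tcdsim` is for computational neuroscientists who want to
study whether a purely *cortical* lesion can trigger this thalamic state,
and for EEG researchers who need the matching analysis chain.

The package provides:

* **A spiking thalamo-cortical network.** Three thalamic nuclei (specific
  relay SP, non-specific NSP, reticular TRN; 100 integrate-and-fire-or-burst
  neurons each) with the membrane equation
  `C dV/dt = -g_L(V-V_L) - g_E(V-V_E) - g_I(V-V_I) - I_T`, where
  `I_T = g_T [V>V_h] h (V-E_T)` and the de-inactivation gate `h` relaxes
  between branches with time constants τh−/τh+; plus an 800E + 200I
  Izhikevich cortical sheet (`dv/dt = 0.04v² + 5v + 140 - u + I`). All 13
  projections (topographic 8-to-1 / 1-to-8, divergent probabilistic,
  one-to-one, all-to-all) with per-projection synaptic decay and
  integer-millisecond delays. The 20 s integration loop is compiled (Rcpp)
  and cross-validated against a pure-R reference stepper.
* **Lesion experiments.** Contiguous deafferentation of 30% of the cortical
  sheet at t = 10 s, a slow-onset post-lesion GABA current, 40-run cohorts
  with the pre-lesion peak-bounds omission rule, lesion-size sweeps, and
  inter-spike-interval burst statistics.
* **Spectral machinery.** Complex Morlet wavelet banks (log-spaced,
  max-value normalised), FFT convolution with squared-real-part power,
  canonical band summaries (δ 1.0–4.0, θ 4.2–7.9, α 8.3–11.9, β 12.4–30.6,
  γ 30.6–80 Hz) as mean spectral energy, and dominant-peak detection.
* **An EEG pipeline.** Butterworth 0.5–35 Hz bandpass, common-average
  reference, artifact-free 2048 ms epoching (±75 µV rule, first 45 epochs),
  electrode mirroring for left-hemisphere lesions, Wilcoxon rank-sum group
  comparisons and per-electrode difference maps.
* **A synthetic-EEG generator** (1/f background, subject-specific alpha
  rhythm, group-level band-gain and lateralisation structure, artifact
  transients) so every pipeline stage is testable without patient data.

## Worked example

```r
library(tcdsim)

# one 20 s run: healthy for 10 s, then a 30% cortical deafferentation
res  <- run_simulation(sim_config(), seed = 7)
bank <- morlet_bank(1, 80, fs = 1000)
pre  <- power_spectrum(res$lfp["CRX", 1:10000],     bank)
post <- power_spectrum(res$lfp["CRX", 10001:20000], bank)
cat(sprintf("pre-lesion peak:  %.2f Hz\npost-lesion peak: %.2f Hz\n",
            dominant_peak(pre), dominant_peak(post)))
#> pre-lesion peak:  9.35 Hz
#> post-lesion peak: 9.35 Hz

# the deafferented thalamic zone switches toward burst firing
zone <- subset(res$spikes, population == "NSP" & neuron <= 30)
isi_statistics(zone, c(10000, 20000), "NSP")$burst_fraction
#> [1] 0.27

# band-wise mean spectral energy of the post-lesion cortical LFP
round(band_mse(post, band_set(model = TRUE)), 1)
#>    delta    theta    alpha     beta    gamma
#>    257.2    727.5 307904.3  83010.6  27553.6

# synthetic patient-like EEG through the full preprocessing pipeline
rec <- generate_subject(subject_spec(f_alpha = 7.9, group = "patient"),
                        seed = 1)
sr  <- analyze_subject(rec)
sr$alpha_peak            # dominant alpha recovered from 45 clean epochs
#> [1] 7.63
round(sr$band_mse, 1)
#>    delta    theta    alpha     beta
#> 337053.4 125260.9  63411.1  27971.2
```

The first run's dominant peak sits at 9.35 Hz before the lesion (healthy
alpha, inside the 8.3–11.9 Hz control range) and stays alpha-locked after
it; the lesioned-zone non-specific nucleus shows a raised intra-burst ISI
fraction (0.27 vs ~0.01 elsewhere). The synthetic patient's 7.9 Hz alpha
is recovered at 7.63 Hz — within one bin of the logarithmic wavelet grid —
with the patient-typical delta/theta elevation and beta reduction visible
in the band summaries.

Cohort-level protocols are one call each: `run_cohort()` (40 seeded runs +
omission rule), `lesion_sweep()` (peak frequency vs lesion size),
`calibrate_cortex()` / `calibrate_gaba()` (the documented calibration
scans), and `compare_groups()` for patient-vs-control EEG statistics.

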