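# csfpulse

Quantification of cerebrospinal fluid (CSF) pulsation in the fourth
ventricle from conventional multislice EPI fMRI, for neuroimaging
researchers studying CSF dynamics and brain clearance in neurodegeneration
(e.g. Parkinson's disease cohorts followed for dementia conversion).

No dedicated flow sequence is needed: in an interleaved 2D EPI acquisition,
anatomically adjacent slices are excited a short interval apart (the
inter-slice RF interval, *interTR*, ~322 or 387 ms for a 31-slice, TR 2 s
protocol — far shorter than the volume TR), so CSF crossing between the two
slices during that interval carries a distinct saturation history. The
paired-slice signal ratio then yields a per-measurement pulsed-volume
estimate

```
CSFpulse(n) = (1/alpha - 1) * (S_i(n) / S_(i-1)(n) - 1) * ROIvolume
```

where `alpha = (1 - exp(-interTR/T1)) / (1 - exp(-TR/T1))` is the ratio of
pulsating to non-pulsated steady-state CSF signal (0.194 at T1 4300 ms,
TR 2000 ms, interTR 322 ms), `S_i(n)` is the ROI-mean intensity of slice `i`
at measurement `n`, and negatives (descending or out-of-range flow) are
clamped to zero. Per subject the pipeline reports the mean pulsed volume,
the mean absolute within-subject z-score, the positive-measurement ratio and
the CSF ROI size, and a statistics layer reproduces the cohort analyses
(pooled t-tests, Fisher exact, age residualization, bootstrap pairwise
comparisons, one-way ANOVA with Bonferroni, Pearson correlations).

The package covers the full chain:

* `acq_protocol()`, `slice_order()`, `interslice_interval()` — the vendor
  interleave (step `1 + floor(sqrt(N))`), slice-pair timing, and captured
  velocity range (0–2.48 cm/s at interTR 322 ms, 0–2.06 cm/s at 387 ms);
* `simulate_schedule()`, `calibrate_alpha()`, `pulse_response_curve()` — a
  matrix-driven Bloch simulation of the moving spin column under the full
  excitation schedule, and the saturation-ratio calibration;
* `segment_csf_roi()` — automatic intensity thresholding of the ventricular
  CSF inside a bounding box (Otsu default, percentile/fixed optional);
* `slice_signals()`, `compute_csfpulse_series()`, `summarize_series()`,
  `temporal_highpass()` — the estimator and per-subject summaries;
* `generate_phantom()`, `generate_cohort()` — synthetic 4D EPI phantoms
  with known pulsation and demographically realistic cohorts, so everything
  is testable without patient data;
* `read_manifest()`, `run_pipeline()`, `group_statistics()` — the
  manifest-driven multi-subject pipeline and the group-level battery.

All user-facing functions take data frames or plain arrays and return
tibbles (with `tidy()`/`glance()` accessors and `autoplot()` methods), so
results chain directly into dplyr/ggplot2 workflows.

## Worked example

Simulate one subject with a pulsatile (0.93 Hz, aliased by the 2 s TR)
ascending CSF flow and 2% noise, then run the per-subject pipeline:

```r
library(csfpulse)

protocol <- acq_protocol()            # TR/TE/flip 2000 ms / 30 ms / 90 deg,
                                      # 31 x 4 mm slices, 160 measurements
interslice_interval(protocol, 8)
#> # A tibble: 1 x 5
#>   lower_slice upper_slice slot_gap inter_tr_ms v_max_cm_s
#> 1           8           9        5         322       2.48

spec <- phantom_spec(protocol = acq_protocol(n_measurements = 160),
                     nx = 24, ny = 24,
                     waveform = velocity_waveform("sinusoid", v0 = 1.5,
                                                  amplitude = 3, freq_hz = 0.93),
                     noise_sd = 0.02, seed = 42)
phantom <- generate_phantom(spec)
result  <- compute_subject(phantom$image, spec$protocol,
                           lower_slice = 8, bbox = phantom_bbox(phantom))
result$summary
#> # A tibble: 1 x 11
#>   lower_slice upper_slice inter_tr_ms v_max_cm_s alpha n_voxels roi_volume_mm3
#> 1           8           9         322       2.48 0.194       13           393.
#>   n_measurements mean_pulse abs_z_mean positive_ratio
#> 1            155       56.5      0.912          0.645
```

Reading the row: the target pair (slices 8–9) is excited 322 ms apart, so
ascending CSF up to 2.48 cm/s is captured; the saturation ratio is 0.194;
13 ROI voxels give a 393 mm³ ROI; from the 155 retained measurements the
subject's mean pulsed volume is 56.5 mm³ per measurement (ground truth for
this phantom: 56.8), with 64.5% of measurements showing ascending in-range
pulsation (truth 67%). `autoplot(result$series)` draws the dynamic series;
`generate_cohort()` plus `run_pipeline()` and `group_statistics()` scale
this to a full cohort.

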