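---
title: "Measuring CSF pulsation from interleaved multislice EPI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CSF pulsation from interleaved multislice EPI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

## The measurement principle

Cerebrospinal fluid (CSF) in the ventricles moves in pulses, driven by the
cardiac and respiratory cycles, and this motion is increasingly studied as a
window on brain waste clearance in neurodegeneration. `csfpulse` quantifies
that pulsation from an ordinary resting-state fMRI acquisition — 2D
multislice echo-planar imaging (EPI) — without any dedicated flow sequence,
by exploiting the *interslice flow-saturation effect*: in an interleaved
acquisition, two anatomically adjacent slices are excited a short interval
apart (the inter-slice RF interval, "interTR", much shorter than the volume
TR), so CSF that crosses from one slice into the other between those two
pulses carries a different saturation history than CSF that stayed put. The
paired-slice signal ratio therefore encodes how much CSF moved during the
interTR.

The per-measurement pulsed-volume estimate for the target slice pair
$(i-1, i)$ in the fourth ventricle is

$$\mathrm{CSFpulse}(n) \;=\; \left(\frac{1}{\alpha} - 1\right)
\left(\frac{S_i(n)}{S_{i-1}(n)} - 1\right)\,\mathrm{ROIvolume},$$

where $S_i(n)$ is the ROI-mean CSF intensity of slice $i$ at measurement
$n$, $\alpha$ is the ratio of pulsating to non-pulsated steady-state CSF
signal, and ROIvolume converts the dimensionless exchanged fraction into a
volume. Negative values (descending or out-of-capture-range flow) are
clamped to zero; the per-subject summaries are the mean of the clamped
series (pulsation strength), the mean absolute within-subject $z$-score
(variability), and the fraction of measurements with a strictly positive raw
value (ascending-pulsation frequency).

## The excitation schedule

The vendor's interleaved ascending scheme steps through slices by
$1 + \lfloor\sqrt{N}\rfloor$: for the 31-slice protocol (step 6) the order
begins 1, 7, 13, 19, 25, 31, 2, 8, 14, 20, 26, ... Acquisition slots are
assumed uniform, $\mathrm{TR}/N$ each with no inter-packet dead time (the
scanner's actual idle time is not published; uniform slots reproduce every
printed timing value). Two numerical conventions matter and are fixed by the
printed protocol numbers:

* the interTR of a pair is `slot_gap * TR / N` **truncated** to integer
  milliseconds — truncation gives 322 ms (5 slots) and 387 ms (6 slots,
  wrapping across the TR boundary for lower slices 6–7), whereas rounding
  would print 323;
* the captured velocity bound is the two-slice span over the interTR,
  $2d/\mathrm{interTR}$, truncated to two decimals: 2.48 cm/s (322 ms) and
  2.06 cm/s (387 ms) for 4 mm slices.

```{r}
p <- acq_protocol()   # 2000/30 ms, 90 deg, 31 x 4 mm slices, 2.75 mm in-plane
slice_pairs(p, lower_slices = 6:10)
```

## The Bloch layer

`simulate_schedule()` propagates a 1-D column of spin packets along the
slice axis through the full schedule: each slice's pulse saturates the
packets inside its slab at its slot time, relaxation toward $M_0$ is applied
between events as the exact exponential operator, packets advect at constant
velocity, and fresh (fully relaxed) packets enter upstream. Assumptions:
ideal rectangular slice profiles, perfect spoiling, 90° saturation pulses
(`mz` is set to 0 in-slab), and no transverse/TE modelling — CSF
$T_2^* \gg$ TE = 30 ms and the estimator is a same-tissue ratio, so TE
factors cancel. $T_1$ of CSF defaults to 4300 ms (the literature-standard
3 T value; configurable via `tissue_params()`).

Numerical choices: nominal packet spacing 0.1 mm with a two-slice margin;
the spacing is snapped so the displacement per TR is an integer number of
packets (a commensurate grid), which makes the slab-mean readouts exactly
periodic in the steady state and lets the cycle-to-cycle convergence check
use a tight tolerance (default `1e-8`, maximum 20 cycles; convergence is in
practice reached within 3 cycles because every in-stack packet is saturated
during its first TR). Failure to converge is an error, never a silent
result. The event-driven propagation is verified in the test suite against
an independently coded fine-time-step integrator (dt = 0.25 ms) to below
1e-6, and the static limit against the closed form
$M_0(1 - e^{-\mathrm{TR}/T_1})$ to 1e-9.

Two routes to $\alpha$ are provided. The closed form

$$\alpha = \frac{1 - e^{-\mathrm{interTR}/T_1}}{1 - e^{-\mathrm{TR}/T_1}}$$

(pulsating spins last excited one interTR before readout, static spins one
TR before) gives 0.194 for T1 4300 / TR 2000 / interTR 322 and is the
default: fast, deterministic, and exactly reproducible. The
`schedule_simulation` route recomputes the same ratio from the full spin
column at the full-exchange velocity (one slice thickness per interTR) and
agrees with the closed form to better than 1%; it exists because the
original derivation of $\alpha$ is not published in full, so an independent
schedule-level reconstruction is worth keeping available.

## The sign convention and the phantom forward model

One genuinely open point deserves a frank statement. Taken literally, a
fully exchanged upper slab whose spins were saturated one interTR ago is
*darker* than static CSF ($\alpha < 1$), which would make the estimator
negative for ascending flow — yet ascending in-range flow is defined to
yield a *positive* CSFpulse, and the published group values are positive.
The full derivation that reconciles the printed estimator with the schedule
physics (inflow chains across several slice gaps, partial-voxel exchange)
is not available. `csfpulse` therefore adopts the estimator-consistent
convention for its synthetic data: the exchanged compartment of the upper
target slice carries the effective signal $S_\mathrm{static}/(1-\alpha)$, so
that an exchanged fraction $f$ scales the upper slice by
$1 + f\alpha/(1-\alpha)$ and the published estimator returns exactly
$f \times \mathrm{ROIvolume}$ for every $f \in [-1, 1]$. Generator and
estimator thus form an exact forward/inverse pair: on a noise-free phantom
the pipeline recovers the ground-truth pulsed volume to machine precision,
which is the property the validation suite (and any user of the phantom)
actually needs. The raw schedule simulator remains available for physics
exploration, and `pulse_response_curve()` — used to map cohort pulsation
targets to velocities, and to document the capture range — is computed on
the same exchanged-fraction model: zero at rest, linear in ascending
velocity up to full slab exchange at $d/\mathrm{interTR}$, flat beyond it
(the fold), and negative for descending flow.

## ROI segmentation

The fourth-ventricle CSF ROI is mapped automatically inside a user-supplied
bounding box on the temporal-mean image of each target slice (first 5
measurements excluded, as everywhere in the pipeline). The default
threshold is Otsu's criterion on the in-box histogram, refined by isodata
iteration so the final threshold sits at the midpoint between the two class
means. The refinement matters: with a small bright structure in a larger
box the classes are very unbalanced, and the raw histogram-bin optimum can
sit close enough to the background cluster that its upper noise tail leaks
into the mask. A pure percentile threshold (also available, default 90th
percentile, along with a fixed absolute threshold) was rejected as the
default because it selects a fixed *fraction* of the box rather than the
bright *structure*: it inflates or truncates the ROI whenever the ventricle
does not occupy exactly the top decile of box voxels, which breaks the
voxel-count comparisons across subjects and the phantom recovery bound.
Data-derived thresholds are exclusive (`>`), so a flat background plateau
exactly at the threshold is never selected; an empty mask is an error
instructing bbox/threshold revision, never a silent empty ROI.

ROIvolume defaults to the upper target slice's voxel count times the voxel
volume (30.25 mm³ for the study protocol), because the group differences in
the derived index are attributed in part to total ROI volume; the literal
per-voxel reading (`roi_volume_mode = "per_voxel"`) is available. One mask
is computed per slice from the same bounding box.

## Summaries and preprocessing

$S_i(n)$ is the ROI-*mean* intensity (a mean, not a sum, so ROI-size
differences between the two slices cannot bias the ratio). The $z$-scores
are computed on the clamped series — the quantity that is actually analyzed
— with the sample (n−1) SD; a zero-variance series yields a missing
$|z|$-mean with a warning. The positive ratio uses the raw (pre-clamp)
series, with ties at exactly zero counted as non-positive. Motion and
slice-timing correction are delegated to standard upstream tools; the
built-in optional high-pass (`highpass_hz = 0.01`) regresses each ROI
series on a discrete-cosine drift basis (all components below the cutoff)
and re-adds the fitted intercept, preserving the absolute scale on which
the ratio depends. For a 155-point, TR 2 s series the 0.01 Hz stopband
spans six DCT components: a linear drift is removed almost entirely while
white noise loses only ~4% of its energy.

## The synthetic cohort

`generate_phantom()` builds 4D EPI series whose ventricle (a bright tube
spanning the target slices) follows the exchanged-fraction forward model
under a programmable velocity waveform, with Gaussian noise (additive, not
Rician — only high-SNR magnitude ROIs are analyzed), optional linear drift,
and full determinism under a seed. The default waveform family includes a
cardiac-like 1 Hz sinusoid, deliberately aliased by the 2 s TR exactly as in
real sampling, with velocities evaluated at each slice's excitation instant.
Defaults mirror the study acquisition (80 × 80 × 31 voxels, 160
measurements); the test suite and acceptance script use 24 × 24 in-plane
grids (the physics is in the slice direction and the ROI covers ~13 voxels
either way) and, for unit tests, 20–60 measurements — sizes chosen as the
package's own benchmark scale. The recovery benchmark uses a constant
ascending 4 mm/s flow (0.4 cm/s, comfortably inside the 0–2.48 cm/s capture
range; exchanged fraction ≈ 0.32).

`generate_cohort()` reproduces the study's group structure — 17 healthy
controls, 16 low-dementia-risk and 19 high-risk Parkinson's patients — with
the printed age/gender/education/MMSE/duration/UPDRS distributions (gender
counts exact, continuous variables normal draws) and group pulsation targets
of 6.6 / 11.9 / 15.6 a.u. The printed dispersions are treated as standard
errors (the figure legend defines its error bars that way) and converted to
between-subject SDs via $\mathrm{SE}\sqrt{n}$. Signal-level mode draws the
derived measures directly (used for the 500-repetition type-I calibration);
image mode synthesizes per-subject phantoms whose constant velocity is the
response-curve inverse of the subject's pulsation target.

What the phantoms do *not* emulate: anatomy, k-space artefacts, motion,
physiological noise structure, partial-volume edges, or any pulsation
waveform measured in patients — the waveform family is an explicit stand-in.
Passing tests therefore demonstrate the correctness and calibration of the
*estimator and statistics*, not the clinical values of the index, which
depend on patient data that are not publicly available.

## Statistics

Group comparisons use the study's battery: pooled-variance two-sample
t-tests (Welch optional; summary-statistics input supported so printed
tables can be tested; zero pooled variance reports p = 1 for equal means
and p = 0 otherwise), Fisher's exact test for gender (zero-margin tables
degenerate to p = 1 with a warning), pooled OLS age-residualization
(residual plus grand mean, preserving the pooled mean exactly), a
percentile bootstrap of pairwise mean differences (B ≥ 1000 enforced,
default 10,000, mandatory seed), one-way ANOVA with Bonferroni-multiplied
pairwise t-tests, and Pearson correlations. The original description calls
the group analysis a "two-way" ANOVA although only one factor (group)
varies; it is implemented as one-way across the three groups, with the
discrepancy noted here. Type-I calibration on null signal-level cohorts at
the study's sample sizes keeps the omnibus test's rejection rate within
[0.025, 0.075] at a nominal 0.05 over 500 seeded repetitions.

## Known limitations

* The $\alpha$ closed form is a reconstruction of an incompletely published
  derivation; its provenance is recorded in every calibration object, and
  the schedule-simulation route bounds the reconstruction error at the
  protocol's operating point (<1%).
* The estimator's sign convention is enforced by construction in the
  synthetic data (see above); conclusions about real-data sign behaviour
  require the original acquisition.
* Piecewise-constant velocity per interval: intra-interTR acceleration is
  not modelled.
* Printed headline group values (6.6 / 11.9 / 15.6 a.u.) are emulated, not
  reproduced, since the patient images are unavailable.
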