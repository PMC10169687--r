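---
title: "Spatial correlation of infraslow EEG amplitude fluctuations: methods and design"
author: "eegpsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial correlation of infraslow EEG amplitude fluctuations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantity being estimated

Band-limited EEG oscillations (theta 3–7 Hz, alpha 8–12 Hz, beta 17–25 Hz)
have slowly varying amplitude envelopes. During rest, those envelopes
fluctuate mainly at infraslow frequencies (0.05–0.1 Hz), and the infraslow
fluctuations are correlated across distant scalp sites. `eegpsi` quantifies
that long-range spatial correlation with an instantaneous phase-difference
statistic rather than a windowed correlation coefficient, so the quantity
exists at every time point:

1. band-pass the EEG into a carrier band, take the Hilbert envelope;
2. band-pass the envelope into the infraslow (or, for comparison, the slow
   0.1–1 Hz) band and take the Hilbert phase, giving per-channel phase
   series $\theta_c(t)$;
3. for a channel pair, wrap the absolute phase difference into $[0, \pi]$
   and map it linearly onto $[1, 0]$:
   $\psi_t = 1 - \Delta(t)/\pi$, with
   $\Delta(t) = \min(|\theta_1 - \theta_2| \bmod 2\pi,\; 2\pi - |\theta_1 - \theta_2| \bmod 2\pi)$.
   Identical phases give $\psi_t = 1$, antiphase gives $0$;
4. summarise each task condition (eyes closed / eyes open) by the median,
   $M_\psi = \mathrm{median}\{\psi_t : t \in \text{condition}\}$, over the
   filter-valid samples. Medians of even-length samples use the midpoint of
   the central pair.

$\psi_t$ is symmetric in its arguments, invariant under a common phase
offset, and for independent uniformly distributed phases its median
converges to $0.5$ — the null value used throughout the tests.

The printed form of the statistic's defining equation in our source material
is typographically corrupted; the implementation pins the function by its
stated boundary conditions (zero difference $\to 1$, maximal difference
$\to 0$) and linearity in between, which determines it uniquely.

## Group screen and discrimination

Per participant, $M_\psi$ is computed for every cross-region channel pair of
an 8-region parcellation (left/right frontal, temporal, parietal,
occipital; 9/9/3/3/7/7/4/4 channels; 28 region pairs; the montage has 60
channels and 1770 channel pairs in total). For a contrast (experimental
vs control group), every channel pair is tested with a one-tailed Wilcoxon
rank-sum test in both directions; Benjamini–Hochberg FDR at $q = 0.05$ is
applied within each (region pair × band × condition × direction) family, and
cells are ranked by their significant-pair fraction. The winning cell (ties:
smaller minimum uncorrected p) and its minimum-p channel pair define the
biomarker. A subject is then discriminated by the leave-one-subject-out
median-closeness rule: recompute both group medians without the test
subject and assign the closer one; accuracy, sensitivity and specificity
come from the resulting confusion matrix. Chance level is 0.5.

Choices the source material left open, fixed here:

* **FDR family.** FDR is controlled within each region pair's channel-pair
  family (matching how significant fractions are reported per region pair);
  a global family is available via `region_pair_screen(family = "global")`.
  BH was chosen over BY as the field default step-up procedure.
* **Exactness of the rank-sum test.** Exact enumeration p-values when the
  smaller sample has ≤ 8 observations and no ties; otherwise the normal
  approximation with tie and continuity corrections.
* **Distance ties in LOSO.** Assigned to the non-target group
  (conservative); `tie_break = "target"` inverts this. Real-valued data
  make ties measure-zero, so the choice is inert in practice.

## Signal chain details

* **Edge trimming.** The first and last 10 s of each recording are removed
  (start/end artifacts), with condition intervals shifted accordingly.
* **FIR design.** Hamming-window linear-phase band-pass of order
  $7\lfloor f_s / f_{lo}\rfloor$ with normalised cutoffs $2f/f_s$ (1163
  taps for theta at 500 Hz), applied forward–backward (zero phase, squared
  magnitude response) over mirror-padded edges
  (`min(3 * n_taps, n - 1)` samples). The mirror padding is capped rather
  than enforced as a hard length requirement: at practical recording
  lengths the infraslow filter would otherwise be inapplicable; signals
  must still be longer than the filter itself.
* **Envelope rate reduction.** The infraslow filter at 500 Hz would need
  70001 taps, longer than any realistic resting recording, so envelopes are
  decimated (anti-aliased: cascaded-boxcar predecimation with nulls on the
  aliasing bands, then a Hamming FIR at 0.2 × the target rate) to 10 Hz
  before envelope-band filtering; the design rule is re-applied at the
  decimated rate (1401 taps for infraslow, 701 for slow). Content below
  1 Hz is unaffected. Internally the carrier band-pass and Hilbert
  transform are fused in the frequency domain, and the analytic signal is
  frequency-domain decimated to the smallest usable rate — numerically
  equivalent to the primitive operations composed, at a fraction of the
  cost.
* **Envelope demeaning.** The envelope's mean is subtracted before
  envelope-band filtering; the band-passed fluctuation is zero-mean up to
  the finite-window residual of a ~0.07 Hz oscillation (about 0.5 % of its
  s.d. over 600 s — no finite filter can beat that bound, which is why the
  tests assert DC rejection of the operator plus a 2 % window bound rather
  than exact zero).
* **Validity masks.** After each filtering stage, half a filter length at
  both ends is marked invalid and excluded from $M_\psi$ (the source
  material states no exclusion rule; this is our decision). Samples whose
  fluctuation amplitude falls below 1 % of the interior s.d. (floored at
  0.1 % of the envelope's mean level, so constant envelopes are flagged)
  carry a `low_amp` flag; they remain in the median but support
  sensitivity analyses.
* **Surface Laplacian.** Spherical-spline current source density
  (`m = 4`, `λ = 1e-5`, 50 Legendre terms; the λ exponent is read as
  $10^{-5}$), precomputed as a single channel-transform matrix on the unit
  sphere without head-radius rescaling — the scale cancels in phase-based
  statistics. Sign convention: a local potential maximum maps to positive
  CSD. A constant potential maps to ~0; a low-degree spherical-harmonic
  pattern is reproduced with cosine similarity > 0.99 and matches an
  independent dense-solve oracle.
* **Montage.** Standard 10-10 positions built geometrically (midline and
  outer-ring arcs, slerp for intermediate rows), nose along +y. The
  conventional left-frontal region listing duplicates F8 (a right-frontal
  channel); we substitute F3, restoring left/right symmetry and region
  disjointness (`standard_montage(frontal_fix = FALSE)` keeps the
  duplicated listing). The union of the 8 regions covers 46 of the 60
  channels.
* **Spectral QC.** `band_peak_check` compares mean spectral magnitude at a
  band's central integer frequencies against its peripheral ones (theta
  4–5 vs 3, 6–7 Hz; alpha 9–11 vs 8, 12 Hz; beta 20–22 vs 17–19,
  23–25 Hz), with strict inequality (a flat spectrum fails).

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground-truth test
bed. Per channel it synthesises

$$x_c(t) = \sum_b A_b\,[1 + m \cos(\eta_{cb}(t))]\,\cos(2\pi f_b t + \varphi_{cb}) + s\,n_c(t)$$

with $f_b$ the band centre, $\varphi_{cb}$ i.i.d. uniform carrier phases and
$n_c$ 1/f noise (spectrally shaped white noise, unit variance, scale
$s = 0.5$). The envelope phase $\eta_{cb}$ is a shared per-band latent
infraslow phase (frequency 0.07 Hz plus a slow common drift) plus a
per-channel offset following a wrapped Ornstein–Uhlenbeck process whose
stationary law is von Mises$(0, \kappa)$: $\kappa = 0$ is a free phase
random walk (independent channels), large $\kappa$ is phase locking.
$\kappa$ is the single coupling knob, assigned per (channel set, band,
condition) by coupling rules over a weak global baseline
($\kappa_{base} = 1$). The coupling model is our choice — the source
material states none — selected because it maps directly onto the
phase-difference definition of $\psi$.

Calibration, fixed once:

* modulation depth 0.5; envelope frequency 0.07 Hz (mid-infraslow);
* phase jitter 0.2236 rad/\sqrt{s}: the offset relaxation time
  $2/(\kappa\sigma^2)$ is 4 s at $\kappa = 10$, and at $\kappa = 0$ a pair
  difference wanders ~1 rad per 20 s, so uncoupled pairs decorrelate well
  within a recording while coupled channels re-lock within seconds of a
  condition change. Faster-than-envelope offset dynamics are deliberate:
  with slower jitter, coupling states carry across condition blocks and
  condition-specific deficits cannot be expressed;
* `generate_recording` defaults to 6 × 30 s alternating eyes-closed/open
  segments (~90 s per condition, matching the motivating dataset's
  per-condition means); cohort recordings use 4 × 90 s segments (360 s,
  comparable to that dataset's ~326 s mean session) because condition
  blocks must be long relative to the infraslow filter's ~±35 s temporal
  support for planted deficits to remain condition-specific after
  filtering;
* the canonical cohort (`default_cohort_config`): controls couple the left
  frontal + left temporal regions in theta ($\kappa = 10$, both
  conditions) and the occipital regions plus midline POZ/OZ in alpha; the
  cMDD group loses the fronto-temporal theta coupling during eyes closed
  ($\kappa = 0$), the pMDD group the inter-occipital alpha coupling during
  eyes open. BDI scores are sampled uniformly within each group's range
  (Control 0–7, depressive groups 13–40).

**What the generator does not emulate.** No volume conduction (each channel
is an independent oscillator; a forward model is out of scope), no eye
blinks or muscle artifacts, no non-stationarity beyond the condition
schedule, no realistic cross-frequency structure. Two consequences matter.
First, passing tests on synthetic cohorts demonstrate that the analysis
chain recovers envelope-phase coupling structure of the assumed form — not
that real depression cohorts carry such structure. Second, synthetic
pipeline runs are executed **without** the surface Laplacian: applying a
volume-conduction-removal operator to volume-conduction-free signals only
mixes independent channels — with i.i.d. carrier phases, the spatial
mixing sums random phasors, and subjects who draw near-cancellation at a
channel lose the envelope into the noise floor, inflating between-subject
variance at coupled pairs. The Laplacian is instead validated
against analytic oracles (constant input, spherical-harmonic
eigenpatterns, a dense-solve reference) and stays in the default path for
real recordings.

## Problem sizes used in the validation suite

Statistical properties are checked at sizes where their expected behaviour
is unambiguous: null $M_\psi$ on 20 seeded 600 s two-channel recordings;
infraslow-vs-slow dominance on a 600 s ten-channel coupled recording;
$\kappa$-monotonicity over $\kappa \in \{0, 1, 5, 20\}$; parameter recovery
on a 30-participant cohort (10 Control, 10 cMDD, 10 pMDD, 360 s each) with
both planted deficits screened across 2 bands × 2 conditions × 28 region
pairs; LOSO chance level on 50 replicates of 20 + 20 null subjects. The
exact rank-sum and BH implementations are compared against brute-force
enumeration oracles at small n, where enumeration is feasible.

## Known limitations

* The per-channel-oscillator generator cannot exercise the surface
  Laplacian meaningfully (see above); a dipolar forward model would be the
  natural extension.
* Region-pair coupling in the generator is transitive (scalar phases):
  deficits are planted by decoupling region groups, not arbitrary pair
  patterns.
* The EDF reader is not included; recordings arrive via the internal
  tabular format (or any converter producing it).
* $M_\psi$ on short conditions (< a few envelope cycles of valid samples)
  is noisy; the per-pair `n_samples` column makes this visible.
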