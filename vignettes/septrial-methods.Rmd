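---
title: "Simulating and quantifying single-trial median-nerve SEPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying single-trial median-nerve SEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septrial)
```

## The problem

Median-nerve somatosensory evoked potentials (SEPs) recorded with scalp EEG
are conventionally averaged over hundreds of stimuli because the single-trial
signal-to-noise ratio is poor. Closed-loop applications — operant
conditioning of sensory responses, SEP-based brain-computer interfaces —
need the opposite: a response that is separable from background on *every
trial*, with minimal post-processing. A protocol that helps get there
combines long stimulus pulses (0.5–1 ms instead of the conventional
0.1–0.2 ms), slow jittered stimulation (mean 0.5 Hz, inter-stimulus
intervals uniform on 1.8–2.2 s), and an intensity chosen not by subjective
thresholds but by objective peripheral markers: the sensory nerve action
potential (SNAP) recorded at the digit and the compound muscle action
potential (CMAP) at the abductor pollicis brevis. The same markers are then
monitored during the run to hold the *effective afferent excitation* — not
merely the delivered current — constant.

`septrial` implements that methodology end to end as testable code: a seeded
generator of complete synthetic sessions, the peripheral (SNAP/CMAP)
analysis chain, the EEG preprocessing and averaged-SEP chain, the
single-trial feature path, and the statistics battery used to quantify
robustness and reliability. Because no public recordings of this protocol
exist, the synthetic generator *is* the study population: every calibration
below is a property of the generator, stated openly, and the tests
demonstrate internal consistency of the pipeline — not claims about any
particular human dataset.

## The synthetic session model

### Strength–duration thresholds and recruitment

Peripheral excitability follows the Weiss strength–duration law: the
threshold current for a rectangular pulse of width $t$ is

$$I_{thr}(t) = b\,\bigl(1 + c/t\bigr),$$

with rheobase $b$ (mA) and chronaxie $c$ (ms). `weiss_threshold()` implements
this; `calibrate_subject()` solves it in the linear charge form
$Q = I\,t = b\,(t + c)$ by least squares through supplied
(pulse width, intensity) pairs. The default calibration targets are group
mean target intensities of 24.2, 9.5 and 8.3 mA at 0.1, 0.5 and 1 ms. The
two long-pulse pairs give $b = 7.1$ mA, $c = 0.169$ ms; the 0.1 ms target is
*not* consistent with that two-parameter law (it would predict ≈19 mA), so
calibrated subjects store a per-pulse-width threshold map directly and keep
the fitted Weiss parameters only for interpolation, reporting the residual
rather than hiding it.

Response amplitude recruits sigmoidally with intensity:

$$A(I) = \frac{A_{\max}}{1 + e^{-(I - I_{50})/s}}, \qquad I_{50} = I_{thr} + 2s,$$

with slope $s = 0.5$ mA. Placing the half-activation point two sigmoid
scales above the threshold puts the "first detectable" response (~12 % of
maximum) at the calibrated threshold intensity, which is what makes the
detection rule below land on the calibrated values.

### EMG trials

Each trial produces two channels on a $[-50, 50)$ ms epoch grid at 3200 Hz:
a digit channel carrying the SNAP (a Gaussian-windowed 250 Hz biphasic
wavelet, σ = 0.8 ms) and a thenar channel carrying the CMAP (150 Hz,
σ = 1.5 ms). Peak latencies of 3.8 and 6.0 ms are snapped to the sample grid
(3.75 and 5.94 ms) and recorded as truth, so noiseless recovery is exact.
Both channels carry a brief high-frequency stimulus artifact at $t \approx
0.4$ ms whose amplitude scales with current, plus Gaussian background
(SD 5 a.u.) shaped by the emulated 10–1000 Hz acquisition band, plus small
quantization-scale noise. Trial-to-trial amplitude variability is
multiplicative with CV 0.10.

### EEG sessions

A session is a continuous 19-channel, 300 Hz record. Background per channel
is $1/f$ noise (power exponent 1, flattened below 0.5 Hz), a 10 Hz alpha
sinusoid and a 60 Hz line component (each at half the background SD), scaled
by `eeg_noise_sd`. For every stimulus, a positive P50 (Gaussian kernel,
σ = 10 ms, latency 44.2 ms) and negative N70 (σ = 12 ms, 80.6 ms) are added
to the contralateral central channel (C4 for left-hand stimulation) with
weight 1, to its Hjorth neighbors with weight 0.35, and 0.05 elsewhere.
Per-condition mean amplitudes follow the calibration table
(P50: 46.4/49.3/55.4; N70: −39.0/−55.1/−66.9 a.u. at 0.1/0.5/1 ms); trial
amplitudes vary with CV 0.10 and latencies jitter with SD 3 ms (snapped to
the grid and recorded). The `impaired` profile halves the N70 and moves its
spatial focus to the parietal channel (P4/P3), leaving the P50 at the
central site.

Seeding is hierarchical: one master seed; per-subject, per-session and
per-trial streams are derived by fixed integer splitting, so subject $k$ is
bit-identical regardless of cohort size.

### Calibration of the noise scales

Two generator constants were fixed once, by simulation, and are not tuned
thereafter:

* `emg_noise_sd = 5`. The detection rule declares a SNAP discernable when
  its peak exceeds the background median + 3 SD of the rectified
  pre-stimulus pool. The noise scale is chosen so that this criterion
  crosses the recruitment sigmoid at the calibrated threshold intensity;
  at that value, simulated cohorts recover their calibrated targets within
  one 0.5 mA recruitment step across master seeds.
* `eeg_noise_sd = 45`. Chosen so that the default cohort's single-trial N70
  ROC AUC sits in the 0.75–0.85 range across conditions
  (≈0.79/0.80/0.84 at 0.1/0.5/1 ms in 24-subject simulations), the
  magnitude regime the methodology is designed for. This is a calibration
  of the generator, not an empirical claim.

## The analysis pipeline

### Peripheral chain

EMG epochs are band-pass filtered 100–300 Hz with a second-order Butterworth
prototype applied forward–backward (zero phase, reflection-padded edges).
The stimulation-artifact interval $[0, 1.5)$ ms is blanked by linear
interpolation *before* filtering — a broadband artifact otherwise rings
through the pass band into the SNAP window. Background is the median of the
rectified $[-50, -15)$ ms pool (SD on the same pool; a per-trial variant is
available). Peak responses are signed window maxima — not peak-to-peak —
in investigator-set windows, defaulting to $[2, 8)$ ms for the SNAP and
$[3, 15)$ ms for the CMAP, bracketing the 3.8/6.0 ms latencies. Recruitment
curves average blocks of four trials per 0.5 mA step; the target intensity
is the smallest level whose SNAP exceeds background median + 3 SD in at
least 3 of 4 trials with a discernable CMAP (same rule) at the same level.
The CMAP criterion reuses the SNAP rule because no separate one is defined
for it.

During assessment runs, `monitor_assessment()` holds the CMAP within ±20 %
of its target: after two consecutive out-of-band trials deviating in the
same direction it steps the intensity by 0.1 mA and then leaves it until
another change is required. The trigger count and direction logic are not
prescribed anywhere; two consecutive trials was chosen as the smallest
stable debounce and is logged explicitly. The delivered intensity never
exceeds the subject's discomfort limit.

### Cortical chain

EEG preprocessing is 55–65 Hz band-stop then 2–40 Hz band-pass, each a
second-order Butterworth applied forward–backward ("order 2" read as the
prototype order; the effective order is 4). Spatial filtering is the Hjorth
surface Laplacian — channel minus the mean of its nearest 10–20 neighbors,
from a fixed montage table (C4: F4, P4, Cz, T8; falls back to the remaining
neighbors when one is rejected, errors below two). Epochs span $[-50, 300)$
ms with per-trial baseline correction over $[-50, 0)$ ms. All windows are
half-open in ms and converted to samples by `floor(t * fs / 1000)`, so
25–65 ms is exactly 12 samples at 300 Hz and every count is reproducible
bit-exactly.

The averaged path masks outlier trials (peak-to-peak or RMS beyond
median + 3 × 1.4826 MAD on the analysis channel) and measures P50 as the
maximum in $[25, 65)$ ms and N70 as the minimum in $[55, 95)$ ms, earliest
sample on ties. The same windows serve both the averaged and single-trial
paths, since the printed latencies fall inside them.

The single-trial path deliberately applies *no* trial rejection — it mimics
what a real-time system can do — and reduces each trial to three RMS
features: the P50 window, the N70 window and the $[-50, 0)$ ms background.
Separability is the ROC AUC of component versus background features,
computed by the rank (Mann–Whitney) formulation with explicit half-credit
for ties; it is exact, $O(n \log n)$, and invariant to monotone transforms.
Background epochs are drawn one per trial and compared unpaired.

One numerical subtlety is worth stating because it changed a default:
computing *energy* features on baseline-corrected epochs biases every
channel's response-vs-background comparison upward, because the correction
centers the very window the background feature is computed from while
leaving post-stimulus windows free to drift in autocorrelated noise. In our
simulations this inflated the r² topography floor from ~0.01 to ~0.19 on
signal-free channels. `topography_r2()` therefore documents that it should
be fed epochs built with `baseline = NULL`, and its default per-trial
measure is the window peak magnitude, matching peak-based topography maps;
the single-trial AUC path keeps the baseline-corrected convention of the
protocol it mimics. Topographic maps are interpreted at the group level
(averaged across subjects) where the contralateral focus is stable;
single-session maps at this SNR are noisy, and the package's tests respect
that distinction.

## The statistics battery

All standard deviations are sample (n − 1) SDs. SNR of a set of per-trial
peaks is |mean|/SD; the coefficient of variation is SD/mean.

* **Friedman test** (`friedman_rm`): within-subject mid-ranks,
  tie-corrected χ²; *exact* p for n ≤ 5, k = 3 by enumerating all within-row
  rank permutations (6ⁿ ≤ 7776 configurations), χ²(k−1) reference above
  that. At n = 12, k = 3 the χ² reference has exact size 0.058 at α = 0.05
  (computed from the full tie-free null distribution); an exact-p test at
  that design would be conservative (size 0.038) because of discreteness,
  which is why the asymptotic reference is kept beyond the enumeration
  cutoff.
* **Kendall's w** (`kendalls_w`): χ²/(n(k−1)), clipped to [0, 1].
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): zeros dropped,
  mid-ranks of |d|; exact two-sided p for n ≤ 25 via the tie-aware
  convolution of the positive-rank-sum distribution (equivalent to full
  sign-pattern enumeration), normal approximation with tie-corrected
  variance above, no continuity correction.
* **Holm correction** (`holm_adjust`): delegated to `stats::p.adjust`.
* **Lilliefors normality** (`lilliefors`): delegated to
  `nortest::lillie.test`, the field-standard implementation.
* **ICC(2,1)** (`icc_a1`): single-measure absolute-agreement intraclass
  correlation from the two-way ANOVA decomposition,
  $(MS_R - MS_E)/(MS_R + (k{-}1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$ — the
  estimator that matches both the "two-way mixed" and "ICC(2,1)" labels in
  common use — with McGraw–Wong F-based 95 % confidence intervals, an
  F-test p-value, and the usual interpretation bands (<0.5 poor, 0.5–0.75
  moderate, 0.75–0.9 good, >0.9 excellent). Degenerate inputs (zero residual
  error) return ICC 1 or a reported non-positive value, never a silent clamp.

## Orchestration

`run_study()` drives the whole design: sample a cohort
(`sample_cohort`, between-subject CV 0.10 on thresholds and amplitudes,
every fourth subject right-hand stimulated), and for each subject × session
× pulse width: simulate a recruitment run, detect the target intensity,
run the maintenance controller over a simulated assessment run, synthesize
and analyze the EEG session, and collect per-run rows. Group tables mirror
the study structure: target intensities with CV, normalization by each
subject's 1 ms intensity, and per-pulse charge; P50/N70 amplitudes and
latencies; a 4-measure × 3-condition ICC grid across two sessions; the
per-condition AUC table; and Friedman + Wilcoxon–Holm + Kendall's w over
conditions (N70 compared in magnitude). Session-to-session amplitude
variability is multiplicative with CV 0.06, chosen so that test-retest ICCs
fall in the moderate-to-good band reported for this class of measurements.
A failed subject-condition is logged and skipped, never silently imputed.

```{r, eval = FALSE}
report <- run_study(study_config(n_subjects = 12, n_sessions = 2, seed = 7))
print(report)
```

Sessions can be serialized to delimited text (`write_session` /
`read_session`) — EEG samples, event log and generator truth as TSV tables.
No binary formats are used anywhere.

## Problem sizes and reproducibility

The shipped tests run cohorts of 3–12 subjects with 12–70 trials per
session — sizes chosen so the full suite exercises every stage, including a
ten-master-seed replication of the group-level N70 analyses, in a few
minutes on one core. All stochastic stages take explicit integer seeds;
repeated runs are bit-identical, and `scripts/acceptance.R` recomputes the
package's headline quantities from scratch at any seed.

## Known limitations

* Components are monophasic Gaussian bumps; real SEPs have multiphasic
  morphology, and component overlap is only as rich as two kernels allow.
  Any smooth unimodal kernel would do; Gaussians keep peak/RMS relations
  analytic.
* There is no volume-conduction head model — spatial structure is a fixed
  three-level weight profile — and no habituation, gating, or attention
  dynamics; ISI effects beyond jitter are not modelled.
* No biophysical membrane model stands behind the Weiss law; it is a
  phenomenological threshold model, which is all the methodology requires.
* EDF I/O is not provided (no EDF reader exists in the supported dependency
  set); external exchange uses delimited text.
* Passing tests demonstrate that the analysis recovers what the generator
  embeds under these assumptions — they cannot certify performance on real
  recordings, where noise is nonstationary and artifacts are structured.
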