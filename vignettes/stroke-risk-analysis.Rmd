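---
title: "Stroke-risk screening of Holter hour-snips: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroke-risk screening of Holter hour-snips: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Paroxysmal atrial fibrillation (pAF) terminates spontaneously, often within
hours, and most episodes are asymptomatic. A routine 24-hour Holter
recording therefore documents fibrillation only when an episode happens to
fall inside the recording window — in the validation cohort this package
ships fixtures for, barely a quarter of patients with confirmed pAF showed
manifest AF during a full recording, and fewer than a fifth during its
first hour. Since untreated AF carries a five-fold stroke risk that
anticoagulation largely removes, every missed diagnosis matters.

The stroke-risk-analysis (SRA) approach exploits the observation that heart
rate *dynamics* change with the onset of an AF episode and remain altered
for some time after it ends. A 1-hour snip of RR intervals that contains no
fibrillation can then still be flagged as "at risk", from the residue the
last episode left in the rhythm. This package implements the full method:
beat detection, the nonlinear RR feature set, a seedable classifier with
the four-way readout (`NOT_ANALYZABLE`, `NO_RISK`, `PAF_RISK`, `AF`), the
hour-snip segmentation convention, patient-level aggregation, and the
diagnostic-accuracy evaluation — together with a synthetic Holter generator
that provides annotated ground truth for every stage.

## Beat detection and morphology

QRS detection runs per lead: 5–25 Hz Butterworth band-pass, squared
derivative, 120 ms moving integration, adaptive signal/noise thresholds
with a 200 ms refractory period. On records with more than one lead the
two best leads are used and their detections fused (kept when seen on
either lead, merged within 100 ms). Lead quality is the agreement rate
between two *independent* single-lead detectors (the energy detector and a
simple amplitude-threshold picker) per 10-second window; windows whose
detection count is physiologically implausible score zero, which is what
rejects a pure-noise lead — both detectors fire on noise, but at the
refractory-limited rate, not a cardiac one. Saturated or flat windows are
marked artifact; beats inside them are labeled `X` and the clean-signal
fraction drops accordingly.

Beat morphology (width at quarter-amplitude, amplitude, correlation with
the pointwise-median normal-beat template over a −150…+300 ms window) feeds
the normal/ventricular split: a beat is `V` when wider than 120 ms or
correlating below 0.8 with the template. Both thresholds are conventional
and configurable (`sra_config()`). A template needs 30 beats; shorter
fragments are wholly labeled `X`. Atrial prematurity is deliberately *not*
a morphology decision — narrow premature beats are typed later from timing
alone.

## The RR feature set

All NN-based features exclude intervals adjacent to `V` or `X` beats.

**Poincaré SD1/SD2.** The population (1/N) covariance of the lagged pairs
(R~i~, R~i+1~) is eigendecomposed. Axes are assigned by *orientation*, not
eigenvalue rank: SD1 belongs to the axis closer to the (1, −1) direction
(perpendicular to the line of identity), SD2 to the identity axis. For an
alternating rhythm the perpendicular dispersion exceeds the longitudinal
one, and rank-based assignment would silently swap the semantics. When the
two marginal variances are equal this reduces exactly to the familiar
closed forms SD1² = Var((R~i~ − R~i+1~)/√2), SD2² = Var((R~i~ + R~i+1~)/√2);
for finite stationary series the closed form agrees to a few percent, and
the test suite checks both this approximation and exact agreement with an
independent closed-form eigenvalue oracle. `SD1/SD2` is reported as `Inf`
when SD2 = 0 (a constant or strictly patterned series), never silently
clipped — the classifier caps it at 10 on entry.

**Normalized RR differences.** d~i~ = (R~i~ − R~i+1~)/(R~i~ + R~i+1~),
summarized by mean, sample SD (`dnorm_sd`) and the 95th percentile of |d|.
Division by the pair sum (twice the pair mean) makes the statistic
heart-rate independent and algebraically bounded in (−1, 1). `dnorm_sd` is
the single strongest AF marker in the set: about 0.02 in sinus rhythm
versus about 0.14 in generated AF.

**Extreme-window ratio.** Among contiguous runs of NN intervals, the
window of six consecutive intervals with the largest sum is located (ties:
earliest); the ratio of its shortest to longest member is returned. The
"six largest consecutive intervals" phrase admits a second reading — the
six individually largest values that happen to be adjacent — which is
rarely satisfiable and non-deterministic under ties; the max-sum-window
reading is deterministic, always defined on long enough series, and is
checked against exhaustive search.

**PAC census.** A narrow-QRS beat with coupling interval CI < 0.85 × NN
(NN = median of the 10 nearest NN intervals, excluding the coupling and
pause intervals themselves) is a premature atrial complex. With pause P,
the type is:

| type | rule |
|---|---|
| `INTERPOLATED` | \|CI+P − NN\| < 0.10·NN |
| `FULL_COMPENSATORY` | \|CI+P − 2NN\| < 0.10·2NN |
| `DELAYED_RESET` | P > 1.15·NN and CI+P < 0.90·2NN |
| `SINUS_RESET` | otherwise |

Tolerances are strict inequalities, so a value exactly on the ±10% band
edge falls through to `SINUS_RESET` — the conservative default, since only
non-reset types are *countable* and feed the risk score. The beat that
resumes sinus rhythm after an interpolated PAC is itself premature against
the local cycle; the census skips a beat whose preceding interval is an
already-identified PAC's pause, so one ectopic event is counted once.

**Approximate entropy.** Classic ApEn(m, r): Chebyshev distance,
self-matches included, m = 2, r = 0.2 × sample SD of the series, zero by
convention for zero-variance input. The O(N²) kernel is implemented in
C++ (an hour snip holds ~4500 intervals); a naive R double-loop oracle in
the test suite pins the implementation to 1e-10.

Every feature whose precondition fails (too few usable intervals: 3 pairs
for Poincaré, 6 in a run for the extreme window, 50 for ApEn) is carried as
an explicit `NA`, and a missing core feature is an analyzability failure
downstream — never a silent zero.

## Classifier

The vendor's production classifier is an undisclosed neural-network
ensemble; this package substitutes a transparent, seedable margin
classifier in the same spirit as the SVM stage the method describes:
one-vs-rest linear support-vector machines (`e1071`, cost 1) over the
standardized feature vector (SD1, SD2, capped SD1/SD2, `dnorm_sd`,
`dnorm_p95`, extreme-window ratio, countable-PAC rate per hour, ApEn).
Design choices that matter:

* **Order-invariant training.** Rows are sorted into a canonical order
  (label, then feature values) before fitting, so permuting the input
  yields bit-identical models.
* **Serialization.** A model is fully described by per-class weight
  vectors, intercepts and standardization constants; it round-trips
  through JSON (full precision) with bit-identical predictions.
* **Regularity guard.** A snip is only called `AF` when its ApEn also
  exceeds 0.5: strictly patterned rhythms such as bigeminy produce large
  `dnorm_sd` and can win the AF margin, but their entropy is near zero.
  A dependency-free rule mode (`af_mode = "rule"`: `dnorm_sd` > 0.06 and
  ApEn > 0.5) is available for operation without a trained model.
* **Precedence.** `NOT_ANALYZABLE` (gate) > `AF` > `PAF_RISK` > `NO_RISK`;
  classification is a pure function of (features, model, config).

The packaged default model (`sra_default_model()`, version 1, seed 42) is
trained on 100 one-hour snips per class from the generator: healthy sinus
(heart rate and SDNN jittered across snips), sinus with the risk signature
fully expressed, and AF with burden 0.2–1 — partial-burden snips are
included deliberately so that episode-boundary snips sit on the AF side of
the surface. Training takes minutes and is reproduced exactly by
`scripts/train-default-model.R`.

The analyzability gate defaults mirror screening practice: at least 1800
NN intervals per snip, at most 20% artifact, at most 30 ventricular beats
per hour (the threshold above which frequent ventricular ectopy was an
exclusion criterion in the validation study).

## Hour-snip segmentation

Holter analysis software defines the "first hour" as running from the
start of recording to the next full clock hour — snip 0 is therefore at
most (and almost always less than) 60 minutes. Subsequent snips are full
clock hours and the trailing incomplete hour is discarded; snip durations
plus the discarded tail reproduce the recording duration exactly, and
every beat belongs to exactly one snip or the tail. Offsets are kept at
second resolution; a `truncate_offset_to_minutes` flag emulates offset
metadata recorded without seconds. A first snip too short to pass the gate
is classified `NOT_ANALYZABLE` rather than merged into hour 1, keeping the
"first hour" semantics of per-patient analyses intact. Pseudonymization
keeps only a keyed-hash pseudonym (stable per patient) and relative times.

## The synthetic generator

The generator is the package's ground-truth instrument; its defaults are
chosen once, as study conditions, and the tests assert against them.

* **Sinus rhythm**: mean NN 800 ms (75 bpm), SDNN 40 ms split between
  AR(1) colored noise (lag-1 0.8) and a 0.25 Hz respiratory modulation.
  Deviations are clipped at min(2.5·SDNN, 12% of the mean cycle):
  physiological sinus variability is bounded, and the clip guarantees that
  ordinary sinus beats never cross the census's prematurity threshold, so
  a clean sinus hour truly contains zero PACs.
* **AF**: i.i.d. gamma intervals, mean 600 ms, CV 0.2 — serially
  uncorrelated (lag-1 within ±0.1), faster and far more dispersed than
  sinus. No AV-node refractory modeling; this is a deliberate
  simplification, sufficient to exercise every feature, not an
  electrophysiological model.
* **Ectopy**: PACs are inserted by replacing one sinus interval with a
  (CI, P) pair built mid-tolerance for the requested type from the same
  local-NN definition the census uses, so typing round-trips at ≥ 95%.
  Ventricular beats get a wide (180 ms), low-correlation template and a
  full compensatory pause.
* **Risk signature**: present in paroxysmal patients. At t hours after the
  last episode the signature level is
  g(t) = 0.1 + 0.9·exp(−t / 1.2 h) (0.1 before any episode; cohort
  patients use a 0.5 floor); it multiplies sinus SDNN by 1 + 0.6·g and
  adds 40·g countable PACs per hour. The functional form is a free choice
  — the underlying physiology asserts only that such post-episode dynamics
  exist and decay — so tests assert the qualitative consequence
  (sensitivity non-increasing over post-episode hours 1–3), not its
  magnitude.
* **Waveforms** (for the detector tests): Gaussian P-QRS-T bumps per beat,
  wide tall P-less complexes for ventricular beats, 1–3 leads with
  distinct gains, white noise at a configurable SNR. R-peak times are
  preserved within one sample.

The default cohort is desk-scale — 10 paroxysmal / 3 chronic / 15 healthy
patients at 6 hours each, with 30% of paroxysmal patients carrying
episodes of 5–30% burden — so the full pipeline benchmark runs in a few
minutes; `cohort_spec(study_scale = TRUE)` switches to the study's 70/19/100
at 20–24 h. What passing synthetic benchmarks shows is that the pipeline
recovers what the generator planted (episodes, PAC types, risk signatures)
at the stated rates; it does not show field performance on real ECGs,
whose artifact structure, ectopy morphology and rhythm pathology are far
richer than this generator.

## Evaluation and packaged fixtures

Sensitivity and specificity are kept as exact rationals
(numerator/denominator); rounding is half-up and happens only at
presentation, matching printed clinical tables. The validation study's
contingency tables and results-text counts ship as CSV fixtures
(`group,stratum,positive,total`), because the raw patient ECGs are not
distributable — the fixtures are the acceptance surface for the printed
statistics. Two transcription notes: one table's printed marginal totals
are internally inconsistent with its cells and footnote, and the fixture
carries the footnote-consistent counts (19/47); another table's footnote
numerator (2794) disagrees with its own cells (2797 + 24 = 2821), and the
fixture carries the cell values — both choices round to the same printed
two-decimal statistics.

## Numerical conventions and limitations

* Population (1/N) variance for Poincaré descriptors; sample SD elsewhere
  (`dnorm_sd`, the ApEn tolerance). Quantiles are R type 7.
* All tie-breaks are deterministic (earliest window, lowest lead index).
* Every stochastic routine takes an explicit seed and restores the global
  RNG state; identical seeds give identical output on the same platform.
  Across platforms, floating-point identity is not guaranteed, only
  statistical equivalence.
* The classifier is linear and trained purely on synthetic data; its
  decision surface is *not* the vendor's, and patient-level sensitivities
  from the validation study are not reproducible from raw signals here —
  they enter via the fixtures instead.
* P-wave analysis, pacemaker handling, and 12-lead diagnostic
  interpretation are out of scope.
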