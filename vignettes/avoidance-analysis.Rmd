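---
title: "Methods: scoring, inference and measurement pipelines in avoidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, inference and measurement pipelines in avoidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidr)
```

`avoidr` analyzes *C. elegans* repellent-avoidance experiments in which
worms sense bacterial secretions through head (amphid, notably the ASH
nociceptor) and tail (phasmid PHA/PHB) chemosensory neurons. This vignette
is the package's methods account: the models and procedures, the defaults
and why they were chosen, what the synthetic-data generator does and does
not emulate, and the numerical conventions.

## Behavioral scoring

**Tail (phasmid) dry-drop assay.** The measured quantity is the backing
time `T` (seconds) until an animal halts after backing into a dried drop of
repellent. Because absolute backing times drift between assay days, indices
are expressed relative to same-day controls. `response_index_wildtype()`
computes `100 · mean(T_treatment) / mean(T_SDS)`, so the 0.6 mM SDS
positive control defines 100% and faster halting yields a smaller index.
`response_index_normalized()` handles mutants whose baseline locomotion
differs from wild type by first forming the mutant's treatment/buffer
ratio and then dividing by the wild-type SDS/buffer ratio. The two
definitions coincide algebraically whenever the mutant and wild-type buffer
means are equal, and the test suite asserts that identity to 1e-12
relative.

Both functions offer `per_day = TRUE`, which computes the index within
each assay day against the same-day control and averages days with equal
weight. This mirrors the practice of normalizing to controls assayed on the
same day; the pooled mode (default) weights by animal and is appropriate
when day structure is absent. Censored animals — those still backing at
the observation cap — enter group means at the cap value; no survival
modeling is attempted, and the censoring fraction is visible in the
records.

**Head (amphid) assay.** The outcome is binary: a worm that halts forward
movement and reverses on contacting the dried drop is a responder.
`head_response_proportion()` reports the responder proportion; buffer
controls sit near 0.2 and strong repellents near 0.8.

**Chemotaxis.** `chemotaxis_index()` scores each plate as
`(#experimental − #control) / #total`, in [−1, 1]; worms at neither spot
count in the denominator.

## Inference

The tests are the field's standard ones, delegated to base R where a
canonical implementation exists:

- `two_sample_z_test()` — pooled two-proportion z without continuity
  correction, the generic large-sample comparison for head-assay
  proportions. It warns (rather than fails) when expected successes or
  failures drop below 5.
- `two_sample_t_test()` — classical pooled-variance t
  (`stats::t.test(var.equal = TRUE)`, df = n1 + n2 − 2); Welch is not
  offered because the assays compare like-for-like group variances and the
  pooled form is the convention here. Zero-pooled-variance degeneracies
  return `t = 0, p = 1` (equal means) or an infinite-statistic sentinel
  with `p = 0` (unequal means) rather than erroring mid-pipeline.
- `one_way_anova_tukey()` — `stats::aov` + `stats::TukeyHSD`; pair rows
  carry the Tukey–Kramer studentized-range statistic
  `q = |diff| / sqrt((MSE/2)(1/ni + 1/nj))` and the family-wise-adjusted p.
- `hochberg_adjust()` — `stats::p.adjust(method = "hochberg")`, verified in
  the tests against a brute-force implementation of the step-up
  definition. Adjusted p-values never fall below the raw ones.
- `cohens_d()` — pooled-sd standardized mean difference, sign preserved.

`run_figure_analysis()` is the declarative layer: a plan table names
comparison families, the test per family (`z`, `t`, or `anova_tukey`), and
the group pairs. Multiplicity is handled *within* family — Hochberg for z
and t families, Tukey's own adjustment for ANOVA families — because a
family corresponds to the set of conclusions drawn from one panel's data.
Family membership is explicit in the plan, never inferred. Significance
codes (`***`, `**`, `*`, `ns` at 0.001/0.01/0.05) are always derived from
the adjusted p-values; for a single-comparison family the Hochberg
adjustment is the identity, so nothing is lost.

**Power and sample size.** `sample_size_t()` finds the smallest integer
per-group n whose noncentral-t power (noncentrality `d·sqrt(n/2)`,
df `2n − 2`) reaches the target — at d = 0.8, α = 0.05, power = 0.8 this
gives 26 per group, and the bracketing property (power ≥ 0.8 at n, < 0.8
at n − 1) is asserted in the tests. `sample_size_two_prop()` uses Cohen's
arcsine effect size `h = |2 asin(√p2) − 2 asin(√p1)|` with
`n = round(2 (z_{1−α/2} + z_{pow})² / h²)`; for pilot proportions 0.3 and
0.8 this yields h ≈ 1.055 and 14 per group. The factor-2 variant of the
formula was chosen deliberately: the per-group n from the plain
`(z_a + z_b)²/h²` form (≈7) is half of it, and 14 is the planning figure
this assay family conventionally uses at these pilot proportions.

## Calcium imaging

The input contract is registered, background-subtracted intensity traces on
a uniform 0.5 s grid starting at 0 s, under a 15 s buffer / 60 s stimulus /
buffer protocol. Image processing (ROI extraction, registration, bleach
correction) is out of scope.

- `delta_f_over_f()` computes `100 · (F(t) − F0)/F0` with F0 the single
  sample at t = 15 s, the last pre-stimulus frame — the definition used
  with this protocol. Because a single-frame baseline is sensitive to frame
  noise, `baseline = "window"` (mean over 10–15 s) is available but off by
  default. Traces with gaps are rejected rather than interpolated:
  acquisition is uniform, and interpolation would fabricate signal.
- `subtract_buffer_control()` subtracts the pointwise mean trace of worms
  exposed to buffer throughout; applying it to the buffer group itself
  leaves a zero mean trace (asserted to 1e-12).
- `auc_stimulus()` integrates the normalized trace over 15–75 s (endpoints
  inclusive) by the trapezoid rule on the native grid, units %·s. Negative
  areas are kept: clipping would bias group means toward responders.
- `compare_auc()` is a pooled t-test on per-worm AUCs, one stimulus at a
  time, with no adjustment across stimuli (they are analyzed separately).

The whole pipeline is invariant to uniform rescaling of raw intensities —
ΔF/F is a ratio — and the tests assert this to 1e-10.

## Mass spectrometry

`monoisotopic_mz()` sums monoisotopic masses of the most abundant isotopes
(H, C, N, O, S, P, Na, K, Cl, F, Br, I, Si built in) and, for ions,
subtracts `charge` electron masses before dividing by |charge|; neutral
mode (`charge = 0`) exists for validation against tabulated masses.
Derivatization chemistry (e.g. the fixed-charge pyridinium esters used to
make carboxylates visible in positive mode) is represented only by the
target ion formula supplied in configuration.

`extract_eic()` sums, per scan, centroid intensities within
`target_mz · ppm_tol · 1e-6` of the target. The window is closed on both
sides (a centroid exactly at ±tol is included — the inclusive reading of
"± tol") and the default is 100 ppm, a common QToF extraction default.
Every scan yields a point, zero when nothing falls in the window, so EICs
from the same run always share a grid. `integrate_peak()` integrates a
caller-specified retention-time window by the trapezoid rule; there is
deliberately no automatic peak detection — the window per target is part of
the analysis configuration, replacing interactive manual integration with
an explicit, reproducible choice. The optional linear baseline subtracts
the chord between window endpoints and floors at zero.
`relative_abundance()` reports the sample/control area ratio with a single
`detection_floor` cutoff; when the control itself is below the floor the
ratio is `Inf` ("not quantifiable against this control") and the detection
flag carries the information that matters.

Runs are tidy centroid tables (`rt_s`, `mz`, `intensity`) with a `scan_rt`
attribute so empty scans survive; `read_centroid_jsonl()` /
`write_centroid_jsonl()` serialize one scan per line. Profile-mode peak
picking, deconvolution, isotope scoring and cross-run alignment are
non-goals.

## The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, at the study's own scale: groups of ~40 animals for behavior,
buffer head-response probability 0.2 and repellent probabilities near 0.8
(with 0.3 as a defective-mutant pilot proportion), ≥15 worms per genotype
for imaging.

- **Backing times** are Gamma-distributed — positive support and the right
  skew typical of latency data — parameterized by the group mean and a
  dispersion given as the coefficient of variation, so `dispersion = 0` is
  the exact noise-free limit. The observation cap defaults to 20 s; an
  animal that never halts is recorded at the cap and flagged censored. The
  source studies report only group means, so the default dispersion used in
  the demo (0.35) is a realistic latency CV chosen once, not an estimate of
  any published variance. An optional multiplicative day effect (off by
  default) exercises within-day normalization.
- **Head responses** are Bernoulli draws per animal with per-treatment
  probabilities.
- **Chemotaxis plates** allocate worms multinomially among experimental
  spot, control spot, and elsewhere.
- **GCaMP traces** are baseline + optional linear bleach + stimulus-locked
  transient + Gaussian noise, on the 0.5 s grid. The transient is a
  difference of exponentials `e^(−s/τ_decay) − e^(−s/τ_rise)` from stimulus
  onset, rescaled so its peak equals `amplitude · baseline` (defaults
  τ_rise = 1.5 s, τ_decay = 15 s, amplitude 0.5 — a transient of the
  shape and magnitude GCaMP6 reports for strong nociceptive responses).
- **Centroid runs** place one centroid per configured chromatographic peak
  per scan, with Gaussian-in-rt intensity, multiplicative ppm jitter on
  m/z, and optional uniform noise-floor centroids.

Every generator takes an explicit seed, runs in its own RNG stream
(`withr::with_seed`), and leaves the global RNG untouched; fixed seed means
bit-identical output, which the demo pipeline inherits (byte-identical CSV
reports).

What the simulator does **not** emulate: worm locomotion or neural
dynamics, day-to-day experimenter variability beyond the optional
multiplicative day factor, non-Gamma latency shapes (e.g. bimodal
responders/non-responders), motion or focus artifacts in imaging,
chromatographic tailing, detector saturation, or isotope patterns. Passing
tests therefore demonstrate that the analysis code implements its
definitions correctly and recovers known parameters under the assumed data
structure — not that those assumptions hold for any particular real
dataset.

## Numerical conventions and test scales

Trapezoid integration everywhere (`pracma::trapz`) on native grids;
inclusive window endpoints in both the calcium AUC (15 and 75 s) and EIC
rt windows; closed ppm bounds; time zero at recording start. Sample-size
searches iterate n upward from 2 — power is monotone in n, so the first
crossing is the answer.

The stochastic checks in the suite run at chosen, fixed scales: type-I
calibration uses 10,000 null replicates at the study's group sizes (two
Gamma groups of 40 for t; Bernoulli p = 0.2, n = 40 for z — a regime where
exact enumeration puts the pooled z-test's true size at 0.051; three
Gamma groups of 20 for Tukey family-wise error), with a 3-Monte-Carlo-SE
band around 0.05. Effect recovery uses 300 replicates of two 40-animal
Gamma groups configured at a standardized difference of 2.8 (buffer mean
10 s vs treatment 5.8 s, common sd 1.5 s — parameters chosen so both
Gammas stay far from zero and the cap). Published effect sizes from real
assays are not reproducible without the original per-animal records; the
recovery check is a parameter-recovery surrogate, which is exactly what a
simulation can honestly establish.

## Known limitations

- Backing-time censoring is handled by cap substitution, not survival
  models; with heavy censoring the indices are biased toward the cap.
- The pooled z and t tests inherit their usual small-sample caveats; the
  z-test only warns below the expected-count rule of thumb.
- `run_figure_analysis()` supports one test type per family and pairwise
  comparisons only.
- EIC extraction assumes centroided input; profile data must be centroided
  upstream. JSON-lines is the only ingestion format.
- The ratio-of-means response indices have no accompanying uncertainty
  interval; inference runs on the underlying records instead.
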