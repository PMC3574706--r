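---
title: "Two-lead ECG beat detection and neuro-fuzzy classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-lead ECG beat detection and neuro-fuzzy classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the signal model, each stage's assumptions and tunables, the numerical
choices, what the synthetic generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

## Problem and signal model

Ambulatory and home-care ECG monitors record one or two leads, not the
clinical twelve. The task is beat-by-beat: find every QRS complex in a
two-lead record (Lead II and V1, 360 Hz, mV), and label each beat as normal
sinus rhythm (N), premature ventricular contraction (V), left or right
bundle branch block (L/R), or premature atrial contraction (A), while
rejecting markers that are not heartbeats at all. Lead II carries the
rhythm; V1 is the precordial lead on which the bundle-branch-block
patterns (QS for LBBB, rsR′ for RBBB) are most distinctive, which is why
the beat feature concatenates both leads.

## Preprocessing

* **Low-pass**: order-10 linear-phase FIR, cutoff 40 Hz. The design method
  is a Hamming-windowed sinc normalized to unity DC gain — the minimal
  standard choice for a short linear-phase filter. The group delay of
  `order/2 = 5` samples is compensated by shifting, so all derived streams
  stay index-aligned with the raw record; edge samples are replicated.
* **Baseline removal**: a single-weight adaptive canceller with constant
  reference input. Its weight is an exponentially weighted running estimate
  of the baseline and the error output is the baseline-free signal — an
  equivalent first-order DC notch. A single first-order section whose
  −3 dB edge sits at 0.5 Hz attenuates a 0.2 Hz drift by only ~86% in
  power, which we judged insufficient for the stop band the design intends
  (0–0.5 Hz). The canceller therefore runs forward and then backward
  (zero-phase, like `filtfilt`), with the per-pass step chosen so the
  *cascade* −3 dB edge is 0.5 Hz: the 0.2 Hz drift loses ~92% of its power
  while a 10 Hz component is preserved within 0.2%, and the zero-phase pass
  removes any group-delay concern in this stage. This is the one deliberate
  departure from the textbook single-pass canceller.
* **Normalization**: the affine min-max map `2(x − min)/(max − min) − 1`,
  applied per record (the sample-wise SVM operates on whole-record
  streams, so per-beat normalization would leak segmentation into the
  detector). Constant input is a degenerate-input error, not a silent NaN.
* **Differentiation**: first difference with `y[1] = 0`, preserving length
  and alignment.

## QRS marking

Every sample contributes a two-dimensional feature: (normalized filtered
Lead II, normalized first difference). A Gaussian-RBF soft-margin SVM
(γ = 2.5, C = 200 — the standard operating point of this detector) is
trained on a small set of annotated cycles: one full RR interval centered
on each selected R wave, with samples within ±40 ms of the R labeled
positive. The 80 ms window covers a minimal 60 ms QRS symmetrically; the
labeling window is a design choice (no more principled boundary is
available without per-sample QRS-extent annotations) and is configurable
(`qrs_halfwidth_ms`). The solver is libsvm via `e1071`; the model is
defined by its support-vector expansion, which the package stores,
evaluates and serializes itself — so the fitted detector is independent of
the solver and its KKT conditions (margin |f| = 1 at unbounded support
vectors) can be checked directly, which the test suite does, alongside a
cross-check against a second independent SVM implementation.

Marker cleanup runs **merge before delete**: gaps under 5 samples are
closed first, then markers narrower than 10 samples are removed. The order
matters for the LBBB double peak, which can produce two narrow neighboring
runs that must merge into one valid marker rather than be deleted
separately. The post-processor is idempotent and is property-tested against
a brute-force reference.

## Beat segmentation

From a marker's start (its positive edge), the R wave is located by a
forward minimum search over 100 samples followed by a backward maximum
search over 50 samples — a convention that lands on the positive deflection
even for inverted (PVC) complexes, where the deep trough is found first and
the preceding positive wave is taken as R. The beat feature is 100 samples
of Lead II centered on R (window `[r − 50, r + 49]`, R at position 51)
concatenated with the same window of V1: 200 inputs. The 100-point window
(~278 ms at 360 Hz) is wider than a typical 150 ms QRS; it is normative
here because it fixes the classifier's input dimension. Beats whose window
would cross a record boundary are skipped and counted — the input dimension
cannot vary.

## The SoNFIN classifier

The network is a five-layer TSK fuzzy model. Rule *j* holds one Gaussian
fuzzy set per input, membership `exp(−(xᵢ − mᵢⱼ)²/σᵢⱼ²)`; its firing
strength is the product over the 200 inputs; output *k* is the
firing-strength-normalized average of the per-rule linear consequents.
Class targets are ±1 vectors with +1 at the true class.

Numerical choices that matter at 200 inputs:

* **Log-space firing**: the product of 200 Gaussian memberships underflows
  double precision routinely. Memberships are summed in log space and the
  normalized strengths are computed by log-sum-exp (softmax); the raw
  strengths are exposed only where they are well-scaled (structure
  learning compares `max log u³` against `log H`).
* **Structure learning**: starting from zero rules, a rule is created
  whenever no rule fires above H = 0.1; its centers copy the sample, its
  widths start at σ = 0.6, and its consequent weights start at zero, which
  leaves the input–output map unchanged at creation except through
  normalization. Growth is restricted to the first epoch by default
  (`structure_epochs = 1`): "concurrent" structure and parameter learning
  is ambiguous about whether growth continues while parameters move, and a
  single growth pass keeps the rule count bounded and runs reproducible.
  On beat data the first pass typically creates one rule per distinct
  morphology cluster (four rules in the worked example).
* **Consequent training**: recursive least squares by default (forgetting
  factor 1, covariance `10⁴·I`). The regressor — normalized firing
  strengths ⊗ (1, x) — is identical for the four outputs, so a single
  covariance matrix serves all of them. A covariance that loses positive
  definiteness numerically is reset to its initial scale with a warning.
  A gradient-descent mode (rate 0.01) is also implemented: descriptions of
  this architecture state both a consequent RLS rule and a consequent
  training *rate*, and rather than hide that discrepancy the
  mode is a config switch (`consequent_mode`), with RLS the default.
* **Antecedent training**: gradient descent (rate 0.05) on
  `V = Σ (dₖ − oₖ)²`, with derivatives taken through the normalized
  defuzzifier; widths are clipped below at 10⁻³ to stay positive. The
  analytic gradients are verified against central finite differences in
  the test suite.
* **Iterations**: training sweeps the dataset ("iterations" are epochs —
  the other reading, single-sample updates, would make 1,000 updates less
  than one pass over a realistic beat set). The package default is 1,000
  epochs; the tests and the acceptance script train for 20 epochs on the
  synthetic task, where the per-epoch error trace shows convergence to
  ~10⁻⁷ within a handful of epochs — the default is kept for fidelity, not
  because the synthetic task needs it.
* **Output coding and decision**: argmax over the four outputs. The four
  output nodes share antecedents and differ only in consequent weights —
  the standard multi-output TSK reading.

## Noise rejection and the PAC rule

A marker that is not a heartbeat yields a segment far off the training
manifold; the TSK consequents are linear in the inputs, so the outputs
extrapolate well past the ±1 coding. A threshold of 2.5 on the output
magnitude flags such beats as noise. The exact statistic is a design
choice: the default compares `max |oᵢ|` (targets are ±1, so a large
negative excursion is as diagnostic as a positive one); `max oᵢ` is
available as a config option for the strictly-positive reading.

PAC beats cannot be separated morphologically — their waveform is normal
— so the classifier has four outputs and PAC is decided by timing: a beat
labeled N whose preceding RR interval is below 0.85 × the mean of the
previous 8 RR intervals is relabeled A. Both parameters are configurable;
0.85 sits comfortably between normal RR jitter (a few percent) and the
0.7 × RR prematurity the generator uses for PAC placement. This rule is a
gap-filling design decision, clearly separated from the network.

## The synthetic generator

`simulate_ecg()` emulates exactly the study conditions the pipeline
assumes: 360 Hz two-lead records with Gaussian-bump templates (P, Q, R, S,
T per label) implementing the textbook morphologies — upright narrow NSR
with rS in V1; wide inverted PVC without P; LBBB with two neighboring
positive peaks in Lead II and QS in V1; RBBB with a wide S in Lead II and
rsR′ in V1; PAC sharing the NSR shape but placed at 0.7 × the nominal RR.
Beats are placed at Gaussian-jittered RR intervals; 50/60 Hz powerline,
sub-0.5 Hz baseline wander, broadband noise and narrow biphasic spike
artifacts (< 10 samples wide, kept away from true QRS supports) are added
on top. Each template's annotated R index is the Lead II maximum within
its QRS support — the same point the marker-based R search converges to —
so annotations, training segments and test-time localization agree by
construction.

What the generator does **not** emulate: beat-to-beat morphology
variability, respiration coupling, electrode-motion baseline steps,
fusion beats, and the within-class diversity of a real arrhythmia
database. Passing the end-to-end tests therefore demonstrates that the
pipeline's stages compose correctly and meet their contracts under
realistic noise, not that the reported full-database accuracies transfer;
reproducing those requires the external database and the original
training-beat selections, which are not available (the optional
`inst/integration/run_mitdb.R` script documents that path).

## Problem sizes and evaluation

The test suite and the acceptance script train the detector on 24 beats
(10 N, 6 V, 4 R, 4 L) from a 150 s mixed-rhythm record and the classifier
on 20 beats per class for 20 epochs, then evaluate on a separately seeded
100 s record (~125 beats) with spike artifacts injected at 8/min. These
sizes were chosen as the smallest at which every stage is exercised with
comfortable margin — detection saturates at ~99–100% sensitivity and
classification at ~99–100% accuracy under the generator's noise levels.
Detection is scored by greedy one-to-one matching with a 150 ms tolerance
(the common arrhythmia-database convention; the tolerance only affects
simulator-based scoring, never the printed-table arithmetic).
Percentages are rounded half-away-from-zero at one decimal, matching the
convention of the shipped reference tables; the "averaged accuracy" of a
multi-class report is ambiguous (mean of per-class one-vs-rest accuracies
vs pooled fraction correct), so `classification_report()` returns both and
neither is treated as the canonical summary.

## Known limitations

* The detector is trained per-generator/per-database; there is no
  pretrained model, by design — the original training-beat selections are
  not available.
* Records must contain both leads; Lead II-only records are rejected
  rather than degraded to single-lead operation.
* Boundary beats (within 50 samples of a record edge) are skipped, not
  classified.
* The PAC rule needs a few beats of RR history and cannot flag a PAC in
  the first two beats of a record.
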