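---
title: "Methods: EEG landscape-emotion scoring and multi-criteria scene evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG landscape-emotion scoring and multi-criteria scene evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Traditional-village landscape scenes differ in material composition (paving,
building materials, vegetation, water), spatial structure (green view index,
visual depth, enclosure), and cultural signal (density and legibility of
symbols). `landemo` quantifies the emotional response such scenes evoke from
scene-locked EEG, ranks scenes by a compromise multi-criteria model, and
estimates dose-response thresholds of individual indicators.

## Emotion indices

From each trial's preprocessed epoch we compute integrated alpha (8-12 Hz)
and beta (13-28 Hz) band powers per channel group. The two indices are

* arousal `E_AR = P(alpha) / P(beta)` over the all-channel group, and
* valence `E_VA = P(alpha)_right / P(beta)_right - P(alpha)_left /
  P(beta)_left` (frontal-asymmetry style).

Both are ratios, hence invariant to any common rescaling of the spectra.
Note the arousal ratio carries alpha in the numerator. Much of the EEG
literature uses beta/alpha for activation; we implement the formula as
printed in the source protocol and flag the direction in the documentation —
all downstream machinery is agnostic to the convention.

A caution that shapes one pipeline default: for a single left/right channel
pair, average re-referencing replaces each channel with plus/minus half the
difference signal, making the two spectra identical and forcing `E_VA = 0`.
The full pipeline therefore re-references only when more than two channels
are present. (The field protocol used a single-channel consumer device yet
prescribes average re-referencing and a bilateral valence index; the
contradiction is inherited, not introduced, and the package accepts
arbitrary channel counts.)

## Preprocessing

Seven stages: (1) zero-phase FFT band-pass, default 1-45 Hz, raised-cosine
transitions of 1 Hz, DC always removed; (2) amplitude masking of fixed 1-s
windows exceeding 100 uV (windows are masked, not deleted, and the mask
propagates to epoching); (3) optional independence-based component removal —
a fixed-point symmetric ICA with tanh contrast; components are flagged by
correlation with an artifact template (|r| > 0.8) or excess kurtosis (> 5)
and zeroed before back-projection; (4) average reference (see above);
(5) epoching -200..1000 ms around scene onsets; (6) baseline correction with
the -200..0 ms mean; (7) Hann-windowed FFT band powers on the 0..1000 ms
post-stimulus segment.

Band power is the **sum** of one-sided periodogram power over bins whose
center frequency falls in the closed band, times the bin width. The sum
(integrated band power) rather than the per-bin average is what makes the
synthetic carrier construction exact (amplitude ratio = square root of the
target power ratio) and gives the flat-spectrum identity
`P(alpha)/P(beta) = (alpha bin count)/(beta bin count)` for white noise —
both serve as test oracles. At 512 Hz with 1-s epochs the resolution is
1 Hz, so alpha spans 5 bins and beta 16.

## Decision model

Per criterion the scene values are range-normalized (benefit:
`(x-min)/(max-min)`; cost reversed; constant columns map to 0.5 with a
warning and receive entropy weight exactly 0). Grey relational coefficients
against the ideal sequence use the global minimum and maximum deviation
(matching the printed double min/max) and distinguishing coefficient
`rho = 0.5`, so with any exactly-ideal cell the coefficients live in
[1/3, 1]. Entropy weights are computed on the normalized matrix (standard
entropy-weight practice; an assumption, since weighting on the relational
coefficients would also be defensible). VIKOR group utility S, individual
regret R, and compromise Q follow with `v = 0.5`; degenerate denominators
(all S equal or all R equal) zero the corresponding term, the continuity
limit of equal scores. The classical compromise conditions (acceptable
advantage/stability) are reported but never alter ranks. Levels I-IV are Q
quartiles — the source reports roughly 25% of scenes per level but states no
rule, so quartiles are the minimal assumption consistent with that. Obstacle
degrees are each criterion's share of a scene's total weighted deviation; a
scene at the ideal gets an all-zero row and a `no_obstacle` flag rather
than a 0/0.

By default the decision matrix joins the two emotion indices with the
indicator columns ("joint" mode); an emotion-only mode exists because the
protocol text can be read either way.

## Synthetic data: the stated world

No field data were deposited, so every downstream stage is exercised against
a generator whose presets *encode* the published effect structure. The three
village archetypes fix scene counts (54 / 128 / 94), vegetation-layer mixes
(64% single-layer in the organically-grown village), water prevalence
(near-ubiquitous in the waterfront village), a bimodal visual-field spread
there, and village-specific symbol-density thresholds (2.0 / 1.8 / 2.2 per
100 m^2). Indicator values come from uniform/categorical mixtures spanning
the effect-relevant ranges (GVI over [10, 90], symbol density over [0, 4],
hard pavement over [0, 40], local material over [30, 100]) — chosen for
coverage of the threshold regions, not realism, since the source gives no
distributions.

Latent emotion per trial is `baseline + scene effect terms + covariate shift
+ scene noise + participant intercept + trial noise`. The preset effects:

| effect | form | size |
|---|---|---|
| hard pavement on arousal | linear | -0.047 / percentage point |
| plant layers on arousal | categorical | +0.95 for 3-layer vs 1-layer |
| water visibility on arousal | saturating at 70% | +0.019 / point |
| GVI below 40 on both indices | ramp | 0.024 / point |
| GVI above 70 on arousal | step | -42% of the peak-interval mean |
| symbol density on valence | step at threshold | +0.18 |
| local material on valence | step at 70% | +0.35 |

Design choices that needed deciding:

* **GVI plateau [40, 70).** The peak interval is printed as 40-60% and the
  oppressiveness drop as "exceeding 70%"; behaviour on (60, 70] is unstated.
  The generator holds the plateau to 70 and drops exactly at 70, keeping the
  latent GVI response piecewise-linear with two breakpoints — the same model
  class the interval detector fits, so the detector's assumptions are
  testable rather than conveniently violated.
* **The 42% drop is relative**, so it is encoded as an additive step of
  `-0.42 * E[arousal | GVI in peak]`, with the expectation computed
  analytically (closed forms/quadrature over the preset's own sampling
  distributions) at preset construction. The percentage reduction is then
  42% in expectation by construction, which is exactly what "the preset
  encodes the printed effect" means; nothing is fitted to observed output.
* **Baseline arousal 7.5.** The ratio index must stay positive for every
  trial (alpha power cannot be negative). With the full effect stack the
  worst deterministic case is `0.58 * E_peak - 0.94` (maximal pavement,
  GVI > 70), and noise components are truncated at +/-3 SD, bounding the
  worst noise excursion by 1.95 arousal units and the hemispheric split by
  a further ~0.8; baseline 7.5 makes the minimum attainable alpha power
  provably positive for all three archetypes. A naive baseline of 2 — the
  obvious first choice — is infeasible under the stack, which is why the
  generator refuses non-positive mappings with an explicit error rather
  than silently clipping.
* **Noise SDs** (emotion-index units): arousal scene/participant/trial =
  0.15/0.2/0.3 — the trial value is fixed by the effect-recovery setup; the
  others sit below it as repeat-averaged field EEG indices typically do.
  Valence noise is 0.10/0.10/0.15, proportionally smaller as the printed
  valence effects (0.18-0.42) are several times smaller than the arousal
  effects. These are the stated world; they were chosen once and are not
  tuned against test outcomes.
* **Emotional benefit composite** defaults to the plain mean of the arousal
  and valence indices. Under a range-normalized composite the printed
  "0.12-unit drop per 5 GVI points" could not be encoded scale-freely (the
  normalization constant depends on each sample's min/max); with the native
  mean and a 0.024/point ramp on both indices the composite slope is
  0.024/point identically, i.e. 0.12 per 5 points. The range-normalized
  variant remains available via `normalize = TRUE`.
* **Covariates** (age 22-66, truncated normal mean 44.5 SD 13.2; 23 of 50
  male) shift both indices linearly, centered at the panel means, so scene
  expectations remain the deterministic effect terms. By default every
  participant views every scene (as the cohort design implies);
  `participants_per_scene` subsamples the panel, which is what makes
  covariate adjustment distinguishable from raw averaging in tests.

Raw-EEG mode emits, per trial and hemisphere, a 10 Hz alpha and a 20 Hz
beta sinusoid with amplitude ratio `sqrt(target power ratio)` — both
complete integer cycles in the 1-s analysis window, so recovered ratios are
leakage-free to numerical precision — plus optional 1/f noise, 50 Hz line,
drift, and 150 uV pulse artifacts placed on the rejection grid at a known
rate (the generator's bookkeeping is the oracle for the rejection stage).

What a green test does **not** establish: realism of EEG morphology (no
ERPs, topographies, or autocorrelated background by default), realism of
indicator distributions, or any claim about the published absolute results
(level counts, obstacle-degree magnitudes, best-scene scores), which are
unreproducible without the undeposited data.

## Threshold analyses

Slopes and step contrasts are OLS with covariate adjustment; covariates with
known-nonlinear shapes can be entered as binned factors. The step contrast
uses a closed upper side (`x >= threshold`). Benjamini-Hochberg adjustment
is implemented directly (it is itself a specified operation with hand-worked
cases) and tested against `stats::p.adjust` as an independent oracle.

The optimal-interval detector combines (a) grid-binned means smoothed with a
3-cell moving average, reporting the maximal contiguous run whose smoothed
mean is within one standard error of the peak cell — the SE of the
peak-minus-cell *difference*, so sampling noise in either cell does not
spuriously break the run — and (b) a two-breakpoint piecewise-linear model
with three independently fitted segments, found by exhaustive grid search
minimizing SSE. Independent segments (rather than a continuous spline) are
deliberate: they represent discontinuous step responses exactly, and on
degenerate (purely linear) data the scan order resolves SSE ties to the
widest outer segments, putting the breakpoints at the grid extremes. The
3-cell smoothing biases the 1-SE run about one cell inward at a sharp
plateau edge; the segmented fit has no such bias, which is why the
per-5-point sub-peak slope is read from the fitted lower segment.

Associations are Pearson by default (`spearman` by flag), with BH-adjusted
q-values over the upper triangle and an edge list filtered by |r| and q.

## Numerical and degenerate-input conventions

Single-scene matrices error (range undefined); constant criteria map to 0.5
and weight 0; an all-ideal matrix yields coefficients 1 everywhere, not an
error; fewer than 4 scenes cannot be quartile-graded and fall back to
Level II with a warning; epochs crossing the record edge are skipped and
counted, not fatal; zero beta power makes a trial's ratio undefined — it is
dropped and logged, never imputed. All CSV artifacts round-trip to at least
12 significant digits, and the JSON manifest (config echo + seed) is
byte-identical across reruns.

## Known limitations

The ICA stage is contract-level: any converging independence rotation
satisfying the flag-and-remove postconditions is conformant; no attempt is
made to reproduce a specific Infomax implementation. EDF support is a
minimal 16-bit codec, not EDF+. The YAML config reader covers the flat
`key: value` subset only (JSON is the primary format). Spatial analyses
(inter-symbol distances, space-syntax integration) are out of scope.
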