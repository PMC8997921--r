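---
title: "Fatty-acid calibration from Raman and NIR spectra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatty-acid calibration from Raman and NIR spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gas chromatography is the reference method for fatty-acid (FA) composition
of muscle tissue, but it is too slow and costly for applications that need
thousands of measurements — feed trials, breeding programs, routine quality
documentation of salmon fillets. Vibrational spectroscopy (Raman and
near-infrared) measures intact homogenates in seconds, and lipid signals
are prominent in both modalities. The open question is not whether spectra
correlate with FA contents but *what exactly a calibration model measures*:
FAs co-vary strongly with each other and with total fat, and calibration
models inherit that covariance — the "cage of covariance". A model with an
excellent R² may be predicting fat content, or a correlated neighbour FA,
rather than its nominal target.

`specfat` implements the complete workflow needed to study this question
with known ground truth: a simulator for FA compositions and Raman-like /
NIR-like muscle spectra, the two standard preprocessing chains, PLS
calibration with venetian-blind cross-validation, two variable-selection
procedures, and diagnostics that quantify the covariance structure of
predictions.

## Composition model

Compositions are drawn from a truncated multivariate normal. The marginal
means and SDs default to GC reference statistics for the 13 FAs that exceed
2% of total FA in farmed Atlantic salmon muscle
(`salmon_reference_stats()`); e.g. C18-1(n-9) at 30.5 ± 1.8% of total FA,
EPA at 5.1 ± 0.5%, DHA at 6.8 ± 0.5%.

Only a few pairwise correlations between salmon-muscle FAs are published:
0.95 between C18-1(n-9) and C18-2(n-6), 0.88 between C18-2(n-6) and
C18-3(n-3), 0.51 between EPA and DHA, and a strong negative association
between the long-chain n-3 PUFAs and C18-1(n-9). The default full matrix
(`salmon_fa_correlation()`) is therefore a declared *synthetic* construct:
a four-factor latent model (a marine-vs-vegetable-oil axis, a saturates
factor, a long-chain-monoene factor, and an EPA/DHA-specific contrast) with
uniformly small uniquenesses, with the published pairs imposed exactly and
the result repaired to positive semi-definiteness by eigenvalue clipping.
The factor construction was chosen so that 5–6 principal components explain
essentially all reference variance, the hallmark of this kind of cohort
(one year class, one feed), and the acceptance checks verify ≥ 95%
cumulative variance by component 6.

Two design choices deserve justification:

* **No compositional closure by default.** Proportional contents sum to
  100% over *all* ~30 GC-detected FAs, but only 13 are modeled (their means
  sum to ~89%). Rescaling every sample so the modeled FAs sum to a constant
  would be a hard closure on a subcomposition, and closure distorts the
  very correlations the simulator is asked to reproduce (two FAs forced to
  a constant sum are perfectly anti-correlated regardless of the request;
  on the 13-FA default the distortion reaches ±0.49 on individual pairs).
  `draw_compositions()` therefore returns the raw truncated-normal draw,
  which recovers the requested structure within ±0.03 at n = 10⁴, and
  offers closure as an explicit `total =` argument. One visible consequence:
  regression coefficients of PUFA models lack the negative CH₂-band lobes
  (1440 cm⁻¹) that closure induces in real data, and the tests assert
  the closure-free property (C=C dominance) instead.
* **Fat content** defaults to N(18, 3²)% of sample, truncated at 5%, drawn
  independently of the composition — a typical fat range for harvest-size
  Atlantic salmon NQC muscle. No reference fat distribution is published
  for this cohort, so these values are declared, not inferred. An optional
  `fat_correlation` couples fat into the joint Gaussian when a fat–FA
  association is wanted.

## Spectral model

Each FA maps to a band model tied to its chemistry (`default_band_library()`):

* **Raman-like** components use narrow Gaussian bands (FWHM ≤ 25 cm⁻¹):
  unsaturation bands at ~1665 cm⁻¹ (C=C stretch), 1266 cm⁻¹ (=C–H rock) and
  935 cm⁻¹ (alkene C–H deformation) scale with the double-bond count; CH₂
  bands at 1440, 1300, 1122 and 1066 cm⁻¹ scale with a CH₂ proxy
  (chain length − 2·#DB). The C=C position shifts with unsaturation
  (1655 cm⁻¹ for monoenes up to 1667 cm⁻¹ for DHA) and DHA's 935 cm⁻¹ band
  is relatively stronger — the two features that make EPA and DHA
  spectroscopically distinguishable at all.
* **NIR-like** components use broad bands (FWHM ≥ 80 nm) at CH
  overtone/combination positions (1210, 1725, 1760, 2140, 2310, 2350 nm)
  whose positions drift a little with chain length and unsaturation. This
  gives NIR its limited, strongly overlapped FA selectivity.

A replicate spectrum is
`fat/100 · Σᵢ Vᵢ/100 · componentᵢ + (protein + water) · (1 − fat/100)`,
multiplied by a random scatter factor `1 + N(0, scatter_sd)`, plus a random
polynomial baseline and iid noise. Both matrix backgrounds scale with the
lean fraction because water and protein displace fat in muscle; this is
what concentrates NIR variance into very few components (bulk water/protein
/scatter), while the weak Raman backgrounds leave Raman variance spread
over many chemistry-driven components. NIR-reflectance spectra are returned
as `R = 10^(−A)` so the log₁₀(1/R) transform is exercised.

The default study conditions (`salmon_study_config()`): 300 samples,
triplicate spectra, Raman noise SD 0.001 / NIR 0.0012 (intensity units),
scatter SD 0.05 (Raman) / 0.10 (NIR), baseline order 4 (Raman) / 2 (NIR).
The noise levels were calibrated once, while designing the generator, so
that calibrations are good but imperfect (cross-validated R² roughly
0.85–0.95 for the major FAs on Raman-like data), and were then frozen. The
sample size of 300 keeps a full simulate-preprocess-calibrate-diagnose run
in seconds on one CPU while leaving ~43 samples per cross-validation fold.

What the generator does **not** emulate: fluorescence, detector
nonlinearity, instrument line-shape functions, wavelength mis-calibration,
temperature effects on band positions, and water-activity shifts. Passing
tests therefore demonstrate correctness of the algorithms and the
qualitative reproduction of the covariance phenomena, not instrument-level
realism.

## Preprocessing

Two fixed chains, mirroring standard practice; order is recorded in the
`provenance` field of every `spectra_set`:

* **NIR**: reflectance → absorbance (log₁₀(1/R)) → replicate averaging →
  SNV → trim to 1150–2500 nm. Averaging precedes SNV because the triplicate
  average is the measurement unit of the downstream analysis; SNV precedes
  trimming as one defensible fixed order (the alternative order changes
  results only marginally; what matters is that the choice is recorded).
  SNV uses the n−1 sample SD — stated because the n convention differs
  between implementations by a constant factor.
* **Raman**: trim to 500–1800 cm⁻¹ → EMSC with sixth-order polynomial
  extension against a common reference → replicate averaging. The EMSC
  reference is the *grand mean over all replicate spectra*, baseline
  corrected with a fourth-order polynomial. A global reference (rather than
  per-sample references) corrects every spectrum into one common frame,
  which any model-transfer use of the corrected spectra requires.

EMSC decomposes each spectrum as
`z = a + b·ref + Σⱼ dⱼ pⱼ + e` and returns `(z − a − Σ dⱼ pⱼ)/b`. The
polynomial basis uses plain powers of the axis affinely mapped to [−1, 1]:
this conditions the least-squares problem without changing the fitted
subspace. A multiplicative coefficient |b| < 10⁻⁸ raises an error naming
the sample (the spectrum carries no signal in the reference's direction).

## Calibration

PLS1 is implemented from first principles with NIPALS: for each component,
weights `w ∝ Xᵀy`, scores `t = Xw`, loadings `p = Xᵀt/tᵀt`, y-loading
`q = yᵀt/tᵀt`, deflation `X ← X − tpᵀ`. Coefficient vectors are accumulated
for every component count up to `A_max` (default 20 — generous headroom
over the counts the selection rule actually picks), so one fit serves all
model sizes. Channels are centered, never scaled: spectral channels share
units, and variance scaling would inflate noise channels. At full rank the
coefficients equal the least-squares solution, which the tests verify
against `lm()`, and predictions are cross-checked against an independent
PLS implementation (mixOmics) to 10⁻¹⁰.

Cross-validation uses seven-fold *venetian blinds*: sample `i` (dataset
order) goes to fold `((i−1) mod 7) + 1`. The interleaved assignment is the
standard choice when acquisition order is already randomized; a seeded
shuffle is available but off by default. R²_cv uses the total sum of
squares about the *global* mean of y (not per-fold means) — conventions
differ, so this is stated. Component selection offers the global
RMSECV minimum (default) and a parsimonious rule (smallest count within
1 + tol of the minimum, tol = 0.01); the exact rule used by any given
study is rarely reported, so both are exposed and logged.

## Variable selection

* `region_retrain()` refits on user-supplied axis windows and keeps the
  restricted model only if its best RMSECV strictly improves on the
  full-spectrum baseline (ties keep the baseline). Sensible NIR windows are
  the CH overtone/combination regions around 1700–1800 nm and 2250–2400 nm,
  but the choice is analysis-specific and deliberately left to the caller.
* `bottom_up_select()` partitions channels into consecutive blocks of 100,
  keeps the best single block (lowest minimum RMSECV over component
  counts), then repeatedly adds the best remaining block while the minimum
  RMSECV improves by more than `tol` (default 0: strict improvement).
  "Performance" is minimum RMSECV — the standard cross-validation loss —
  with the R² trace logged alongside; the component count is re-optimized
  for every candidate because candidate sets differ in dimensionality, and
  a fixed count would bias against small selections. Ties between candidate
  blocks break to the lower block index, so the procedure is deterministic
  given the fold assignment. The last, possibly shorter, block is a
  candidate like any other.

## Diagnostics

* `explained_variance_curves()`: cumulative variance of the top components
  of each mean-centered data block via SVD. On the default conditions the
  reference block is low-dimensional (≥ 95% by component 6), the NIR block
  is dominated by bulk signals (≈ 99% by component 3), and the Raman block
  needs many components — the qualitative signature distinguishing the
  modalities.
* `cage_analysis()`: for each FA, cross-validated models are trained on
  absolute contents (% of sample) and proportional contents (% of total
  FA), and each prediction is also converted through the measured fat
  content to the other scale. On data generated as fat × composition with
  fat independent of composition, absolute models are largely fat models:
  their predictions correlate strongly with fat (> 0.5, typically ~0.9),
  while proportional models' predictions are essentially uncorrelated with
  fat, and converting proportional predictions *to* absolute (× fat)
  outperforms converting absolute predictions to proportional (÷ fat).
  This is the practical lesson of the cage: calibrate on proportional
  contents even when absolute contents are the end goal.
* `covariance_inflation()`: mean absolute off-diagonal correlation among
  predicted FA columns divided by the same quantity among the references.
  Exactly 1 for perfect predictions; > 1 when truncated models exaggerate
  the reference covariance. The published inflation statistic is not
  defined precisely anywhere, so this declared convention uses correlations
  (scale-free); the raw-covariance variant is attached as an attribute. At
  the package's desk-scale conditions the Raman models select few
  components (3–5), so inflation is substantially larger than the ~8%
  reported for 618-sample studies with 7–15-component models — fewer
  retained components mean a tighter cage.
* `coefficient_profile()`: unit-norm regression coefficients paired with
  the axis, for band-level interpretation. EPA/DHA models on the default
  conditions are dominated by the C=C stretch region around 1665 cm⁻¹.

## Numerical choices and degenerate inputs

* Correlation matrices are repaired to PSD only when the most negative
  eigenvalue exceeds −10⁻⁸ (clipped to zero, diagonal rescaled); anything
  worse is an inconsistent request and errors with the eigenvalue.
* Truncation at zero in the composition draw is by rejection; with the
  salmon defaults rejections are essentially impossible (means are > 4 SD
  above zero), so the truncation never distorts the structure in practice.
* A PLS component whose weight norm falls below 10⁻¹² truncates `A_max`
  with a warning; a zero-variance response, a constant spectrum under SNV,
  nonpositive reflectance, and an EMSC reference collinear with the
  polynomial basis all raise errors naming the offending sample/channels.
* Zero-variance columns yield `NA` correlations with a warning — never a
  silent 0.
* All simulation entry points take integer seeds; the pipeline derives
  per-stage seeds from one global seed by fixed small offsets (kept below
  2³¹), so stages can be re-run in isolation and identical configs
  reproduce outputs bit for bit.

## Problem sizes

The shipped tests and the acceptance script run the full study at n = 300
samples (13 FAs, triplicate spectra, 1301 Raman channels, 676 NIR
channels), plus Monte-Carlo checks at n = 10⁴ for the composition
structure. These sizes were chosen so a complete run takes seconds on a
single CPU while every qualitative contrast of interest (modality
complexity, cage behaviour, selection localization) is stable across
seeds.

## Limitations

The simulator is a linear mixture model with Gaussian noise; it cannot
probe nonlinear matrix effects, and its band library is a stylized
13-component chemistry. Conclusions about *algorithms* (preprocessing
identities, PLS/CV correctness, selection behaviour, cage mechanics)
transfer directly to real data; conclusions about *achievable accuracy* on
real muscle spectra do not. The confidence procedures sometimes used to
compare R² between modalities are deliberately out of scope — no method is
implemented rather than a guessed one.
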