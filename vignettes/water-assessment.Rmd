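---
title: "Uncertainty-aware optical water assessment with aquaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware optical water assessment with aquaspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaspec)
```

## The measurement problem

Cyanobacterial (blue-green algae) and green-algal blooms in surface waters
are an ecological and public-health hazard. A submersible optical probe can
watch for them continuously: it records four spectra per water sample on a
shared 225–900 nm grid (1.5 nm step) — UV/Vis transmission, fluorescence
under 440 nm and 590 nm LED excitation, and 90° scattered light under
850 nm excitation. Chlorophyll fluoresces near 680 nm under 440 nm
excitation and is common to green algae and cyanobacteria; phycocyanin,
fluorescing near 650 nm under 590 nm excitation, is specific to
cyanobacteria and serves as the blue-green marker. Scattered light at
850 nm measures turbidity (in FNU), which both matters in itself and
contaminates the UV/Vis channel.

Field spectra carry substantial measurement uncertainty — temperature
drift, turbidity, matrix effects, lamp variation. `aquaspec` implements a
processing chain that treats that uncertainty explicitly: preprocessing
removes the systematic effects it can model, full-spectrum conformity
features condense each channel into a shape-match score, and a fuzzy
pattern classifier widens its class boundaries by the expanded measurement
uncertainty of the features, so that an observation is never forced into a
crisp decision its precision cannot support.

## Preprocessing

Per modality the chain is: blank handling, temperature normalization,
zero-phase smoothing, then (UV/Vis only) turbidity compensation.

**Blank handling.** Each sample is paired with a pure-water blank. The
UV/Vis channel converts to absorbance by Beer–Lambert,
$A(\lambda) = \log_{10} I_0(\lambda)/I(\lambda)$ (base 10, the absorbance
convention). Emission channels subtract the blank,
$F(\lambda) = I(\lambda) - I_0(\lambda)$; negative values are kept, since
they carry information for filtering, and a systematic negative baseline
shift (seen with some LED configurations) is corrected by subtracting the
5th percentile — but only when it is more negative than three times the
noise scale. The significance gate matters: the 5th percentile of zero-mean
noise is itself about $-1.6\sigma$, and "correcting" it would bias every
weak spectrum upward.

**Temperature.** The instrument response drifts with temperature,
differently per light source. Spectra are normalized to the 21.3 °C
reference by a multiplicative factor, modelled linearly:
$f(T) = 1/(1 + s_m (T - 21.3))$ with per-modality slopes $s_m$ (defaults
0.4–1.0 %/°C, the magnitude of LED output drift; real deployments should
supply their own calibrated slopes via `temperature_model()`). The model is
trusted up to 30 °C; beyond that the correction is still applied but the
spectrum is flagged, since non-linear thermal effects may dominate.

**Smoothing.** A 30th-order linear-phase FIR low-pass (windowed-sinc,
Hamming window; passband 0.1 f_s, stopband 0.3 f_s, cutoff midway) is
applied forward and backward, so the net phase is zero and peak positions
are preserved exactly; the effective magnitude response is the squared
single-pass response. Edges are handled by odd-symmetric extension of
three filter lengths. A consequence worth knowing: odd extension anchors
the first and last samples to the data (exactly as MATLAB's `filtfilt`),
so attenuation guarantees hold in the interior, not at the two endpoints.

**Turbidity.** Turbidity in FNU is the mean blank-subtracted intensity in
the 850 ± 15 nm scatter band divided by a calibration slope
(counts/FNU). Its apparent-absorbance contribution is removed from the
UV/Vis spectrum as $A_{corr}(\lambda) = A(\lambda) - \mathrm{FNU} \cdot
p(\lambda)$ with a $1/\lambda$ profile normalized at 850 nm. The
compensation is valid to about 20 FNU; above that (multiple scattering)
results carry a low-confidence flag. A limitation inherent to single-band
estimation: substances that themselves scatter at 850 nm (concentrated
extracts do) are partly attributed to turbidity and slightly
over-compensated. The conformity features are robust to this because the
references are built through the same chain, but absolute absorbance
accuracy below 5% relative RMS is only guaranteed for non-scattering
analytes.

## Full-spectrum conformity features

Each substance/modality pair gets a reference spectrum modelled as a
scaled Gaussian sum,
$$A_{ref}(\lambda) = k \sum_{i=1}^{N} a_i \exp\!\left(-\frac{(\lambda - \lambda_i)^2}{c_i}\right),$$
built by iterative peak fitting: locate the most prominent local maximum,
least-squares-fit a Gaussian within ±3σ of it, subtract, repeat until the
residual is almost flat (maximum below 2% of the original) or no peak is
significant. A peak is significant when its prominence exceeds five times
the noise scale estimated from first differences; five (rather than a
smaller multiple) is needed because the most prominent of the ~150 local
maxima in a pure-noise record of this length regularly exceeds three times
the noise scale. Residual RMS is guaranteed non-increasing across
iterations; an iteration that fails to decrease it is rejected.

An unknown spectrum is scored against a reference by fitting the scale $k$
in closed form (least squares) and reporting the coefficient of
determination $R^2 = 1 - SS_{res}/SS_{tot}$ over the **full** wavelength
grid — a shape-conformity measure that is invariant to intensity scale
(so it measures "is this substance present", not "how much"). Poor fits
(negative raw values) are floored to 0 by convention. The default feature
vector scores fl440 and UV/Vis against the spinach-extract (chlorophyll)
references, fl590 against the phycocyanin reference, and sc850 against the
turbidity-standard scatter reference, and carries the turbidity estimate
itself (normalized by the 20 FNU validity bound) as a fifth feature.

The default library is built from clean mid-concentration standards (25%
spinach dilution, 85 mg/L phycocyanin, a 10 FNU turbidity standard):
mid-range spectra have fully developed band shapes without saturation, and
because conformity is scale-invariant the choice of level within the clean
range is not critical.

## Measurement uncertainty and the fuzzy classifier

Standard uncertainties combine by root-sum-of-squares and expand with a
coverage factor (default $k_{cov} = 2$, ~95% coverage). For this
measurement system the expanded uncertainty of the conformity features is
$U_{R^2} = 5.90\%$ for UV/Vis and $7.11\%$ for the fluorescence and
scattered-light channels; these are configuration constants of the
package (the full sensitivity budget behind them belongs to the
instrument's metrological characterization, not to this package). The
turbidity feature, deriving from the scattered-light channel, uses the
7.11% value by default.

Each of six expert classes — blue algae, green algae, moderate turbidity
(2–10 FNU), high turbidity and/or foreign substances (10–20 FNU), another
unknown substance, no detectable substance — is a multidimensional fuzzy
set built from one-dimensional Aizerman potential functions
$$\mu(x) = \frac{a}{1 + \left(\frac{1}{b_s} - 1\right)\left(\frac{|x - x_0|}{c_s}\right)^{d_s}}, \qquad s = \begin{cases} l & x < x_0 \\ r & x \ge x_0\end{cases}$$
with the conventional parameters $a = 1$, $b_{l/r} = 0.5$, $d_{l/r} = 2$.
Training derives, per class and dimension, $x_0$ as the class mean and the
scopes from the member spread widened by the expanded uncertainty:
$c_l = (x_0 - \min x) + U$, $c_r = (\max x - x_0) + U$. Even a singleton
class is thus exactly as wide as the measurement uncertainty — the sense in
which the classifier "knows" how precise its inputs are. Dimensions
aggregate by the N-fold compensatory mean
$\mu_\cap = \frac{1}{N}\sum_i \mu_i$ (idempotent, bounded by the
per-dimension extremes; the aggregation rule is pluggable). A sample is
assigned to the class of maximum membership; exact ties resolve to the
earlier class in the report order and are flagged. Because $\mu > 0$
everywhere, every sample gets a graded membership to every class — a
competing class above 0.4 (configurable) is reported as a secondary-class
alert, the numeric form of "elevated blue-green levels warrant a warning".

**Dimensionality.** The classifier is data-driven in its feature order.
The default pipeline uses five dimensions (four conformity features plus
normalized turbidity): with the plain compensatory mean and $a = 1$, four
R² dimensions alone cannot produce the high memberships observed for
samples whose 590 nm feature is zero, while a fifth, turbidity-like
dimension resolves this — turbidity is also the natural fifth observable
the instrument produces. Published field feature tables that print four
features per object are evaluated with a four-dimensional classifier
trained on the same corpus.

## The synthetic-data generator

No public spectra exist for this instrument class, so the generator is
first-class, tested code that emulates it: per modality a blank (lamp
envelope or stray-excitation background) plus a sample adding substance
bands, turbidity contributions, the thermal response, and Gaussian counts
noise (default σ = 50 counts) with 2% replicate-to-replicate gain jitter,
clipped at the 40,000-count ceiling. Band tables come from standard
pigment spectroscopy: chlorophyll emission at 680/735 nm; C-phycocyanin
emission at 650/710 nm, modelled as a commercial extract with a trace
chlorophyll-type impurity (670 nm emission under 440 nm excitation, kept
below 10% of the 590 nm response; trace 430/675 nm absorbance) — pigment
extracts are never spectrally pure, and cyanobacterial material always
carries chlorophyll; uranine with 238/322/490 nm absorbance and strong
515 nm emission; and broad UV protein/organic absorbance (~270–280 nm)
for the extracts, without which dissolved organics would be invisible to
the UV/Vis conformity feature. Dissolved extracts also scatter weakly at
850 nm. The default training corpus mirrors the reference campaign: 40
spinach spectra (0.25–40% dilution), 22 phycocyanin (10–700 mg/L), 12
moderate-turbidity (2–10 FNU), 12 high-turbidity (10–20 FNU), 11 pure
water, 22 uranine (0.5–20 mg/L), at a nominal 22 °C — 119 labeled bundles.
One master seed drives per-bundle sub-seeds, so corpora are
bit-reproducible.

What the generator does *not* emulate: excitation–emission matrix
structure, inner-filter effects, stray light beyond a fixed excitation
line, multiple scattering above 20 FNU, biofouling, and drift over time.
Passing tests therefore demonstrate that the chain is internally
consistent and recovers what it models — not that the band tables match
any particular real instrument.

## Numerical choices and degenerate inputs

* Non-positive UV/Vis sample counts are clipped to a small epsilon before
  the log ratio and flagged; a blank with non-positive counts is a
  calibration error.
* Saturation (≥ 40,000 counts, configurable) flags a spectrum; a saturated
  scatter band refuses to yield a turbidity estimate rather than return a
  silently wrong one.
* `R^2` is clamped to [0, 1]; an all-zero reference evaluation is a
  degenerate-reference error; a constant spectrum has zero total sum of
  squares and scores 0.
* Gaussian fits run on a ±3σ window around each peak to decouple
  overlapping bands; width starts from the half-maximum crossing. Fits are
  bounded (amplitude > 0, width above a quarter grid-step squared).
* Resampling is linear interpolation and refuses extrapolation; all
  downstream math runs on the common 225–900 nm grid.
* Model and reference JSON is written with 17 significant digits, which
  round-trips IEEE doubles exactly.

## Worked-example scale and known limitations

The test suite and the acceptance script train on the 119-bundle corpus
and validate against a same-size held-out corpus — the full study scale,
which runs in seconds. Known limitations, beyond the generator scope
above: the turbidity/substance-scatter ambiguity already described;
class boundaries shared by construction (the moderate/high turbidity
split at 10 FNU) leave genuinely ambiguous samples near the boundary; and
membership values for the published field campaigns depend on the feature
distributions of the original training spectra, which are not public — a
classifier trained on the synthetic corpus reproduces the published class
assignments and the ordering of memberships, but not every printed
membership value.
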