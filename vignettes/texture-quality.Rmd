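---
title: "Texture-based quality auditing of grayscale MR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based quality auditing of grayscale MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Whether a higher-field MR scanner really captures more diagnostic detail
than a lower-field one cannot be settled by looking at the images: to the
naked eye, well-windowed 1.5 T and 3 T slices of the same anatomy are
often indistinguishable. `mritexture` implements an objective,
region-of-interest (ROI) based comparison built entirely from first-order
texture statistics and wavelet subband energies, together with the
bit-depth auditing needed to know how much dynamic range an image really
contains — as opposed to what its DICOM header claims.

The pipeline is: audit the pixel container (measured vs reported stored
bits), extract per-ROI histogram features and Haar subband energies,
derive two scalar quality indices from them, place each ROI as a point in
a three-dimensional feature space, and quantify how well the four
anatomical classes (ventricles, thalamus, grey matter, white matter)
separate with a between-class/within-class variance ratio and a
leave-one-out 1-nearest-neighbour error. Patient data are replaced
throughout by a synthetic labeled phantom.

## Features and indices

For a pixel sample $x_1,\dots,x_n$ the package uses *population* moments:
$\mu = \tfrac1n\sum x_i$, $\sigma^2 = \tfrac1n\sum(x_i-\mu)^2$, skewness
$\gamma_1 = m_3/\sigma^3$ and *excess* kurtosis
$\gamma_2 = m_4/\sigma^4 - 3$. These match the conventions of the MaZda
texture-analysis family of tools. A constant sample has $\sigma^2 = 0$
and *undefined* shape moments — they are flagged as such, never silently
zeroed, and downstream indices refuse them. Whether kurtosis should be
raw or excess is genuinely ambiguous in this field; excess is adopted
(the MaZda manual convention) and only affects focus-index magnitudes,
not any of the tabulated group statistics, which are computed from index
values directly.

Two derived indices drive the quality comparison:

* **Focus index** $= \gamma_1 / \gamma_2$. An undistorted, in-focus
  texture scores near zero. Samples outside the closed interval
  $[-1, +1]$ behave like random quantum mottle and are excluded by
  `filter_by_focus()`; the interval is closed because the boundary values
  are explicitly described as acceptable. The ratio is refused when
  $|\gamma_2| \le \varepsilon$ (default $\varepsilon = 10^{-12}$), since
  near-mesokurtic samples make it numerically meaningless.
* **Dispersion index** $= \sigma^2/\mu$ (variance-to-mean ratio), in
  intensity units. Larger spread between per-region values indicates
  better discriminability of neighbouring structures. It requires
  $\mu > 0$.

The wavelet feature is the mean squared coefficient of the orthonormal
Haar HL subband (`wavenhl`): high-pass along x, low-pass along y, i.e.
a vertical-edge response. The transform uses the filters
$(1,1)/\sqrt2$ and $(1,-1)/\sqrt2$ and recurses on LL for deeper scales;
orthonormality gives a Parseval identity that the tests assert. Because
the mapping from an arbitrary ROI to a dyadic grid is not standardised,
the package computes the transform over the largest
$2^{\text{scale}}$-aligned square centred in the ROI's *bounding box*.
For non-convex regions (the ventricle crescents) this window deliberately
includes region boundaries, so `wavenhl` picks up the edge content that
makes regions distinguishable — the "fingerprint" role of this feature.
The window policy is recorded in every `wavelet_energies()` result.

## Bit-depth auditing and 8-bit degradation

The measured usable bit depth of an image is the smallest $b$ such that
$\max(\text{pixels}) \le 2^b - 1$ (an all-zero image measures 1 bit by
convention). This max-value reading matches how grey-level counts such as
4096 or 65,536 are reported for 12- and 16-bit acquisitions; the count of
occupied levels is also reported for diagnostics, but headers are never
trusted: a 16-bit container that only ever reaches 4095 is a 12-bit image
with four padded bits, and the audit flags the discrepancy.

Down-conversion to 8 bits (`to_8bit`) shifts away least-significant bits:
$v_8 = v \gg (b - 8)$ with $b$ the *measured* depth, so a padded header
cannot distort the conversion. A linear rescale mode is provided for
comparison; a constant image rescales to all zeros with a warning rather
than dividing by zero. Acquisition-criteria filtering
(`check_acquisition_criteria`) uses closed intervals — slice thickness
3–5 mm, repetition time 800–2100 ms, echo time 1–95 ms, imaging
frequency 60–130 MHz, pixel bandwidth 400–1200 Hz — and absent tags are
reported as "unverified" rather than failing the check, since absence of
a tag is not evidence of a violation.

## The feature-selection coefficient and 1-NN error

Class separation over a feature matrix with classes $k = 1..K$ is scored
by

$$F \;=\; \frac{D^2}{V^2} \;=\;
\frac{\frac{1}{1-\sum_k P_k^2}\sum_k\sum_j P_k P_j\,\lVert\mu_k-\mu_j\rVert^2}
     {\sum_k P_k V_k^2},$$

with $P_k = n_k/N$, class centroids $\mu_k$, and population within-class
variance $V_k^2 = \tfrac{1}{n_k}\sum_i \lVert x_i - \mu_k\rVert^2$.
Distances are multivariate Euclidean over the full feature vector (the
trace form) and the within-class variance is pooled to a scalar; this
combination reproduces the worked control-point example exactly (F
rounding to 18), which is how it was validated. A per-feature univariate
mode (`fisher_per_feature`) is available for ranking. Internally $D^2$
uses the moment identity
$\sum_{kj} P_k P_j \lVert\mu_k-\mu_j\rVert^2 =
2\bigl(\sum_k P_k\lVert\mu_k\rVert^2 - \lVert\bar\mu\rVert^2\bigr)$;
the test suite checks it against the explicit double loop.

When every class is internally constant, $V^2 = 0$ and $F$ is capped at
a configurable `f_max` (default $10^6$) with a `capped` flag — reference
implementations disagree on the printed cap value, so it is configurable
and never part of any asserted result.

Classification error is leave-one-out 1-nearest-neighbour: each sample is
assigned the class of its nearest Euclidean neighbour among the remaining
samples (ties broken toward the lowest sample index), and the
misclassified-data-error (MDE) is the misclassified percentage.
Leave-one-out (not resubstitution) is required to reproduce the 25%
worked example: a singleton-like displaced control point finds its
nearest neighbour in the wrong class. Feature standardization is off by
default, matching the RAW analysis convention; when enabled,
zero-variance features are dropped with a warning.

Control points `control_points()` bound the feature space before the
analysis: $C_{min} = (0,-1,0)$ and $C_{max} = (5500, 1, 120000)$ for the
3 T preset, $C_{max} = (307, 1, 120000)$ for 1.5 T — only the dispersion
axis differs. Two replicates of each control are injected
(`add_controls`); two is the smallest count that makes the controls
behave as proper classes under leave-one-out, and it reproduces both
printed control results (capped F with 0% MDE unperturbed; F ≈ 18 with
25% MDE when one $C_{max}$ is displaced to $(0,-1,60000)$).

## Group statistics

The group-comparison module (`select_best`, `pooled_t_test`,
`summary_table`, `roi_variability`) deliberately switches to *sample*
(n−1) statistics, the convention of the tabulated group results it
reproduces. "Best nine" selection keeps the nine focus values closest to
the ideal of zero, and the nine largest dispersion values; both criteria
are configurable, and were inferred from the ideal-focus definition and
the descending order of the printed dispersion columns. The two-sample
test is the pooled (equal-variance) t with $df = n_a + n_b - 2$; pooled
rather than Welch because the printed $df = 16$ equals $9+9-2$ and the
pooled form reproduces all four printed t values from the bundled
columns. The t sign convention is 1.5 T minus 3 T. One printed standard
deviation (3 T, second age group, dispersion) is inconsistent with its
own printed column — the recomputed sample sd is ≈ 1222, and the printed
t of −5.6 is consistent only with the recomputed value — so the package
reproduces the columns and the t statistic and treats that printed sd as
a transcription artefact.

## The synthetic phantom

`generate_phantom()` emulates the statistical structure the analysis
assumes, not MR physics. The geometry is a fixed elliptical layout in
normalised coordinates (a documented constant, not a contract): a brain
ellipse with a cortical grey-matter rim, white matter filling the
interior, a central thalamic ellipse and two ventricle ellipses above it.
Pixels are region mean + Gaussian noise, blurred in floating point
*before* quantisation (acquisition blur precedes digitisation; noise is
added after the blur, as receiver noise follows the point-spread
function), clipped to the stored-bit range and rounded. `"zero_msb"`
padding stores values as-is inside the larger container; `"shift_lsb"`
left-shifts them into the most significant bits — both padding
interpretations exist in the wild and the audit treats them identically
through the max-value measurement.

The two presets fix the study conditions: `t1p5` is a 256 × 256 matrix
with 12 stored bits and `t3` a 446 × 446 matrix with 16 stored bits.
Fractional region means are matched between presets (ventricles 0.85,
white matter 0.65, grey matter 0.50, thalamus 0.40 of full scale, a
T2-like contrast ordering). Relative noise is 3% of full scale at 1.5 T
versus 1.5% at 3 T, and both share a 1-pixel acquisition blur; the noise
fractions are this package's choice of a realistic SNR disadvantage for
the lower field strength, set once when the generator was written. Each
call seeds its own RNG stream and restores the caller's state, so a spec
is bit-reproducible and never perturbs session randomness.

What the phantom does *not* emulate: anatomical texture within regions
(regions are flat apart from noise), partial-volume effects, bias
fields, motion artefacts, or any TR/TE contrast mechanism. Passing the
seeded comparison therefore shows that the pipeline detects the
resolution/noise/dynamic-range differences it was designed to detect —
not that real 3 T acquisitions are superior; that claim would need the
original cohort.

## Problem sizes and determinism

The seeded two-modality comparison (`compare_modalities_fisher`) uses 20
replicate runs of 8 phantoms per modality, i.e. 32 ROI samples per
feature matrix — enough for the four-class F to stabilise while keeping
a full run under a minute on one core. Sub-seeds are derived from the
base seed with fixed prime multipliers, kept below $2^{31}-1$. All
tolerances asserted in the tests are stated there: oracle agreement at
relative $10^{-9}$, Poisson dispersion within $[0.95, 1.05]$ at
$n = 50{,}000$, and exact equality for the worked examples after their
printed rounding.

## Limitations

* DICOM support is deliberately minimal: single-frame monochrome,
  uncompressed little-endian syntaxes only; everything else raises an
  explicit unsupported-format error.
* The focus index is a ratio of two noisy, near-zero shape moments on
  Gaussian-like samples and is accordingly heavy-tailed; this is a
  property of the index itself, and is why the retention filter and the
  undefined-index guards exist.
* The elliptical phantom geometry makes no claim to anatomical accuracy;
  ROI placement in the original study is not recoverable.
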