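---
title: "Methods: band assignment, similarity and seasonal chemometrics for seaweed FTIR-ATR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band assignment, similarity and seasonal chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycospec)
```

## The measurement and the model

An FTIR-ATR absorbance spectrum of a polysaccharide extract is a sum of
overlapping absorption bands riding on a slowly varying baseline, plus
instrument noise. Each band belongs to a vibrational mode of a structural
unit: in carrageenans, the sulfate-ester S=O stretch near 1240 cm⁻¹, the
3,6-anhydrogalactose bands (DA near 930 cm⁻¹, its 2-sulfate DA2S near
805 cm⁻¹ with a shouldered companion DA2S* near 905 cm⁻¹), the galactose
backbone G/D near 970 cm⁻¹ and its sulfated variants (G4S near 845, G/D6S
near 817, G/D2S near 827, the shouldered G/D6S* near 867 cm⁻¹). Fucoidans
are marked by S=O (1220), O=S=O (1020) and C-O-S (820 cm⁻¹); alginates by
C-C/C=O (1600), C-OH (1410), the 1081 and 797 cm⁻¹ guluronic-acid bands and
O=S=O (1026 cm⁻¹).

`phycospec` models the analysis, not the physics: bands are treated as
pseudo-Voigt profiles (Lorentzian fraction `eta`), the baseline as a smooth
additive nuisance, and the diagnostic knowledge as a *band library* — one
row per structural unit with a nominal center, a tolerance window, the
colloid types it indicates, whether it usually appears as a shoulder, and
whether it is specific to a subset of types. Libraries are versioned
plain-text CSVs under `inst/extdata/` so they can be audited and extended.

Band windows are the library's empirical tolerance for where an apex may
wander: ±8 cm⁻¹ around single-valued nominal centers, literature ranges
widened by ±4 cm⁻¹, and windows further widened where reported standard
positions demanded it (the S=O apex of commercial standards sits 15–22 cm⁻¹
below the 1240 cm⁻¹ textbook value, so its window is [1210, 1270]; the DA
window reaches down to 917 cm⁻¹ and DA2S* to 888 cm⁻¹ for the same reason).

## Conditioning

All operations assume ascending wavenumber storage; descending instrument
exports are reversed on read.

* **Cropping** is closed-interval (`lo <= w <= hi`), matching the way
  analysis windows are quoted in the application literature.
* **Baseline**: Eilers' asymmetric least squares — minimize
  `sum(w_i (y_i - z_i)^2) + lambda * sum((Δ²z)_i^2)` with `w_i = p` above
  the curve and `1 - p` below, 10 reweighting iterations. Defaults
  `p = 0.01`, `lambda = 1e6` on the canonical 0.482 cm⁻¹ grid. The penalty
  is defined on index space, so `lambda` trades off against grid density:
  at this spacing, `1e6` keeps the apex of an isolated 12 cm⁻¹-wide band
  within 1% of its true height while still tracking drifts of
  10⁻⁴ AU/cm⁻¹ (a stiffer `1e5` costs ~3% of apex height, which would leak
  into the low-intensity assignment logic, so the softer-drift default was
  chosen).
* **Normalization**: SNV (per-spectrum mean 0, SD 1 over the window) is the
  default before similarity scoring and PCA because ATR contact pressure
  and effective pathlength scale the raw absorbance arbitrarily; SNV makes
  all downstream statistics invariant to `a*x + b` with `a > 0`.
* **Savitzky–Golay**: 21 points (~10 cm⁻¹) and polynomial order 3, for both
  smoothing and the second derivative used by shoulder detection. Narrower
  filters pass more noise; wider ones flatten the weak shoulders the
  assignment table cares about.

## Peak and shoulder detection

Apexes are strict local maxima whose *topological prominence* (height above
the higher of the two separating valleys) reaches 2% of the window's
absorbance range; their positions are refined by 3-point parabolic
interpolation, which keeps the position error of an isolated noise-free
band below half a grid step (0.24 cm⁻¹) across the diagnostic region.

Shoulders are partially resolved bands that produce no local maximum, only
an inflection: they are recovered as local minima of the Savitzky–Golay
second derivative with magnitude at least 10% of the window's largest, and
only outside the derivative filter's half-support (10 grid steps) of any
accepted apex — curvature structure closer to an apex than the filter can
resolve belongs to that apex, not to a separate band.

On noisy input, both detectors additionally require features to clear five
times an externally supplied noise standard deviation (`noise_sd`). The
`classify_spectrum()` wrapper estimates that floor robustly from the
smoothing residual (`mad(raw - smoothed)`, scaled by the filter's variance
gain), which suppresses the spurious 1–3-point bumps that would otherwise
satisfy windows of bands genuinely absent from the sample.

## Assignment and classification

`match_bands()` pairs detected peaks with library bands: only in-window
peaks are eligible, each band takes at most one peak and each peak
satisfies at most one band, nearest-to-center wins with ties broken toward
the lower wavenumber, and shoulder-expecting bands prefer shoulder matches
over apexes. After matching, a matched peak whose height is below 8% of
the tallest matched height is demoted to `present_low` — the `"+"` cell of
a conventional peak-identification table; unmatched bands render `"-"`.

Carrageenan typing then follows the sulfation chemistry rather than a bare
band count, because κ-carrageenan has no band that ι lacks:

* the ι-unique 2-sulfated anhydrogalactose bands (DA2S, DA2S*) define ι
  evidence;
* the anhydro bands (DA, DA*) are shared between ι and κ and count toward
  κ *only when no ι-unique band is present* — anhydro plus 2-sulfate is ι,
  anhydro alone is κ;
* ν evidence comes from G/D2S, G/D6S and the 867 cm⁻¹ G/D6S* shoulder.
  G/D6S* matches far from 867 cm⁻¹ (the 871–874 cm⁻¹ region, where both
  commercial standards show a weak sulfate feature) are ambiguous and count
  half.

Matched bands weigh 1, `present_low` entries 0.5. The dominant type is the
strictly largest score; at least two types scoring ≥ 1 declares a
`mixture`; no evidence at all gives `undetermined`. A consequence worth
stating: an ι+κ mixture is indistinguishable from pure ι in this scheme
(every κ band is also an ι band), which matches the practical limit of
infrared typing — resolving such hybrids needs NMR.

Colloid family is decided by the fraction of each library's marker bands
matched (weak presences counting half); ties — e.g. a genuine
alginate+fucoidan co-extract matching both marker sets completely — return
`undetermined` rather than an arbitrary winner.

## Similarity

`similarity_percent()` is `100 * max(0, r)` with `r` the Pearson
correlation of the two traces after identical conditioning (common grid,
baseline correction, SNV) over the chosen window. Commercial library-search
"match" values are proprietary; this score is an open analog with the same
qualitative behavior (self-match 100, unrelated colloids near 0, noise
degrading the score monotonically), not a numerical replica, and the result
object records the window and point count it was computed on.

## PCA and seasonal grouping

`pca_fit()` mean-centers the samples-by-wavenumbers matrix and computes
PCA without unit-variance scaling of the wavenumber variables (scaling
would inflate baseline regions into the components). Explained variance is
reported against the total variance of the conditioned data, so the
percentages of the retained components sum to at most 100. Component signs
are canonicalized (largest-magnitude loading element positive), making
scores reproducible across sample orderings and linear-algebra backends.

Published seasonal analyses argue grouping from score plots; to make that
claim testable, `season_separation()` computes silhouette widths on
Euclidean distances in the space of the first `n_components_used` scores.
Singleton groups get silhouette 0 and are flagged rather than dropped.

## The simulator: what it emulates, what it does not

`simulate_spectrum()` draws pseudo-Voigt bands (`eta = 0.3`; FWHM 12 cm⁻¹,
widened to 16–18 cm⁻¹ for shouldered bands and broad envelopes) at the
positions reported for the commercial ι- and κ-carrageenan standards and
the fucoidan/alginate marker sets, with three relative height tiers
(1.0 / 0.5 / 0.25 for strong / medium / weak-shouldered) — two tiers plus a
detectability gap are the minimum structure needed to exercise the
matched / `+` / `-` distinction. On top of the bands it adds per-band
center jitter, multiplicative height noise, a smooth random cubic baseline
drift, and white Gaussian noise, all on the canonical 0.482 cm⁻¹
acquisition grid over 400–4000 cm⁻¹, in monthly triplicates.

Two study designs ship with the package. `solieria_2014` (12 months × 3
replicates) plants pure ι composition in September–December and adds a
ν-precursor trace (weight 0.35) plus an amide/protein background (0.3) in
January–August; `sargassum_2015` (February, April, June, October × 3)
varies the alginate/fucoidan balance across the four seasons. In both, the
between-season composition shifts are roughly five times the within-month
dispersion (height CV 0.07, jitter SD 0.5 cm⁻¹, noise SD 0.01 AU, drift
0.02 AU) — the regime in which seasonal score plots show the clearly
separated clouds reported for these systems. Master seeds are fixed per
design, and per-spectrum seeds derive from a stable hash of
(month, year, replicate), so extending a design never perturbs existing
draws.

The simulator does **not** model ATR penetration-depth dispersion,
water-vapor rotational lines, CO₂ bands, detector nonlinearity, or the
biochemical covariance of real extracts (e.g. protein contamination
correlating with season). Passing the package's tests therefore
demonstrates that the *analysis chain* is correct and robust to the modeled
noise processes — not that any particular field sample will classify
correctly.

## Numerical choices and degenerate inputs

* Grids must be strictly increasing; derivative and detection steps require
  uniformity (checked at 10⁻⁶ relative tolerance) and direct the user to
  `resample_to_grid()` otherwise.
* Resampling is linear interpolation with no extrapolation.
* SNV of a constant trace, similarity of a constant-after-conditioning
  trace, PCA of fewer than three spectra, and empty crop windows raise
  errors naming the offending condition; batch operations attach the sample
  id to propagated failures.
* All-zero compositions are rejected at profile construction; a zero-weight
  component contributes no bands and no ground-truth rows.
* Matching ties are broken deterministically (nearest center, then lower
  wavenumber); classification ties below the mixture threshold are reported
  as `mixture` rather than resolved arbitrarily.

## Problem sizes used in validation

The shipped test suite validates detection/assignment round trips on
noise-free standards (full 7469-point canonical grid), classifier recovery
on 200 noisy draws (noise SD 1/30 of the strongest band, i.e. SNR 30, plus
50 extra ι-only draws), similarity properties on 5 noise levels × 50 draws,
and seasonal separation on the 36-spectrum `solieria_2014` design with 20
label shuffles. These sizes were chosen to exercise each statistical claim
with comfortable margins while keeping the whole suite near half a minute
on a single core.

## Known limitations

* λ-carrageenan is representable in a library but no typing rule ships for
  it — its spectrum lacks the anhydro bands this scheme pivots on.
* Hybrid carrageenan quantitation (how much ν in an ι background) is out of
  scope; the monotone response of the 867 cm⁻¹ band height to the ν weight
  is verified, but no calibration curve is provided.
* The similarity score is an analog of, not a replacement for, instrument
  library-search values; absolute percentages are not comparable across
  software.
* JCAMP-DX support covers AFFN-encoded XYDATA/XYPOINTS only (no SQZ/DIF
  compression, no proprietary binary formats).
* Input absorbance is taken as-is; no ATR correction or atmospheric
  compensation is applied.
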