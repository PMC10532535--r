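# phycospec

FTIR-ATR characterization of seaweed phycocolloids in R.

Red and brown macroalgae build their cell walls from gel-forming sulfated
polysaccharides — carrageenans, fucoidans and alginates — whose structure
(and hence bioactivity and commercial value) shifts with the season and the
life-cycle stage of the alga. Attenuated-total-reflectance Fourier-transform
infrared (FTIR-ATR) spectroscopy resolves these structures quickly and
non-destructively: each structural unit absorbs at a diagnostic wavenumber,
so a spectrum over the 800–1240 cm⁻¹ region reads like a fingerprint of the
colloid's sulfation pattern.

`phycospec` turns that workflow into a reproducible pipeline for analysts
working with algal polysaccharide extracts:

* **Spectrum handling** — two-column CSV, wide-matrix CSV and minimal
  JCAMP-DX I/O; strictly ascending canonical storage; linear regridding.
* **Conditioning** — closed-interval cropping, asymmetric-least-squares
  (ALS) baseline correction, SNV / max normalization, Savitzky–Golay
  smoothing and derivatives.
* **Band model** — apex detection with topological prominence and 3-point
  parabolic refinement; shoulder detection from second-derivative minima;
  matching against versioned diagnostic band libraries; assignment tables in
  the conventional matched / `+` (weak) / `-` (absent) notation.
* **Classification** — carrageenan typing (ι / κ / ν / mixture) from the
  sulfation logic of the matched bands (anhydro-galactose + 2-sulfate → ι,
  anhydro alone → κ, 6-/2-sulfated galactose → ν precursor), and colloid
  family calls (carrageenan / fucoidan / alginate) from marker-band
  fractions.
* **Similarity** — a clipped-Pearson spectral match score (percent) against
  standard spectra, an open analog of commercial library-search metrics.
* **Chemometrics** — mean-centered PCA of spectrum collections with
  deterministic sign conventions, plus silhouette-based quantification of
  seasonal grouping.
* **Simulation** — a seeded pseudo-Voigt spectrum generator with shipped
  seasonal study designs and full ground truth, so every stage is testable
  without instrument data.

## Worked example

Synthesize the ι-carrageenan standard from its published band positions,
condition it, detect and assign bands, and classify:

```r
library(phycospec)

iota  <- simulate_spectrum(c(iota = 1), seed = 1)
cond  <- baseline_correct(crop(iota, "carrageenan"))
report <- match_bands(detect_peaks(cond), band_library("carrageenan"),
                      meta = sample_meta(sample_id = "iota_standard"))
report_to_table(list(report))
#>          sample     S=O     DA*    G/D     DA  DA2S* G/D6S*    G4S G/D2S G/D6S   DA2S
#> 1 iota_standard 1218.04 1066.37 967.90 923.73 901.67 870.30 844.69     -     - 802.48

classify_carrageenan(report)
#> Type profile
#>   dominant type: iota
#>   colloid family: carrageenan
#>   scores: iota=4.00  kappa=0.00  nu=0.50
```

Every matched position lands within 0.5 cm⁻¹ of the planted standard value;
the two ν-specific bands (G/D2S, G/D6S) are correctly reported absent, and
the ι-specific 2-sulfated anhydrogalactose bands (DA2S at 802.5, DA2S* at
901.5 cm⁻¹) drive the ι call.

Seasonal structure is resolved by PCA over the 580–1350 cm⁻¹ window. The
shipped `solieria_2014` design plants a pure-ι composition in
September–December (the mature stage) and adds a ν-precursor trace plus an
amide background in January–August:

```r
sim   <- simulate_seasonal_dataset("solieria_2014")
model <- pca_fit(sim$set, window = "pca_red", n_components = 2)
model
#> Spectral PCA: 36 samples, 1597 wavenumbers in [580, 1350] cm^-1, 2 components
#>   explained variance (%): 63.6, 6.9

months <- vapply(sim$set$spectra, function(s) s$meta$month, 0L)
season_separation(model, ifelse(months >= 9, "mature", "transition"))
#> Group separation: mean silhouette 0.791 over 36 samples
#>   mature: 0.738
#>   transition: 0.818
```

A mean silhouette of 0.79 on the PC-1/PC-2 scores says the two seasonal
blocks form well-separated groups — the scalar counterpart of the two-cloud
score plots such studies show.

The same machinery is available end to end through `run_pipeline()` /
`read_pipeline_config()` (YAML configs) and the `inst/cli/phycospec.R`
command-line front end (`simulate`, `classify`, `similarity`, `pca`, `run`).

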