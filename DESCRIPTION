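Package: phycospec
Title: FTIR-ATR Characterization of Seaweed Phycocolloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of attenuated-total-reflectance Fourier-transform
    infrared (FTIR-ATR) absorbance spectra of algal cell-wall polysaccharides
    (carrageenans, fucoidans, alginates). Reads and writes two-column CSV and
    JCAMP-DX spectra, conditions them (cropping, asymmetric-least-squares
    baseline correction, standard-normal-variate normalization,
    Savitzky-Golay smoothing and derivatives), detects absorption peaks and
    shoulders, matches them against a diagnostic band library to produce
    structural-unit assignment tables, classifies carrageenan type
    (iota/kappa/nu) and colloid family (carrageenan/fucoidan/alginate),
    scores spectral similarity against standards, and resolves seasonal
    groupings of spectrum collections by principal component analysis with a
    silhouette separation statistic. A seeded pseudo-Voigt spectrum simulator
    with shipped seasonal designs makes the whole pipeline testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    cluster,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
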