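Package: metanno
Title: Modular Toolkit for Metabolite Annotation in LC-MS and CE-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Low-level building blocks and high-level workflows for
    annotating features from untargeted liquid chromatography mass
    spectrometry (LC-MS) and capillary electrophoresis mass spectrometry
    (CE-MS) experiments. Provides chemical formula parsing and
    monoisotopic mass calculation, conversion between neutral exact
    masses and ion m/z through a registry of electrospray adducts,
    ppm/tolerance-based value matching and peak-join strategies between
    tandem mass spectra, normalized spectra similarity scores including a
    precursor-shift aware (GNPS-style) modified cosine, grouping of MS1
    peaks into isotopologue groups, retention-time indexing and
    migration-time to effective-mobility conversion, a portable
    SQLite-based compound reference database format, and scored
    many-to-many MS1 and MS2 annotation results that retain query,
    target and parameters for reproducibility. Readers and writers for
    MGF and NIST MSP spectral library formats and a seeded synthetic
    reference generator are included so every component can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    stats,
    utils,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
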