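Package: gcvoc
Title: Simulation and Two-Group Classification of GC Metal-Oxide-Sensor
    Urine Headspace Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing bladder cancer from gas-chromatography
    metal-oxide-sensor chromatograms of urine headspace. Provides a seeded
    generator of synthetic chromatogram cohorts and daily ethanol
    calibration runs (Gaussian peaks, retention-time jitter, baseline
    drift), within-profile standardization, marker-peak detection and
    retention-time stability summaries, forward stepwise two-group linear
    discriminant analysis under Wilks' lambda with tolerance and
    F-to-enter guards, partial least squares discriminant analysis
    (PLS-DA) with a 1-10 latent-factor sweep, leave-one-out
    cross-validation for both classifiers, and a replicate-simulation
    evaluation harness with confusion matrices and jitter-robustness
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
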