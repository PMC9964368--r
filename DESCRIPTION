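Package: mealwormNIRS
Title: Near-Infrared Calibration of Fat and Fatty Acids in Living Mealworm Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for predicting the fat and fatty-acid
    content of living Tenebrio molitor larvae from near-infrared (NIR)
    spectra. Provides spectral pretreatments (multiplicative scatter
    correction, polynomial detrend, mean centering, Savitzky-Golay
    derivatives), PLS1 regression via the NIPALS algorithm with
    cross-validated latent-variable selection, and the usual calibration
    diagnostics (R2, RMSEC/RMSEP, RPD). Also includes fatty-acid profile
    accounting (SFA/MUFA/PUFA class sums from GC peak areas), insect
    rearing metrics (weight gain per larva, feed conversion ratio,
    conversion efficiency, specific growth rate), linear diet-formulation
    arithmetic, and a synthetic NIR spectra generator with Gaussian
    absorption bands for end-to-end testing of the calibration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    signal,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
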