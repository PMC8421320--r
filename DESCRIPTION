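Package: dualperf
Title: Dual-Modality Myocardial Blood Flow Quantification from PET and DCE-MRI Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracer-kinetic quantification of myocardial blood flow (MBF) from
    dynamic 15O-water PET time-activity curves and dynamic contrast-enhanced
    MRI signal curves, and the agreement analysis between the two modalities.
    Implements the single-tissue compartment model for 15O-water (perfusable
    tissue fraction and arterial blood-volume spillover), saturation-recovery
    signal-to-concentration conversion for gadolinium, three MRI analysis
    routes (plain one-tissue K1, Renkin-Crone extraction-corrected K1, and
    direct flow/permeability estimation), per-subject and population
    permeability-surface-area calibration, AHA 17-segment/territory/global
    aggregation, myocardial flow reserve, and Bland-Altman, Spearman and
    paired t-test agreement statistics. A reproducible synthetic rest/stress
    cohort generator with known ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
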