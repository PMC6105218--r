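Package: wwscreen
Title: Non-Target and Suspect Screening of Wastewater LC-HRMS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling wastewater composition from centroided
    LC-HRMS peak lists: deterministic molecular-feature extraction (noise
    filtering, trace linking, deisotoping), molecular-formula assignment with
    Seven Golden Rules filtering, sub-2-ppm mass accuracy and isotope-ratio
    gates, suspect screening of emerging contaminants with MS/MS transition
    confirmation, matrix-effect quantification, treatment-stage removal
    statistics, and selection of effluent-persistent pollution markers.
    Includes a synthetic-data generator that emulates wastewater treatment
    plant sampling campaigns (three treatment stages, three extraction
    protocols, both ESI polarities) with full ground-truth bookkeeping, so
    every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
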