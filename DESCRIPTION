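Package: tdfmetab
Title: Standard Metabolic Rate and Trophic Discrimination Factors from
    Intermittent-Flow Respirometry and Stable Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes intermittent-flow respirometry oxygen traces into
    standard metabolic rate (SMR) estimates: per-loop slope fits,
    chamber-specific background correction, mass-specific conversion, an
    R-squared quality filter, and the mean of the lowest decile of oxygen
    consumption measures. Computes carbon and nitrogen trophic
    discrimination factors (TDF) from tissue stable isotope data with
    C:N-based lipid normalization of delta-13C, gates TDF reporting on
    predicted isotopic equilibrium, and fits the associated statistical
    layer (ANCOVA with Bonferroni pairwise comparisons, TDF-on-SMR
    regressions, Welch t-test). A synthetic-data generator produces
    respirometry traces and isotope cohorts with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    emmeans,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
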