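Package: phosFly
Title: Flyability-Corrected Phosphosite Occupancy from Targeted Label-Free LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes absolute phosphorylation-site stoichiometry (occupancy)
    from targeted label-free LC-MS peak-area reports of cognate
    phosphopeptide/dephosphopeptide pairs.  Provides monoisotopic peptide
    mass and precursor m/z calculation for bracket-annotated modified
    peptides, charge-state aggregation and phosphospecies screening of
    extracted-ion-chromatogram peak areas, flyability (relative ionization
    efficiency) calibration from matched phosphatase-treated/untreated
    sample pairs, occupancy estimation with mean +/- SEM summaries,
    one-way ANOVA with Dunnett's many-to-one comparisons, a log-quadratic
    (Wagner) calibration for adenine nucleotide quantification with
    AMP/ATP and ADP/ATP ratio reporting, and a synthetic peak-area
    generator with a ground-truth ledger for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
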