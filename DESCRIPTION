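Package: fdindex
Title: Florey Dementia Index Modelling of Age at MCI and Alzheimer Dementia Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying the Florey Dementia Index (FDI),
    a disease-progression timescale for Alzheimer disease derived from
    longitudinal Clinical Dementia Rating Sum of Boxes (CDR-SB) trajectories.
    Individual trajectories are aligned to a population mean logistic curve by
    per-participant time shifts; Kaplan-Meier analysis of onset events on the
    aligned scale yields FDI thresholds for mild cognitive impairment (MCI)
    and Alzheimer dementia (AD) onset, overall and stratified by sex or
    medical comorbidity; predicted chronological age at onset for a new
    participant is the threshold minus the participant's shift. Includes
    cohort input/output and validation, model serialization, evaluation with
    bootstrap confidence intervals for mean absolute and root mean square
    error, a synthetic longitudinal cohort generator with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
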