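Package: igfrec
Title: Cell-Line-Specific Modeling of Competitive Signaling Protein
    Recruitment to IGF1R
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic mass-action models of early insulin-like growth
    factor 1 receptor (IGF1R) signaling. Implements the detailed-balance
    constrained cyclic scheme for IGF1 binding to the preformed IGF1R
    dimer (harmonic-oscillator mechanism), exact restructuration
    (decoupling, bunching, scaling) of the rule-derived reaction network
    for competitive SH2/PTB-domain recruitment to six receptor
    phosphotyrosines, an analytical single-occupancy equilibrium
    approximation, cell-line-specific model assembly from protein
    copy-number tables, lognormal population-level variability with
    pairwise recruitment correlations, five-way recruitment ranking, and
    Ward hierarchical clustering of recruitment profiles. Synthetic data
    generators emulate the supplementary-table input formats so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
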