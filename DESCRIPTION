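Package: pepwire
Title: Network-Based Multi-Omic Analysis of Kinase-Dependent HLA-I
    Antigen Presentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative differential analysis of four mass-spectrometry
    omic layers (immunopeptidome, phospho-immunopeptidome, proteome,
    phosphoproteome) with left-censored MinProb imputation, causal-network
    proximity screening of candidate kinases against the antigen processing
    and presentation machinery, assignment of drug-modulated HLA class I
    peptides to three signed regulatory mechanisms (direct peptide
    phosphorylation, source-protein stability, transcription-factor
    control), and tumor-associated antigen set identification. Includes a
    synthetic multi-omics generator with planted ground truth for
    end-to-end recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
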