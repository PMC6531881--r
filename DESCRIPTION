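Package: ampsim
Title: Simulation and Truth-Based Assessment of PCR Artifacts in 16S rRNA
    Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how DNA polymerase choice and the number of PCR
    cycles shape 16S rRNA gene amplicon data. Provides a count-space PCR
    simulator with per-cycle nucleotide misincorporation, template-switch
    chimera formation, per-template amplification efficiency bias and
    replicate-to-replicate drift; mock-community ground truth machinery
    (exhaustive bimera libraries, margin-based chimera classification,
    reference-based error-rate estimation, intra-genome variant ratios);
    abundance-based denoising that merges reads within a fixed number of
    nucleotides of a more abundant sequence; a de novo chimera detector in
    the style of UCHIME together with sensitivity and specificity
    evaluation against truth labels; and community-level analyses
    (abundance-greedy OTU clustering, rarefaction, alpha diversity,
    Bray-Curtis distances, principal coordinates, PERMANOVA,
    amplification-bias attribution and replicate drift summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
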