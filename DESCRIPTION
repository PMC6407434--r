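Package: smipseq
Title: Targeted RNA Sequencing with Single-Molecule Molecular Inversion Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for targeted RNA sequencing (t/RNA-NGS) with
    single-molecule molecular inversion probes (smMIPs): panel definition and
    validation, UMI-based consensus deduplication of reads into unique
    molecule counts, fragments-per-million (FPM) normalization and
    transcript-level expression, variant calling with a variant-allele-fraction
    filter and matched-normal somatic classification, unsupervised UPGMA
    clustering with Wilcoxon rank-sum differential expression and a signed
    fold-change convention, and Chou-Talalay median-effect drug-synergy
    analysis (combination index and dose-reduction index). Includes a
    synthetic-data generator emulating a tumor-versus-healthy cohort design
    so the whole chain is testable without patient material.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
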