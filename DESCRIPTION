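Package: retrosat
Title: Analysis and Simulation of Retrotransposon-Derived Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises satellite DNA arrays that originated
    from the long terminal repeat (LTR) and untranslated region (UTR) of
    LTR retrotransposons, as described for the centromeric retroelement
    derived tandem repeats of maize. Provides a self-contained pairwise
    alignment and Kimura two-parameter (K2P) distance core; homology-seeded
    tandem array detection with island segmentation and phase-normalised
    monomer extraction; decomposition of monomers into start / internal
    repeat / end-variant domain architectures; diagnostic-SNP selection and
    haplotype tabulation; gene-conversion tract inference with minimal and
    maximal breakpoint bounds; dating of nested retrotransposon insertions
    from the divergence of their LTR pairs; and a forward simulator of the
    splice-seed / gene-conversion growth model of array genesis that emits
    sequence together with machine-readable ground truth for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
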