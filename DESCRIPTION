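Package: exrna
Title: Analysis of Nonvesicular Extracellular RNA Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the nonvesicular extracellular RNA fraction of
    cultured cells. Deconvolutes two-wavelength (260/280 nm) size-exclusion
    chromatograms into RNA- and protein-attributable signals and quantifies
    the canonical P0/P1/P2 peaks; annotates mature tRNAs with a cloverleaf
    template and predicts single-strand-specific ribonuclease cleavage
    products (long and short 5' tRNA halves); classifies small-RNA reads into
    a tRNA/rRNA fragment taxonomy with RPM/RPKM profiling; scores
    dimer-forming capacity of fragments and the RNase protection it confers;
    and simulates extracellular RNA release and progressive ribonuclease
    fragmentation to generate fully labelled synthetic inputs for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
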