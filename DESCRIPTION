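Package: paicdemog
Title: Comparative Phylogeography and Historical Demography of Island Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial phylogeography of co-distributed island
    taxa: haplotype and nucleotide diversity with Nei sampling variances,
    Jukes-Cantor corrected between-population divergence (Dxy, Da),
    hierarchical analysis of molecular variance (AMOVA) with Phi-statistics
    and permutation tests, neutrality statistics (Tajima's D, Fu's Fs,
    Ramos-Onsins and Rozas R2) with coalescent-simulation significance,
    mismatch distributions with least-squares fitting of the sudden-expansion
    model and parametric-bootstrap confidence intervals for the expansion age
    tau, multi-rate conversion of tau to calendar time, median-joining
    haplotype networks, classification of rooted trees against hierarchical
    island-vicariance hypotheses, and a neutral coalescent simulator
    (constant-size, stepwise-expansion and two-deme divergence models) that
    doubles as the significance engine and synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
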