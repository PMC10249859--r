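Package: numtrisk
Title: Detection and Risk Assessment of COI-Derived Nuclear Mitochondrial
    Pseudogenes (NUMTs)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect nuclear copies of the mitochondrial COI barcode
    region (NUMTs) in genome assemblies, diagnose them through frameshift
    indels and premature stop codons under the invertebrate mitochondrial
    genetic code, classify them into amplicon-relevant length categories,
    and quantify how undiagnosable NUMTs inflate apparent species richness
    under different amplicon protocols. Includes a self-contained
    seed-and-extend local aligner with Karlin-Altschul E-values, a
    Smith-Waterman oracle, a mitochondrial-scaffold screen, mitogenome-wide
    windowed NUMT counting, single-linkage OTU clustering, and a synthetic
    genome simulator that plants NUMTs with full ground truth so every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
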