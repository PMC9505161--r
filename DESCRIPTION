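Package: plastedit
Title: Detection and Comparative Analysis of Chloroplast RNA Editing Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls C-to-U and G-to-A RNA editing sites in plastomes from
    matched same-individual DNA and strand-specific RNA base counts, rescues
    sites masked by indel-bearing reads, annotates genomic region, codon
    position, amino-acid and hydropathy consequences, projects sites to
    homologous coordinates across species for intersection and density
    analysis, reconstructs gain and loss events on a fixed phylogeny under a
    two-state Markov model, and correlates editing-site abundance with
    plastome features. Includes a synthetic-data generator that emulates the
    statistical structure of gymnosperm chloroplast editing for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
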