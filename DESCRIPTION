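Package: retrosplice
Title: Alternative Splicing Responses to Chloroplast Retrograde and Light
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Junction-based quantification of alternative splicing (percent
    spliced in, PSI) and a threshold-based differential-splicing and
    differential-expression caller of the kind used to study how chloroplast
    retrograde signals (norflurazon, lincomycin), GUN1, the nonsense-mediated
    decay pathway (upf mutants) and light reshape the Arabidopsis splicing
    landscape. Includes reconstruction of inclusion/exclusion isoforms,
    premature-termination-codon detection under the 50-nt rule, repressive
    AS-NMD event classification, intron/exon regulatory-feature comparison,
    Fisher/Kruskal-Wallis convergence statistics, and a synthetic-data
    generator that emulates the condition structure of the underlying
    experimental designs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
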