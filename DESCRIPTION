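Package: antisenser
Title: Classification and Comparative Analysis of Antisense Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising antisense transcription from stranded
    genome annotations. Classifies opposite-strand transcript overlaps into
    intronic, nested, exonic and UTR-overlap configurations, tests antisense
    transcripts for protein-coding evidence against a length-matched resampling
    null, compares host/antisense expression correlation to a random-gene-pair
    null, calls cross-genome conservation of antisense gene pairs by span
    containment of homology hits, screens conserved non-coding element
    candidates, and compares intron-length and synteny-block-size
    distributions. Ships a synthetic-data generator that plants every
    configuration with known ground truth so the whole pipeline is testable
    end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
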