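Package: pednar
Title: Partitioning Protected Extracellular DNA into Viral and Non-Viral
    Fractions and Attributing It to Transfer Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protected extracellular DNA (peDNA), the
    sequence space recovered from size-filtered, DNase-treated environmental
    samples. Provides a seeded synthetic marine-community generator with
    per-read truth labels, an SSU rRNA contamination screen, a viral versus
    non-viral contig partition with a read-pair ratio, per-genome attribution
    of the non-viral fraction to extracellular-vesicle production, gene
    transfer agent production or active transduction, and COG-category
    functional profiling with signed fold changes. All user-facing functions
    take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
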