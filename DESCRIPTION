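Package: secondhit
Title: Second-Hit Variant Screening for Autosomal-Recessive Rare Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the systematic search for the missing second allele in
    suspected autosomal-recessive rare-disease cases where one pathogenic
    ("first-hit") variant is already known. Aggregates structural-variant (SV)
    calls across samples and callers by reciprocal overlap, computes cohort
    carrier frequencies and prioritises rare clusters; screens the first-hit
    gene window for candidate SVs and rare small variants; phases candidate
    pairs by trio inheritance; estimates mosaic fractions for deletions from
    read depth; detects runs of homozygosity to support homozygous candidates;
    and annotates splice-altering variants with retained-intron, pseudoexon
    and exon-skip length arithmetic. Ships a synthetic-cohort generator with
    planted truth so that every stage of the screen is testable end-to-end
    without access-controlled genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    zoo,
    igraph,
    IRanges,
    S4Vectors,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
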