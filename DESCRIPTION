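Package: mutmapr
Title: MutMap-Style Bulked-Segregant Mapping of Recessive Mutant Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a single recessive mutant locus in an F2
    population by bulked-segregant whole-genome sequencing. Implements
    segregation-ratio goodness-of-fit tests with continuity correction,
    the SNP-index and delta(SNP-index) genome scan with per-SNP Fisher
    exact tests, sliding-window averaging and simulation-based null
    confidence bands, recessive-class fine mapping with codominant
    markers, and candidate-gene interval intersection. A forward
    simulator of an EMS-mutant x wild-type F2 cross (meiosis with
    Haldane crossovers, phenotypic bulking, pooled short-read allele
    counts, SSR marker genotypes) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
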