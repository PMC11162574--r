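Package: allodup
Title: Duplicated-Gene Expression Fates, Cis/Trans Regulation and DNA
    Methylation Dynamics in Allopolyploids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the evolution of duplicated genes in an
    allopolyploid and its two diploid progenitors. Classifies duplicate
    retention mechanisms (conservation, neofunctionalization,
    subfunctionalization, specialization) from multi-tissue expression
    profiles by Euclidean expression distance against a single-copy-ortholog
    derived cutoff; computes the tissue-specificity index tau and
    correlations of expression divergence with Ka, Ks, Ka/Ks and tau;
    assigns homoeolog pairs to seven cis/trans regulatory-divergence
    categories from progenitor-mix and allopolyploid read counts; builds
    expression-class-stratified meta-gene DNA-methylation profiles around
    transcription start and end sites; and classifies generational
    transmission of homoeolog expression/methylation bias into nine patterns
    in three groups. Every input can be simulated with planted ground truth,
    so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
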