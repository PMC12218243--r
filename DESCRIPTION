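Package: ssufuse
Title: Three-Domain SSU rRNA Metabarcoding with Quantitative 16S/18S Merging
Version: 0.1.0
Authors@R: person("ssufuse", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes mixed 16S/18S rRNA amplicon libraries generated with
    universal SSU primers (515Y/926R). Read pairs are primer-trimmed, binned
    into 16S and 18S pools by exclusive k-mer evidence, denoised per pool
    (overlap merging for 16S, fixed-length concatenation for 18S), screened
    for bimeras, and finally merged into a single quantitative ASV table
    using bioanalyzer-based correction factors that undo the sequencing
    platform's bias against longer 18S fragments. Includes a naive Bayes
    k-mer taxonomy classifier with rank harmonization across reference
    schemes, oceanographic context helpers (euphotic depth, Longhurst
    province, season), and a seeded mock-community read simulator that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
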