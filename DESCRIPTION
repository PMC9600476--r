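Package: microherit
Title: Heritability and Microbiability of Host-Associated Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of host genetics and the rumen
    microbiome. Estimates per-taxon narrow-sense heritability from a genomic
    relationship matrix with a single-kernel REML animal model, classifies
    heritable versus nonheritable taxa, builds the microbiota relationship
    matrix from standardized log relative abundances, estimates microbiability
    and mean microbiability of subcommunities for lactation and volatile fatty
    acid traits, runs mixed-model association scans on heritable taxa with
    Benjamini-Hochberg false-discovery-rate control, and constructs thresholded
    Spearman correlation networks. Includes a synthetic-data generator with
    known ground truth (planted heritabilities and microbiabilities) so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
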