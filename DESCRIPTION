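Package: histosketchr
Title: Streaming Histosketches of Microbiome k-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fixed-memory streaming reduction of microbiome sequencing reads
    to similarity-preserving "histosketches" of the k-mer spectrum.
    Canonical k-mers from FASTQ streams are hashed into histogram bins,
    counted approximately with count-min sketches, and summarised with
    consistent weighted sampling (a weighted MinHash) into fixed-size
    sketches that support weighted-Jaccard distance estimation, LSH-forest
    indexing and search, and random-forest classification of (possibly
    incomplete) data streams with optional concept-drift decay. Includes a
    synthetic-community read generator with exact-spectrum oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
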