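Package: scscreen
Title: Reference-Free Contamination Screening for Single-Cell Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects foreign DNA in single-cell genome assemblies without any
    reference database. Contigs are converted to windowed canonical
    tetranucleotide frequency signatures, embedded in two dimensions with
    Barnes-Hut t-SNE, and tested for cluster structure by two complementary
    detectors: per-point Hartigan dip tests on pairwise distances and connected
    components of a mutual k-nearest-neighbour graph. Bootstrap subsampling
    turns detector agreement across folds into contamination confidences and a
    clean/warning/contaminated verdict. Contaminated assemblies can be split
    into per-cluster FASTA files using Ward clustering with Davies-Bouldin
    selection of the cluster number. A synthetic assembly generator with
    ground-truth labels supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    FNN,
    graphics,
    igraph,
    jsonlite,
    parallel,
    Rcpp,
    Rtsne,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    boot,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
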