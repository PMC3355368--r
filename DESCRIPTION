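Package: proteoprobe
Title: Metabolic Classification of Microbial Proteomes with Conserved
    Sequence Probe Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans microbial proteomes with conserved amino-acid sequence
    probes (PROSITE-style pattern descriptors), encodes each proteome as a
    normalized probe-frequency pattern, clusters the patterns into a
    classification tree with Spearman-distance average-linkage clustering,
    and compares classification trees quantitatively through the correlation
    of their leaf-to-leaf traveling-distance matrices.  Includes a seeded
    synthetic-data generator (planted probe motifs in random background
    proteomes, random binary trees) and random-truncation robustness
    experiments, so the whole pipeline can be exercised without external
    databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
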