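Package: litppi
Title: Integrating Literature-Derived Protein Interactions for Protein
    Complex Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the value of protein-protein
    interactions (PPIs) mined from the biomedical literature as a
    supplement to experimental PPI networks.  Confidence-scored literature
    interactions are normalized to systematic yeast ORF names and merged
    into a PPI network above a confidence threshold; protein complexes are
    then detected with a cohesiveness-based greedy algorithm in the style
    of ClusterONE, and predictions are scored against gold-standard
    catalogs (MIPS-style category tables or GO-derived complex
    annotations) with the overlap score, clustering-wise
    sensitivity/positive predictive value, geometric accuracy and the
    maximum matching ratio.  A planted-complex simulator generates
    networks, held-out literature edges, alias tables and noisy gold
    standards so the whole threshold-sweep experiment runs without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
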