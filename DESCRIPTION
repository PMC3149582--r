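Package: phenomap
Title: Quantification and Semantic Mapping of Visually Observed Plant Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An image-analysis and knowledge-discovery toolkit for visually
    observed plant phenotypes. Generates labeled synthetic leaf and fruit
    images with ground truth, segments necrotic and chlorotic lesions from
    leaf images, extracts standardized feature vectors (color, size,
    roundness, nearest-neighbor distance and spatial histograms for leaves;
    Tomato-Analyzer-style morphometrics for fruit), mines quantitative
    class-association rules linking feature intervals to phenotype
    semantics, fuzzifies rule antecedents into possibility distributions,
    evaluates semantic retrieval and annotation by mean average precision,
    and models a five-layer visual phenotype ontology with JSON and OWL
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    xml2,
    png,
    igraph,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
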