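# phenomap

Quantification and semantic mapping of visually observed plant phenotypes.

Plant phenotypes are still mostly described in words — "brown lesions",
"extensive coverage", "oxheart-shaped fruit" — and those words are vague,
inconsistent across curators, and unsearchable. `phenomap` implements a
computable bridge between curator vocabulary and image content for two
model settings: maize-style leaves with necrotic/chlorotic lesions, and
tomato-style fruit silhouettes.

The package provides, end to end:

* **Synthetic phenotypes with ground truth** — a deterministic, seeded
  generator of labeled leaf images (lesion color, size, shape, count and
  spatial pattern all controlled) and fruit silhouettes (eight shape
  classes, three sizes), with pixel-level masks and degree-coded semantic
  labels. No public image collection accompanies the method, so the
  generator is the package's test bed.
* **Segmentation** — leaf isolation from a solid background, HSV-gate
  tissue classification (necrotic / chlorotic / normal), and per-lesion
  geometry from 8-connected components (touching lesions merge, as a real
  segmenter would see them).
* **Feature extraction** — the fixed 452-feature leaf vector (RGB/HSV
  histograms per pixel region, plus 12-bin lesion size, roundness and
  nearest-neighbor-distance histograms per tissue class) and the
  56-feature fruit vector (geometry, shape indices, color averages, 37-bin
  LCh hue histogram).
* **Semantic mapping** — the core method: mine quantitative
  class-association rules `{F006 ∈ [0.09, 0.16] ∧ F399 ∈ [0.12, 0.21]} →
  elliptical_lesions` linking feature intervals to semantic terms, then
  fuzzify the intervals into possibility distributions
  π(x; λ1 center, λ2 width, λ3 slope), normalized so π(λ1) = 1, so image
  relevance is graded instead of binary.
* **Retrieval and annotation** — semantic search with CombSUM rank fusion,
  automatic annotation of new images, and the resubstitution evaluation
  protocol (average precision, class MAP, 11-point precision-recall).
* **A layered visual phenotype ontology** — plant taxon → structure →
  abnormality → phenotype expression → phenotype quantification, with
  typed relations, mined rules embedded as quantification nodes, JSON
  round-trip and OWL 2 (RDF/XML) export, plus an imagery-and-algorithms
  ontology that validates the processing pipeline.

## Worked example

Run the packaged synthetic leaf study — generate a balanced labeled image
set, extract 452-feature vectors, mine and fuzzify rules, and evaluate
retrieval on the training set:

```r
library(phenomap)

study <- run_leaf_study(seed = 1, n_per_class = 5)   # 40 images
study$eval
#> <pheno_eval>
#>   lesion_color       MAP = 1.000 (2 terms)
#>   lesion_coverage    MAP = 1.000 (3 terms)
#>   lesion_shape       MAP = 1.000 (2 terms)
#>   lesion_size        MAP = 1.000 (3 terms)
```

Every semantic class reaches mean average precision 1.0: on data whose
class bands are disjoint by construction, the mined possibility rules rank
every relevant training image above every irrelevant one. The map itself
is a small set of interval rules:

```r
glance(study$map)
#> # A tibble: 1 × 5
#>   n_rules n_terms n_classes mean_confidence mean_support
#> 1      16      10         4               1        0.361

format_rules(study$map$rules[study$map$rules$semantic_class == "lesion_color", ][1, ])
#> {F014 ∈ [0,  0.1]} -> brown_lesions
```

(F014 is a high-red bin of the entire-leaf histogram — the band that
bright yellow chlorotic tissue occupies. Absence of that mass on a
lesion-bearing leaf identifies brown lesions: the miner found the
complement of the yellow class.)
Semantic search fuses per-term relevance lists; querying two terms ranks
images that satisfy both first:

```r
semantic_search(study$features, study$map, c("medium_lesions", "brown_lesions"))
#> # A tibble: 40 × 2
#>   image_id     score
#> 1 brown_few_01  1.16
#> 2 brown_few_02  1.16
#> ...
```

Fruit morphometrics reproduce printed reference measurements — shape index
1 (maximum height / maximum width, two decimals) for the Anna Russian
fruits:

```r
tab <- read.csv(system.file("extdata", "anna_russian_table.csv", package = "phenomap"))
shape_index_1(tab$max_width, tab$max_height)
#> [1] 1.04 1.07 1.23 1.26 1.14 1.16 1.01 1.00
```

A command-line interface wraps the same functions
(`inst/cli/phenomap synth | extract | mine | eval | search |
export-ontology`).

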