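---
title: "Quantifying and semantically mapping visual plant phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and semantically mapping visual plant phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

## The problem

Curators describe plant phenotypes with qualitative terms — "brown
lesions", "extensive coverage", "oxheart shape" — that are vague,
heterogeneous across curators, and hard to search. phenomap implements a
computable bridge between such terms and image measurements: images taken
under a fixed protocol (solid background) are processed by a standard
pipeline into feature vectors; association-rule mining then learns, from a
curator-labeled training set, which regions of feature space correspond to
which terms; and the crisp rules are softened into possibility
distributions so that the relevance of an image to a term is graded rather
than binary. The rules live in a five-layer ontology (plant taxon → plant
structure → plant abnormality → phenotype expression → phenotype
quantification) together with a three-layer ontology of imagery and
algorithms that annotates the pipeline itself.

## The measurement pipeline

For a maize-style leaf image the pipeline is: background segmentation
(`segment_leaf()`, RGB distance to the declared background color, largest
8-connected component, holes filled), tissue classification
(`classify_tissue()`, HSV gates: necrotic tissue is brown — hue below 45°
with bounded brightness; chlorotic tissue is yellow — hue in 45–90°; the
rest of the leaf is normal), lesion extraction (`extract_lesions()`,
8-connected components per tissue class, minimum area 5 px² against
speckle), and feature extraction (`extract_leaf_features()`). Touching
lesions merge into a single component by construction — with 8-connectivity
even diagonal contact merges, which matches how a segmentation algorithm
sees physically touching necrosis even when the eye projects separate
lesions.

The 452-feature leaf vector has a fixed block layout: RGB histograms
(16+16+16 bins) over the entire leaf, necrotic, chlorotic and non-lesion
pixels; HSV histograms (15+16+16) over the same regions (entire, necrotic,
non-lesion, chlorotic — in that order); then 12-bin histograms of lesion
area, lesion roundness and nearest-neighbor centroid distance for each
lesion tissue class. Hue is measured in degrees on [0, 360). Roundness is
the area of a lesion over the area of the circle whose diameter is the
lesion's maximum (Feret) diameter — 1 for a disk, lower for elongated or
ragged shapes; the Feret diameter is computed exactly on convex-hull
vertices. Area bins span one tenth of the leaf area by default
(`size_max_frac`), nearest-neighbor bins span the leaf's long axis.

Fruit silhouettes get the 56 morphometric features familiar from
tomato-fruit phenotyping tools: perimeter, area, bounding-box and
mid-slice extents, curved height (arc length of the per-row medial curve),
three shape indices, average RGB / luminosity / L\*a\*b\* / hue / chroma,
and a 37-bin hue histogram in CIE LCh space. Shape index 1 is maximum
height over maximum width, reported at two decimals; the package reproduces
all eight printed reference values for the Anna Russian variety from the
shipped measurement table. Shape index 2 (height at mid-width over width
at mid-height) and the curved shape index (curved height over width at
mid-height) follow the conventional definitions; they cannot be
cross-checked against the printed table, which lacks the mid-slice
columns, and are therefore verified only by geometric oracles (rectangles,
disks, scale invariance).

### Normalization of count histograms

Color histograms are normalized per channel (each sums to 1). The count
histograms (size, roundness, nearest-neighbor distance) are
*range-normalized*: divided by a fixed reference count (`count_scale`,
default 50). An earlier draft divided each block by its own sum, but that
erases lesion frequency — after per-block sum normalization a leaf with 2
lesions and a leaf with 30 lesions of the same size distribution are
indistinguishable, and the coverage semantics (few / moderate / extensive)
become unlearnable in principle. A fixed reference keeps counts comparable
across images while bounding the features; the raw counts are retained in
the `counts` attribute.

## Semantic mapping

Features are min–max rescaled to [0,1] over the training table (the
scaling is stored for inference). Per semantic class, feature selection
(`select_features()`) uses correlation-based subset merit — mean
feature-class correlation penalized by mean inter-feature correlation —
searched greedily or with best-first backtracking (exhaustive search is
available up to 15 candidates). Because interval rules can express
*middle-band* signatures that a linear correlation cannot see (a feature
value of exactly 2 lesions between 0 and 4 is invisible to a point-biserial
coefficient), selection additionally guarantees each term its
`per_term_top` features by single-bin contrast: the largest difference,
over ten equal-width bins, between the term's bin occupancy and the rest.

`discretize()` cuts each rescaled feature into `n_bins` interval-carrying
bins (equal width over [0,1], or equal frequency via mid-gap cut points);
intervals are half-open `[lo, hi)` with the final bin closed.
`mine_rules()` then enumerates *every* rule `A → term` whose antecedent is
a conjunction of at most `max_len` per-feature intervals (each interval a
run of adjacent bins; the uninformative full-range interval is excluded),
with support (fraction of rows matching antecedent and term) and confidence
above the thresholds. The enumeration is level-wise with anti-monotone
support pruning and is output-identical to brute force — the test suite
checks exact equality against an independent brute-force enumerator on
randomized tables. Default thresholds: `min_support` 0.05,
`min_confidence` 0.8, `max_len` 3, 10 equal-width bins. A term is mined
only when its class has at least two terms with supported examples.

A trained map (`train_semantic_map()`) does not keep the complete rule
set: on cleanly separable data the number of qualifying rules is
combinatorially large and most are interval-variants of one another.
Rules are kept by *database coverage*, the selection used by classic
class-association-rule classifiers: walking rules in confidence-then-
support order, a rule is kept only when it matches at least one relevant
training image not matched by an already-kept rule. This collapses
redundant variants while guaranteeing that every coverable training image
keeps a covering rule. For the same reason the trainer collapses
row-equivalent candidate intervals (those differing only across empty
bins) to the narrowest one (`distinct_masks`); the public miner default
leaves the complete enumeration untouched.

### Fuzzification and possibility

Each crisp interval `[lo, hi]` becomes a possibility distribution with
center λ1 = (lo+hi)/2, width λ2 = hi−lo and slope λ3 = `slope_scale`/λ2,
so narrower intervals get proportionally steeper edges. The distribution
itself is a renormalized product of two logistic edges — a rise at
λ1−λ2/2 and a fall at λ1+λ2/2, both with slope λ3 — divided by its value
at λ1 so that π(λ1) = 1 exactly. It is monotone non-increasing away from
the interval, tends to 0 in the tails, and converges pointwise to the
crisp indicator as λ3 → ∞. The relevance of an image to a rule combines
per-condition possibilities with a t-norm (minimum by default, product
optionally); relevance to a term is the maximum over the term's rules, 0
when a term has no rules. `slope_scale` defaults to 5 (in rescaled feature
units): at the crisp interval edge the possibility is about one half, and
a value one interval-width away from the center is suppressed below 0.08.

## Retrieval, annotation and evaluation

`semantic_search()` scores every image against each query term and fuses
the per-term lists by summed scores (CombSUM; product fusion optional),
with ties broken by ascending image id. `annotate_image()` returns all
terms of positive relevance for one feature vector.
`evaluate_resubstitution()` implements the training-set evaluation
protocol: for each term, all training images are ranked by semantic
relevance and scored against the training labels, where an image is
relevant to a term when it carries the term at degree other than "none"
(degrees — none/few/moderate/extensive — are retained as metadata but
binarized for mining and evaluation). Average precision is the standard
retrieval AP; class MAP is the mean AP over the class's terms;
precision-recall curves use 11-point interpolated precision.

## The synthetic study

No public image collection accompanies the method, so the package ships a
deterministic generator. A `leaf_spec()` fully determines one image (seed
included — identical specs are bit-identical): an elongated blade on a
solid background carries lesions of a configured tissue class (necrotic
brown / chlorotic yellow), area band, shape class and spatial pattern.
Size classes map to pairwise-disjoint area bands; elliptical lesions draw
an axis ratio in [0.71, 0.76] (roundness lands in bins 8–9 of the 12-bin
roundness histogram, with a buffer bin below), irregular lesions perturb a
disk radially with even harmonics at amplitude 0.7–0.95 (roundness bins
3–6). Coverage degree is a step function of lesion count with thresholds
(2, 12). Fruit silhouettes come from a parametric half-width profile
family with eight shape classes (a circle for round, a tall ellipse for
long, superellipse for rectangular, pointed-bottom beta profiles for the
heart types) and three size classes.

Five spatial patterns are available: uniform, clustered, tip- and
base-biased — all of which allow lesions to touch and overlap, so
downstream merging is exercised — plus `spaced`, a hard-core inhibition
pattern that rejects placements until a lesion touches no earlier lesion.

The packaged study (`run_leaf_study()`) uses eight templates × 15 images
on a 720×180 blade with spaced placement and low counts (2 / 4–6 / 16
across the coverage classes). These conditions were chosen from collision
geometry: the probability that two lesions of area *a* touch scales as
4·*a*/*A*<sub>leaf</sub> per pair, and a merged pair is measurement-level
contamination — its area doubles and its roundness collapses, smearing one
class's measurements into another's band in a way no rule language can
undo. Low counts on a large blade with hard-core placement keep the
*measured* class bands as disjoint as the generative ones. The study
extracts features with `leaf_study_config()` (size bins at the same
absolute width as on the default blade) and trains with two-condition
rules, best-first selection capped at 12 features and a per-term contrast
guarantee of 5. Under these conditions resubstitution MAP is 1.0 for all
four semantic classes, and shuffling the labels collapses MAP to chance
prevalence — both checked in the test suite.

What passing this study does *not* show: real leaf images have textured
backgrounds, venation, lighting gradients, color-calibration error,
overlapping disease agents, and — most importantly — lesions that really
do touch. On real field collections the same merging physics depresses size- and
shape-class retrieval precision well below the color and coverage
classes; the synthetic study intentionally isolates the
rule-learning machinery from that confound rather than claiming it away.

## The ontology

`vpheno_ontology()` builds a typed, layered DAG. Cross-layer relations are
fixed: structure *part_of* taxon, abnormality *expressed_on* structure,
expression *expressed_by* abnormality, quantification *describes*
expression; *is_a* is allowed within any single layer; cycles and
layer-violating edges are rejected with typed errors. `embed_rules()`
turns each fuzzy rule into a quantification node (payload: antecedent with
λ parameters, support, confidence) with a *describes* edge to the
expression node matching its consequent, and records implicit links from
antecedent features to the pipeline stages that produce them. External
vocabularies (plant structure, trait and quality ontologies, taxonomy) are
referenced by identifier string only and never fetched. JSON serialization
round-trips losslessly; OWL 2 export writes RDF/XML with object-property
restrictions for the typed relations and the rule payload as a JSON
annotation property (OWL has no native interval syntax). A pipeline
description (`maize_pipeline()`) validates against the imagery ontology:
every stage term must resolve, the input/output kind chain must be
contiguous, and parameterized stages must carry parameters.

## Numerical choices and conventions

* Hue is in degrees in [0, 360) everywhere; all gates and bin edges are
  declared in degrees.
* Pixel coordinates are 0-based, x right, y down; centroids are unweighted
  pixel means; a centroid exactly on a spatial-partition boundary goes to
  the lower-index partition.
* Histogram bins are half-open `[lo, hi)` with the final bin closed;
  values beyond the declared range are clamped into the end bins.
* Roundness is clipped to at most 1 (rasterization overshoot) and defined
  as 1 for single-pixel lesions.
* Min–max scaling parameters are persisted with the semantic map; new
  images may rescale outside [0,1] and are handled by the possibility
  tails.
* Equal-frequency discretization cuts at mid-gaps between boundary order
  statistics so bins stay half-open; constant features collapse to a
  single bin with a warning.
* The miner's determinism: rules are sorted by confidence, support,
  antecedent length, consequent and interval key; search ties in feature
  selection break lexicographically.

## Limitations

The tissue classifier is a fixed HSV gate validated only on synthetic
images; real collections would need gate calibration or a trained
classifier. Color-checker calibration is accepted as an identity
transform. The genetic feature-selection variant is not provided (three
deterministic methods are). Curved height uses a per-row medial curve,
which is exact for vertically convex fruit but an approximation for
strongly lobed silhouettes. Degree codes are binarized for evaluation;
graded-relevance retrieval metrics are not implemented.
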