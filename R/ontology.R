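# Layered visual phenotype ontology: a validated DAG over five layers
# (plant taxon -> plant structure -> plant abnormality -> phenotype
# expression -> phenotype quantification) plus a three-layer imagery-and-
# algorithms ontology, with mined-rule embedding, JSON/OWL serialization and
# pipeline validation.

vpheno_layers <- c("plant_taxon", "plant_structure", "plant_abnormality",
                   "phenotype_expression", "phenotype_quantification")
imagery_layers <- c("imagery", "algorithms", "machine_representation")

# Allowed (child layer, parent layer, relation) triples. is_a is permitted
# within any single layer; cross-layer relations are fixed per layer pair.
allowed_relations <- function(kind) {
  if (kind == "vpheno") {
    tibble(
      child = c(vpheno_layers,
                "plant_structure", "plant_abnormality",
                "phenotype_expression", "phenotype_quantification"),
      parent = c(vpheno_layers,
                 "plant_taxon", "plant_structure",
                 "plant_abnormality", "phenotype_expression"),
      relation = c(rep("is_a", 5),
                   "part_of", "expressed_on", "expressed_by", "describes")
    )
  } else {
    tibble(
      child = c(imagery_layers, "algorithms", "machine_representation"),
      parent = c(imagery_layers, "imagery", "algorithms"),
      relation = c(rep("is_a", 3), "part_of", "part_of")
    )
  }
}

#' Create an empty layered phenotype ontology
#'
#' @param kind `"vpheno"` (five layers: plant_taxon, plant_structure,
#'   plant_abnormality, phenotype_expression, phenotype_quantification) or
#'   `"imagery"` (three layers: imagery, algorithms, machine_representation).
#' @return object of class `vpheno_ontology` with empty `nodes` and `edges`
#'   tibbles.
#' @export
vpheno_ontology <- function(kind = c("vpheno", "imagery")) {
  kind <- match.arg(kind)
  structure(list(
    kind = kind,
    nodes = tibble(id = character(), label = character(), layer = character(),
                   xref = character(), payload = list()),
    edges = tibble(child = character(), parent = character(), relation = character())
  ), class = "vpheno_ontology")
}

#' Add a node to an ontology
#'
#' @param ont a [vpheno_ontology()].
#' @param id unique node id.
#' @param label human-readable label.
#' @param layer one of the ontology's layers (fixed at creation).
#' @param xref optional external identifier string (e.g. `"PO:0009025"`,
#'   `"TO:0000299"`, an NCBI taxon id); referenced by string only, never
#'   fetched.
#' @param payload optional list payload stored on the node.
#' @return the updated ontology.
#' @export
add_node <- function(ont, id, label = id, layer, xref = NA_character_, payload = NULL) {
  stopifnot(inherits(ont, "vpheno_ontology"))
  layers <- if (ont$kind == "vpheno") vpheno_layers else imagery_layers
  if (!layer %in% layers) {
    abort(sprintf("invalid layer '%s' for a %s ontology", layer, ont$kind),
          class = "phenomap_ontology_error")
  }
  if (id %in% ont$nodes$id) {
    abort(paste0("duplicate node id: ", id), class = "phenomap_ontology_error")
  }
  ont$nodes <- bind_rows(ont$nodes,
                         tibble(id = id, label = label, layer = layer,
                                xref = xref, payload = list(payload)))
  ont
}

#' Add a typed edge to an ontology
#'
#' Cross-layer relations are constrained (structure `part_of` taxon,
#' abnormality `expressed_on` structure, expression `expressed_by`
#' abnormality, quantification `describes` expression; `is_a` within a
#' layer) and the graph must stay acyclic; violating edges are rejected with
#' a typed error.
#'
#' @param ont a [vpheno_ontology()].
#' @param child,parent node ids (must exist).
#' @param relation one of `is_a`, `part_of`, `expressed_on`, `expressed_by`,
#'   `describes`.
#' @return the updated ontology.
#' @export
add_edge <- function(ont, child, parent, relation) {
  stopifnot(inherits(ont, "vpheno_ontology"))
  child <- unname(child); parent <- unname(parent)
  if (!child %in% ont$nodes$id || !parent %in% ont$nodes$id) {
    abort("edge endpoints must exist", class = "phenomap_ontology_error")
  }
  if (child == parent) abort("self-edges are not allowed", class = "phenomap_ontology_error")
  cl <- ont$nodes$layer[ont$nodes$id == child]
  pl <- ont$nodes$layer[ont$nodes$id == parent]
  ok <- allowed_relations(ont$kind)
  if (!any(ok$child == cl & ok$parent == pl & ok$relation == relation)) {
    abort(sprintf("relation '%s' not allowed from layer '%s' to layer '%s'",
                  relation, cl, pl), class = "phenomap_ontology_error")
  }
  edges <- bind_rows(ont$edges, tibble(child = child, parent = parent, relation = relation))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    abort("edge would create a cycle", class = "phenomap_ontology_error")
  }
  ont$edges <- edges
  ont
}

#' Node counts per layer
#'
#' @param ont a [vpheno_ontology()].
#' @return tibble `layer`, `n` (all layers, zero-filled), in layer order.
#' @export
layer_counts <- function(ont) {
  layers <- if (ont$kind == "vpheno") vpheno_layers else imagery_layers
  tibble(layer = layers,
         n = vapply(layers, function(l) sum(ont$nodes$layer == l), integer(1),
                    USE.NAMES = FALSE))
}

#' Embed mined fuzzy rules as phenotype-quantification nodes
#'
#' Adds one quantification node per rule, linked by a `describes` edge to
#' the phenotype-expression node whose label (or id) matches the rule's
#' consequent. The rule payload (antecedent with possibility parameters,
#' support, confidence) is stored on the node. When a `pipeline` is given,
#' implicit links from each antecedent feature to its pipeline stage are
#' recorded in the `feature_links` attribute.
#'
#' @param ont a `vpheno` ontology with expression nodes for all consequents.
#' @param rules a `fuzzy_rules` tibble.
#' @param pipeline optional pipeline tibble (see [maize_pipeline()]) used to
#'   record feature-to-stage links.
#' @return the updated ontology.
#' @export
embed_rules <- function(ont, rules, pipeline = NULL) {
  stopifnot(inherits(ont, "vpheno_ontology"), ont$kind == "vpheno")
  if (nrow(rules) == 0L) return(ont)
  expr_nodes <- ont$nodes[ont$nodes$layer == "phenotype_expression", ]
  match_expr <- function(term) {
    hit <- expr_nodes$id[expr_nodes$label == term | expr_nodes$id == term]
    if (length(hit) == 0L) NA_character_ else hit[1]
  }
  targets <- vapply(rules$consequent, match_expr, character(1))
  if (any(is.na(targets))) {
    abort(paste0("no phenotype_expression node for consequent(s): ",
                 paste(unique(rules$consequent[is.na(targets)]), collapse = ", ")),
          class = "phenomap_ontology_error")
  }
  n0 <- sum(ont$nodes$layer == "phenotype_quantification")
  for (i in seq_len(nrow(rules))) {
    rid <- sprintf("rule_%03d", n0 + i)
    ont <- add_node(ont, rid, label = format_rules(rules[i, ]),
                    layer = "phenotype_quantification",
                    payload = list(antecedent = rules$antecedent[[i]],
                                   consequent = rules$consequent[i],
                                   support = rules$support[i],
                                   confidence = rules$confidence[i]))
    ont <- add_edge(ont, rid, targets[i], "describes")
  }
  if (!is.null(pipeline)) {
    links <- bind_rows(lapply(seq_len(nrow(rules)), function(i) {
      tibble(rule = sprintf("rule_%03d", n0 + i),
             feature = rules$antecedent[[i]]$feature)
    }))
    links$stage <- feature_stage(links$feature, pipeline)
    attr(ont, "feature_links") <- bind_rows(attr(ont, "feature_links"), links)
  }
  ont
}

# Pipeline stage (term id) that produces a leaf feature, from its layout block.
feature_stage <- function(feature, pipeline) {
  cls <- vapply(feature, function(f) describe_feature(f)$feature_class, character(1))
  stage_by_class <- c("RGB histogram" = "alg:color_histogram",
                      "HSV histogram" = "alg:color_histogram",
                      "Size histogram" = "alg:size_histogram",
                      "Roundness histogram" = "alg:roundness_histogram",
                      "NN distance histogram" = "alg:nn_histogram")
  unname(stage_by_class[cls])
}

#' Structural integrity report of an ontology
#'
#' Checks that every quantification node has exactly one `describes` parent
#' and that every abnormality node reaches the taxon layer through
#' `expressed_on` then `part_of` edges.
#'
#' @param ont a `vpheno` ontology.
#' @return tibble of issues (`node`, `issue`); zero rows when valid.
#' @export
check_ontology <- function(ont) {
  issues <- list()
  quant <- ont$nodes$id[ont$nodes$layer == "phenotype_quantification"]
  for (q in quant) {
    k <- sum(ont$edges$child == q & ont$edges$relation == "describes")
    if (k != 1L) {
      issues[[length(issues) + 1L]] <-
        tibble(node = q, issue = sprintf("%d describes parents (expected 1)", k))
    }
  }
  abn <- ont$nodes$id[ont$nodes$layer == "plant_abnormality"]
  for (a in abn) {
    structs <- ont$edges$parent[ont$edges$child == a & ont$edges$relation == "expressed_on"]
    reaches <- any(vapply(structs, function(s)
      any(ont$edges$child == s & ont$edges$relation == "part_of"), logical(1)))
    if (!reaches) {
      issues[[length(issues) + 1L]] <-
        tibble(node = a, issue = "does not reach the taxon layer via expressed_on . part_of")
    }
  }
  if (length(issues) == 0L) tibble(node = character(), issue = character())
  else bind_rows(issues)
}

# -- serialization ------------------------------------------------------------

#' Write an ontology to JSON (lossless round trip)
#'
#' @param ont a [vpheno_ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(ont, path) {
  payload <- list(
    kind = ont$kind,
    nodes = lapply(seq_len(nrow(ont$nodes)), function(i) {
      list(id = ont$nodes$id[i], label = ont$nodes$label[i],
           layer = ont$nodes$layer[i],
           xref = if (is.na(ont$nodes$xref[i])) NULL else ont$nodes$xref[i],
           payload = ont$nodes$payload[[i]])
    }),
    edges = ont$edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ontology from JSON
#'
#' @param path JSON path written by [write_ontology_json()].
#' @return a `vpheno_ontology`.
#' @export
read_ontology_json <- function(path) {
  p <- tryCatch(jsonlite::read_json(path),
                error = function(e) abort(paste0("parse error in ", path, ": ",
                                                 conditionMessage(e))))
  if (is.null(p$kind) || !p$kind %in% c("vpheno", "imagery")) {
    abort(paste0("malformed ontology file (missing/unknown kind): ", path))
  }
  ont <- vpheno_ontology(p$kind)
  for (nd in p$nodes) {
    payload <- nd$payload
    if (!is.null(payload$antecedent)) {
      payload$antecedent <- bind_rows(lapply(payload$antecedent, as_tibble))
    }
    ont <- add_node(ont, nd$id, nd$label %||% nd$id, nd$layer,
                    xref = nd$xref %||% NA_character_, payload = payload)
  }
  for (e in p$edges) {
    if (!e$relation %in% c("is_a", "part_of", "expressed_on", "expressed_by", "describes")) {
      abort(paste0("unknown relation in file: ", e$relation))
    }
    ont <- add_edge(ont, e$child, e$parent, e$relation)
  }
  ont
}

owl_base <- "http://phenomap.example.org/vpheno#"

#' Export an ontology as OWL 2 (RDF/XML)
#'
#' Every node becomes an `owl:Class` with `rdfs:label` and a layer
#' annotation; `is_a` edges become `rdfs:subClassOf`; other relations become
#' `rdfs:subClassOf` of an `owl:Restriction` on the corresponding object
#' property. Rule payloads are carried as a JSON annotation property (OWL
#' has no native interval syntax).
#'
#' @param ont a [vpheno_ontology()].
#' @param path output `.owl` path.
#' @return `path`, invisibly.
#' @export
write_ontology_owl <- function(ont, path) {
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "xmlns:rdfs" = "http://www.w3.org/2000/01/rdf-schema#",
    "xmlns:owl" = "http://www.w3.org/2002/07/owl#",
    "xmlns:pm" = owl_base
  )
  onto <- xml2::xml_add_child(doc, "owl:Ontology",
                              "rdf:about" = sub("#$", "", owl_base))
  xml2::xml_add_child(onto, "rdfs:comment", paste0("kind=", ont$kind))
  for (prop in c("part_of", "expressed_on", "expressed_by", "describes")) {
    xml2::xml_add_child(doc, "owl:ObjectProperty",
                        "rdf:about" = paste0(owl_base, prop))
  }
  for (ap in c("layer", "xref", "payload")) {
    xml2::xml_add_child(doc, "owl:AnnotationProperty",
                        "rdf:about" = paste0(owl_base, ap))
  }
  for (i in seq_len(nrow(ont$nodes))) {
    cls <- xml2::xml_add_child(doc, "owl:Class",
                               "rdf:about" = paste0(owl_base, ont$nodes$id[i]))
    xml2::xml_add_child(cls, "rdfs:label", ont$nodes$label[i])
    xml2::xml_add_child(cls, "pm:layer", ont$nodes$layer[i])
    if (!is.na(ont$nodes$xref[i])) {
      xml2::xml_add_child(cls, "pm:xref", ont$nodes$xref[i])
    }
    if (!is.null(ont$nodes$payload[[i]])) {
      xml2::xml_add_child(cls, "pm:payload",
                          as.character(jsonlite::toJSON(ont$nodes$payload[[i]],
                                                        auto_unbox = TRUE, digits = NA)))
    }
    ed <- ont$edges[ont$edges$child == ont$nodes$id[i], ]
    for (k in seq_len(nrow(ed))) {
      if (ed$relation[k] == "is_a") {
        xml2::xml_add_child(cls, "rdfs:subClassOf",
                            "rdf:resource" = paste0(owl_base, ed$parent[k]))
      } else {
        sub <- xml2::xml_add_child(cls, "rdfs:subClassOf")
        restr <- xml2::xml_add_child(sub, "owl:Restriction")
        xml2::xml_add_child(restr, "owl:onProperty",
                            "rdf:resource" = paste0(owl_base, ed$relation[k]))
        xml2::xml_add_child(restr, "owl:someValuesFrom",
                            "rdf:resource" = paste0(owl_base, ed$parent[k]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an ontology from OWL written by [write_ontology_owl()]
#'
#' @param path `.owl` path.
#' @return a `vpheno_ontology`.
#' @export
read_ontology_owl <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("parse error in ", path, ": ",
                                                   conditionMessage(e))))
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#",
          pm = owl_base)
  kind <- sub("^kind=", "", xml2::xml_text(
    xml2::xml_find_first(doc, ".//owl:Ontology/rdfs:comment", ns)))
  ont <- vpheno_ontology(kind)
  classes <- xml2::xml_find_all(doc, ".//owl:Class", ns)
  strip <- function(iri) sub(paste0("^", owl_base), "", iri)
  edges <- list()
  for (cls in classes) {
    id <- strip(xml2::xml_attr(cls, "about"))
    label <- xml2::xml_text(xml2::xml_find_first(cls, "./rdfs:label", ns))
    layer <- xml2::xml_text(xml2::xml_find_first(cls, "./pm:layer", ns))
    xref_node <- xml2::xml_find_first(cls, "./pm:xref", ns)
    xref <- if (inherits(xref_node, "xml_missing")) NA_character_ else xml2::xml_text(xref_node)
    pay_node <- xml2::xml_find_first(cls, "./pm:payload", ns)
    payload <- if (inherits(pay_node, "xml_missing")) NULL else {
      p <- jsonlite::fromJSON(xml2::xml_text(pay_node), simplifyDataFrame = TRUE)
      if (!is.null(p$antecedent)) p$antecedent <- as_tibble(p$antecedent)
      p
    }
    ont <- add_node(ont, id, label, layer, xref = xref, payload = payload)
    for (sub in xml2::xml_find_all(cls, "./rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sub, "resource")
      if (!is.na(res)) {
        edges[[length(edges) + 1L]] <- tibble(child = id, parent = strip(res),
                                              relation = "is_a")
      } else {
        prop <- strip(xml2::xml_attr(
          xml2::xml_find_first(sub, ".//owl:onProperty", ns), "resource"))
        tgt <- strip(xml2::xml_attr(
          xml2::xml_find_first(sub, ".//owl:someValuesFrom", ns), "resource"))
        edges[[length(edges) + 1L]] <- tibble(child = id, parent = tgt,
                                              relation = prop)
      }
    }
  }
  for (e in if (length(edges)) seq_len(nrow(bind_rows(edges))) else integer(0)) {
    ee <- bind_rows(edges)[e, ]
    ont <- add_edge(ont, ee$child, ee$parent, ee$relation)
  }
  ont
}

# -- pipeline -----------------------------------------------------------------

#' The standard leaf-processing pipeline, annotated with imagery-ontology terms
#'
#' Ordered stages from raw image to normalized feature blocks; each stage
#' carries its imagery/algorithms-ontology term id, parameters, and
#' input/output kinds (the output kind of each stage is the input kind of
#' the next).
#'
#' @param config a [leaf_pipeline_config()] supplying stage parameters.
#' @return tibble with `stage`, `term_id`, `input_kind`, `output_kind`,
#'   `params` (list column).
#' @export
maize_pipeline <- function(config = leaf_pipeline_config()) {
  tibble(
    stage = c("background_segmentation", "tissue_classification",
              "lesion_extraction", "color_histograms", "size_histogram",
              "roundness_histogram", "nn_histogram", "block_normalization"),
    term_id = c("img:background_segmentation", "img:tissue_classification",
                "img:lesion_extraction", "alg:color_histogram",
                "alg:size_histogram", "alg:roundness_histogram",
                "alg:nn_histogram", "rep:block_normalization"),
    input_kind = c("raw_image", "leaf_mask", "tissue_labels", "lesion_set",
                   "lesion_set", "lesion_set", "lesion_set", "raw_vector"),
    output_kind = c("leaf_mask", "tissue_labels", "lesion_set", "raw_vector",
                    "raw_vector", "raw_vector", "raw_vector", "feature_vector"),
    params = list(list(tol = config$tol),
                  list(gates = config$gates),
                  list(min_lesion_area = config$min_lesion_area),
                  list(rgb_bins = 16, hue_bins = 15, sv_bins = 16),
                  list(n_bins = config$n_size_bins, max_frac = config$size_max_frac),
                  list(n_bins = config$n_roundness_bins),
                  list(n_bins = config$n_nn_bins),
                  list(method = "block_sum"))
  )
}

#' The imagery-and-algorithms ontology behind [maize_pipeline()]
#'
#' @return an `imagery`-kind [vpheno_ontology()] whose nodes resolve every
#'   pipeline stage term.
#' @export
imagery_ontology <- function() {
  ont <- vpheno_ontology("imagery")
  ont <- add_node(ont, "img:image", "phenotype image", "imagery")
  ont <- add_node(ont, "img:protocol_solid_background",
                  "solid-background imaging protocol", "imagery")
  ont <- add_node(ont, "img:background_segmentation", "background segmentation", "imagery")
  ont <- add_node(ont, "img:tissue_classification", "tissue classification", "imagery")
  ont <- add_node(ont, "img:lesion_extraction", "lesion extraction", "imagery")
  ont <- add_node(ont, "alg:measurement", "measurement algorithm", "algorithms")
  ont <- add_node(ont, "alg:color_histogram", "color histogram", "algorithms")
  ont <- add_node(ont, "alg:size_histogram", "lesion size histogram", "algorithms")
  ont <- add_node(ont, "alg:roundness_histogram", "lesion roundness histogram", "algorithms")
  ont <- add_node(ont, "alg:nn_histogram", "nearest-neighbor distance histogram", "algorithms")
  ont <- add_node(ont, "rep:normalization", "vector normalization", "machine_representation")
  ont <- add_node(ont, "rep:block_normalization", "block-sum normalization", "machine_representation")
  for (x in c("img:protocol_solid_background", "img:background_segmentation",
              "img:tissue_classification", "img:lesion_extraction")) {
    ont <- add_edge(ont, x, "img:image", "is_a")
  }
  for (x in c("alg:color_histogram", "alg:size_histogram",
              "alg:roundness_histogram", "alg:nn_histogram")) {
    ont <- add_edge(ont, x, "alg:measurement", "is_a")
  }
  ont <- add_edge(ont, "rep:block_normalization", "rep:normalization", "is_a")
  ont <- add_edge(ont, "alg:measurement", "img:image", "part_of")
  ont <- add_edge(ont, "rep:normalization", "alg:measurement", "part_of")
  ont
}

#' Validate an annotated pipeline against an imagery ontology
#'
#' Checks that every stage term resolves in the ontology, that the
#' input/output kind chain is contiguous, and that every stage carries
#' parameters.
#'
#' @param pipeline tibble as returned by [maize_pipeline()].
#' @param imagery_graph an `imagery`-kind [vpheno_ontology()].
#' @return tibble of failures (`stage`, `issue`); zero rows when valid.
#' @export
validate_pipeline <- function(pipeline, imagery_graph = imagery_ontology()) {
  issues <- list()
  for (i in seq_len(nrow(pipeline))) {
    if (!pipeline$term_id[i] %in% imagery_graph$nodes$id) {
      issues[[length(issues) + 1L]] <- tibble(
        stage = pipeline$stage[i],
        issue = paste0("term does not resolve in the imagery ontology: ",
                       pipeline$term_id[i]))
    }
    if (i > 1L && pipeline$input_kind[i] != pipeline$output_kind[i - 1L] &&
        !pipeline$input_kind[i] %in% pipeline$output_kind[seq_len(i - 1L)]) {
      issues[[length(issues) + 1L]] <- tibble(
        stage = pipeline$stage[i],
        issue = sprintf("kind chain broken: input '%s' not produced upstream",
                        pipeline$input_kind[i]))
    }
    if (length(pipeline$params[[i]]) == 0L) {
      issues[[length(issues) + 1L]] <- tibble(
        stage = pipeline$stage[i], issue = "missing stage parameters")
    }
  }
  if (length(issues) == 0L) tibble(stage = character(), issue = character())
  else bind_rows(issues)
}

#' A small maize-style VPhenoO skeleton (taxon to expression layers)
#'
#' Convenience builder of the four upper layers with expression nodes for
#' the leaf semantic terms, ready for [embed_rules()].
#'
#' @param terms expression-layer term labels to include.
#' @return a `vpheno`-kind [vpheno_ontology()].
#' @export
vpheno_skeleton <- function(terms = c("brown_lesions", "yellow_lesions",
                                      "elliptical_lesions", "irregular_lesions",
                                      "small_lesions", "medium_lesions", "large_lesions",
                                      "few", "moderate", "extensive")) {
  ont <- vpheno_ontology("vpheno")
  ont <- add_node(ont, "zea_mays", "Zea mays", "plant_taxon", xref = "NCBITaxon:4577")
  ont <- add_node(ont, "leaf", "leaf", "plant_structure", xref = "PO:0009025")
  ont <- add_node(ont, "lesion_mimic", "lesion mimic mutation", "plant_abnormality")
  ont <- add_edge(ont, "leaf", "zea_mays", "part_of")
  ont <- add_edge(ont, "lesion_mimic", "leaf", "expressed_on")
  for (t in terms) {
    ont <- add_node(ont, t, t, "phenotype_expression")
    ont <- add_edge(ont, t, "lesion_mimic", "expressed_by")
  }
  ont
}

#' @export
print.vpheno_ontology <- function(x, ...) {
  cat(sprintf("<vpheno_ontology (%s): %d nodes, %d edges>\n",
              x$kind, nrow(x$nodes), nrow(x$edges)))
  lc <- layer_counts(x)
  for (i in seq_len(nrow(lc))) cat(sprintf("  %-26s %d\n", lc$layer[i], lc$n[i]))
  invisible(x)
}
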