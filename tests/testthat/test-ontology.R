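# Ontology model: layer/relation validation, rule embedding, serialization,
# pipeline checks.

test_that("layer and relation rules are enforced", {
  ont <- vpheno_ontology("vpheno")
  ont <- add_node(ont, "maize", "Zea mays", "plant_taxon", xref = "NCBITaxon:4577")
  ont <- add_node(ont, "leaf", "leaf", "plant_structure", xref = "PO:0009025")
  ont <- add_node(ont, "les", "lesion mimic", "plant_abnormality")

  ont <- add_edge(ont, "leaf", "maize", "part_of")  # accepted
  expect_equal(nrow(ont$edges), 1)

  # abnormality -> structure must be expressed_on, not part_of
  expect_error(add_edge(ont, "les", "leaf", "part_of"),
               class = "phenomap_ontology_error")
  ont <- add_edge(ont, "les", "leaf", "expressed_on")

  expect_error(add_edge(ont, "leaf", "leaf", "is_a"),
               class = "phenomap_ontology_error")  # self edge
  expect_error(add_node(ont, "leaf", "again", "plant_structure"),
               class = "phenomap_ontology_error")  # duplicate id
  expect_error(add_node(ont, "x", "x", "imagery"),
               class = "phenomap_ontology_error")  # wrong-kind layer
  expect_error(add_edge(ont, "ghost", "leaf", "is_a"),
               class = "phenomap_ontology_error")  # missing endpoint

  # cycles are rejected (is_a within one layer)
  ont <- add_node(ont, "leaf2", "leaf subtype", "plant_structure")
  ont <- add_edge(ont, "leaf2", "leaf", "is_a")
  expect_error(add_edge(ont, "leaf", "leaf2", "is_a"),
               class = "phenomap_ontology_error")
})

test_that("embedding k rules adds k quantification nodes and k describes edges", {
  ont <- vpheno_skeleton()
  rules <- fuzzify(parse_rules(
    c("{F006 ∈ [0.09, 0.16] ∧ F399 ∈ [0.12, 0.21]} -> elliptical_lesions",
      "{F010 ∈ [0.3, 0.5]} -> brown_lesions",
      "{F399 ∈ [0.6, 0.9]} -> brown_lesions"),
    semantic_class = "maize"), 5)
  rules$support <- 0.2; rules$confidence <- 0.9
  before <- layer_counts(ont)
  ont2 <- embed_rules(ont, rules, pipeline = maize_pipeline())
  after <- layer_counts(ont2)
  expect_equal(after$n[after$layer == "phenotype_quantification"],
               before$n[before$layer == "phenotype_quantification"] + 3L)
  expect_equal(sum(ont2$edges$relation == "describes"), 3)
  # layer bookkeeping reports expression and quantification separately
  expect_equal(after$n[after$layer == "phenotype_expression"],
               before$n[before$layer == "phenotype_expression"])
  # payload carries the possibility parameters
  q <- ont2$nodes[ont2$nodes$layer == "phenotype_quantification", ]
  expect_true(all(c("lambda1", "lambda2", "lambda3") %in%
                    names(q$payload[[1]]$antecedent)))
  # implicit feature -> pipeline-stage links recorded
  links <- attr(ont2, "feature_links")
  expect_equal(nrow(links), 4)
  expect_equal(links$stage[links$feature == "F399"],
               rep("alg:size_histogram", 2))

  # empty rule list leaves the graph unchanged
  expect_identical(embed_rules(ont, rules[0, ])$nodes, ont$nodes)
  # unmatched consequent errors, naming the term
  bad <- rules; bad$consequent <- c("no_such_term", "brown_lesions", "brown_lesions")
  expect_error(embed_rules(ont, bad), "no_such_term")
  # the structural invariants hold on the embedded graph
  expect_equal(nrow(check_ontology(ont2)), 0)
})

test_that("JSON round trip is lossless including payloads", {
  ont <- vpheno_skeleton()
  rules <- fuzzify(parse_rules("{F010 ∈ [0.3, 0.5]} -> brown_lesions"), 5)
  rules$support <- 0.4; rules$confidence <- 0.95
  ont <- embed_rules(ont, rules)
  path <- withr::local_tempfile(fileext = ".json")
  write_ontology_json(ont, path)
  back <- read_ontology_json(path)
  expect_equal(back$kind, ont$kind)
  expect_equal(back$nodes$id, ont$nodes$id)
  expect_equal(back$nodes$layer, ont$nodes$layer)
  expect_equal(back$edges, ont$edges)
  expect_equal(layer_counts(back), layer_counts(ont))
  i <- which(back$nodes$layer == "phenotype_quantification")
  expect_equal(back$nodes$payload[[i]]$antecedent$lambda1,
               ont$nodes$payload[[i]]$antecedent$lambda1)

  # malformed file -> parse error
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"kind\": \"nope\"}", bad)
  expect_error(read_ontology_json(bad), "malformed")
})

test_that("a random valid graph survives serialize-parse identity", {
  set.seed(42)
  ont <- vpheno_ontology("vpheno")
  layers <- c("plant_taxon", "plant_structure", "plant_abnormality",
              "phenotype_expression")
  ids <- list()
  for (li in seq_along(layers)) {
    k <- sample(3:6, 1)
    ids[[li]] <- sprintf("%s_%02d", substr(layers[li], 7, 12), seq_len(k))
    for (id in ids[[li]]) ont <- add_node(ont, id, toupper(id), layers[li])
  }
  rel <- c("part_of", "expressed_on", "expressed_by")
  for (li in 2:4) {
    for (id in ids[[li]]) {
      ont <- add_edge(ont, id, sample(ids[[li - 1]], 1), rel[li - 1])
    }
    # a few intra-layer is_a edges (child index > parent index: acyclic)
    if (length(ids[[li]]) >= 3) {
      ont <- add_edge(ont, ids[[li]][3], ids[[li]][1], "is_a")
    }
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_ontology_json(ont, path)
  back <- read_ontology_json(path)
  expect_equal(back$nodes$id, ont$nodes$id)
  expect_equal(back$edges, ont$edges)
})

test_that("OWL export is valid XML and round-trips the graph", {
  ont <- vpheno_skeleton()
  rules <- fuzzify(parse_rules("{F006 ∈ [0.09, 0.16]} -> elliptical_lesions"), 5)
  rules$support <- 0.3; rules$confidence <- 1
  ont <- embed_rules(ont, rules)
  path <- withr::local_tempfile(fileext = ".owl")
  write_ontology_owl(ont, path)

  # strict XML parse with the OWL/RDF namespaces resolvable
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_true("http://www.w3.org/2002/07/owl#" %in% unlist(ns))
  classes <- xml2::xml_find_all(
    doc, ".//owl:Class", c(owl = "http://www.w3.org/2002/07/owl#"))
  expect_length(classes, nrow(ont$nodes))

  back <- read_ontology_owl(path)
  expect_equal(sort(back$nodes$id), sort(ont$nodes$id))
  expect_equal(nrow(back$edges), nrow(ont$edges))
  expect_equal(layer_counts(back), layer_counts(ont))
  qi <- which(back$nodes$layer == "phenotype_quantification")
  expect_equal(back$nodes$payload[[qi]]$antecedent$lambda2, 0.07)
})

test_that("pipeline validation catches broken chains and missing parameters", {
  pipe <- maize_pipeline()
  expect_equal(nrow(validate_pipeline(pipe)), 0)

  # swapping two stages breaks the kind chain
  swapped <- pipe[c(2, 1, 3:8), ]
  expect_gt(nrow(validate_pipeline(swapped)), 0)

  # removing a stage parameter is reported
  nopar <- pipe
  nopar$params[[3]] <- list()
  expect_true(any(grepl("parameters", validate_pipeline(nopar)$issue)))

  # a term that does not resolve is reported
  dangling <- pipe
  dangling$term_id[1] <- "img:unknown_stage"
  expect_true(any(grepl("resolve", validate_pipeline(dangling)$issue)))
})

test_that("ontology tidiers summarise nodes and layers", {
  ont <- vpheno_skeleton()
  td <- tidy(ont)
  expect_true(all(c("id", "label", "layer") %in% names(td)))
  g <- glance(ont)
  expect_equal(g$n_nodes, nrow(ont$nodes))
  expect_equal(g$plant_taxon, 1L)
})
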