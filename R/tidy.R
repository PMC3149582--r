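# broom-style tidiers for rule sets, evaluations and ontologies.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a crisp rule set: one row per antecedent condition
#'
#' @param x a `crisp_rules` tibble.
#' @param ... unused.
#' @return tibble with `rule_id`, `semantic_class`, `consequent`, `support`,
#'   `confidence`, `feature`, `lo`, `hi` (plus lambda columns for fuzzy
#'   rules).
#' @method tidy crisp_rules
#' @export
tidy.crisp_rules <- function(x, ...) {
  tidyr::unnest(
    select(as_tibble(x), rule_id, semantic_class, consequent, support,
           confidence, antecedent),
    antecedent)
}

#' @rdname tidy.crisp_rules
#' @method tidy fuzzy_rules
#' @export
tidy.fuzzy_rules <- tidy.crisp_rules

#' Tidy a resubstitution evaluation: per-term average precision
#'
#' @param x a `pheno_eval` from [evaluate_resubstitution()].
#' @param ... unused.
#' @method tidy pheno_eval
#' @export
tidy.pheno_eval <- function(x, ...) x$terms

#' One-row summary of a resubstitution evaluation
#'
#' @param x a `pheno_eval`.
#' @param ... unused.
#' @return tibble with `n_terms`, `n_classes`, `mean_ap`, `macro_map` (mean
#'   of per-class MAPs).
#' @method glance pheno_eval
#' @export
glance.pheno_eval <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), n_classes = nrow(x$classes),
         mean_ap = mean(x$terms$ap), macro_map = mean(x$classes$map))
}

#' Tidy a semantic map: its fuzzy rules, one row per condition
#'
#' @param x a `semantic_map` from [train_semantic_map()].
#' @param ... unused.
#' @method tidy semantic_map
#' @export
tidy.semantic_map <- function(x, ...) tidy(x$rules)

#' One-row summary of a semantic map
#'
#' @param x a `semantic_map`.
#' @param ... unused.
#' @method glance semantic_map
#' @export
glance.semantic_map <- function(x, ...) {
  tibble(n_rules = nrow(x$rules),
         n_terms = length(unique(x$rules$consequent)),
         n_classes = length(unique(x$rules$semantic_class)),
         mean_confidence = mean(x$rules$confidence),
         mean_support = mean(x$rules$support))
}

#' Tidy an ontology: its node table
#'
#' @param x a `vpheno_ontology`.
#' @param ... unused.
#' @method tidy vpheno_ontology
#' @export
tidy.vpheno_ontology <- function(x, ...) select(x$nodes, id, label, layer, xref)

#' One-row summary of an ontology
#'
#' @param x a `vpheno_ontology`.
#' @param ... unused.
#' @method glance vpheno_ontology
#' @export
glance.vpheno_ontology <- function(x, ...) {
  lc <- layer_counts(x)
  out <- as_tibble(as.list(setNames(lc$n, lc$layer)))
  mutate(out, kind = x$kind, n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         .before = 1)
}
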