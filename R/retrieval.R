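# Applications and evaluation: semantic search with rank fusion, automatic
# annotation, average precision and the resubstitution protocol.

map_scaled_features <- function(features, map) {
  if (inherits(map, "semantic_map")) apply_scaling(features, map$scaling) else features
}

map_rules <- function(map) {
  if (inherits(map, "semantic_map")) map$rules else map
}

#' Semantic search over a feature database
#'
#' Scores every image against each query term (maximum rule relevance) and
#' fuses the per-term score lists: `"sum"` (CombSUM, default) or
#' `"product"`. Terms without rules are dropped with a warning; if no term
#' has rules the search errors.
#'
#' @param features raw feature tibble (id column + features).
#' @param map a `semantic_map` (or a `fuzzy_rules` tibble of already
#'   rescaled features).
#' @param terms character vector of query terms.
#' @param fusion `"sum"` or `"product"`.
#' @return tibble `image_id`, `score`, ordered by decreasing score with ties
#'   broken by ascending image id.
#' @export
semantic_search <- function(features, map, terms, fusion = c("sum", "product")) {
  fusion <- match.arg(fusion)
  rules <- map_rules(map)
  have <- terms %in% rules$consequent
  if (any(!have)) {
    warn(paste0("no rules for term(s), dropped: ", paste(terms[!have], collapse = ", ")))
  }
  terms <- terms[have]
  if (length(terms) == 0L) abort("none of the query terms has rules")
  scaled <- map_scaled_features(features, map)
  scores <- relevance_scores(scaled, rules[rules$consequent %in% terms, ])
  fused <- scores |>
    group_by(image_id) |>
    summarise(score = if (fusion == "sum") sum(relevance) else prod(relevance),
              .groups = "drop") |>
    arrange(desc(score), image_id)
  fused
}

#' Annotate an image with all semantics of non-zero relevance
#'
#' @param v a raw feature vector: named numeric vector or one-row tibble.
#' @param map a `semantic_map` (or `fuzzy_rules` over rescaled features).
#' @param threshold minimum relevance to report (default: strictly positive).
#' @return tibble `term`, `relevance`, sorted by decreasing relevance; may
#'   be empty.
#' @export
annotate_image <- function(v, map, threshold = 0) {
  rules <- map_rules(map)
  if (is.numeric(v)) v <- as_tibble(as.list(v))
  if (!"image_id" %in% names(v) && !"fruit_id" %in% names(v)) {
    v <- mutate(v, image_id = "query", .before = 1)
  }
  scaled <- map_scaled_features(v, map)
  scores <- relevance_scores(scaled, rules)
  scores |>
    filter(relevance > threshold) |>
    arrange(desc(relevance), term) |>
    select(term, relevance)
}

#' Average precision of a ranked list
#'
#' Standard retrieval AP: the mean, over the relevant items, of precision at
#' each relevant item's rank. Items absent from the ranking contribute
#' precision zero.
#'
#' @param ranked character vector of ids in rank order (or a tibble with an
#'   `image_id` column as returned by [semantic_search()]).
#' @param relevant non-empty character vector of relevant ids.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(ranked, relevant) {
  if (is.data.frame(ranked)) ranked <- ranked$image_id
  if (length(relevant) == 0L) abort("relevant set must be non-empty")
  hits <- ranked %in% relevant
  prec_at <- cumsum(hits) / seq_along(ranked)
  sum(prec_at[hits]) / length(relevant)
}

# 11-point interpolated precision at recall 0, 0.1, ..., 1.
interpolated_pr <- function(ranked, relevant) {
  hits <- ranked %in% relevant
  prec <- cumsum(hits) / seq_along(ranked)
  rec <- cumsum(hits) / length(relevant)
  vapply(seq(0, 1, by = 0.1), function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
}

#' Resubstitution evaluation of a semantic map
#'
#' For each term with rules, ranks all training images by semantic relevance
#' and scores the ranking against the training labels (relevant = labeled
#' with the term at degree other than `"none"`). Terms with no relevant
#' training image are skipped with a warning. Class MAP is the mean AP over
#' the class's evaluated terms; precision-recall curves use 11-point
#' interpolated precision.
#'
#' @param features raw training feature tibble.
#' @param labels training labels (`image_id`, `semantic_class`, `term`,
#'   `degree`).
#' @param map a `semantic_map`.
#' @return object of class `pheno_eval`: list with `terms` (term, class,
#'   n_relevant, ap), `classes` (semantic_class, map), `pr` (term, recall,
#'   precision).
#' @export
evaluate_resubstitution <- function(features, labels, map) {
  rules <- map_rules(map)
  scaled <- map_scaled_features(features, map)
  id_col <- intersect(c("image_id", "fruit_id"), names(features))[1]
  ids <- features[[id_col]]
  terms <- unique(rules$consequent)
  scores <- relevance_scores(scaled, rules)
  term_rows <- list(); pr_rows <- list()
  for (t in terms) {
    rel <- unique(labels$image_id[labels$term == t & labels$degree != "none"])
    rel <- intersect(rel, ids)
    if (length(rel) == 0L) {
      warn(paste0("term has no relevant training images, skipped: ", t))
      next
    }
    cl <- labels$semantic_class[match(t, labels$term)]
    ranked <- scores |>
      filter(term == t) |>
      arrange(desc(relevance), image_id) |>
      pull(image_id)
    ap <- average_precision(ranked, rel)
    term_rows[[t]] <- tibble(semantic_class = cl, term = t,
                             n_relevant = length(rel), ap = ap)
    pr_rows[[t]] <- tibble(semantic_class = cl, term = t,
                           recall = seq(0, 1, by = 0.1),
                           precision = interpolated_pr(ranked, rel))
  }
  if (length(term_rows) == 0L) abort("no term could be evaluated")
  terms_tb <- bind_rows(term_rows)
  classes_tb <- terms_tb |>
    group_by(semantic_class) |>
    summarise(map = mean(ap), n_terms = dplyr::n(), .groups = "drop")
  structure(list(terms = terms_tb, classes = classes_tb, pr = bind_rows(pr_rows)),
            class = "pheno_eval")
}

#' @export
print.pheno_eval <- function(x, ...) {
  cat("<pheno_eval>\n")
  for (i in seq_len(nrow(x$classes))) {
    cat(sprintf("  %-18s MAP = %.3f (%d terms)\n", x$classes$semantic_class[i],
                x$classes$map[i], x$classes$n_terms[i]))
  }
  invisible(x)
}

#' Write an evaluation report as JSON and CSV
#'
#' Writes `<prefix>.json` (terms, class MAPs and PR points), `<prefix>_terms.csv`
#' and `<prefix>_pr.csv`.
#'
#' @param eval a `pheno_eval` from [evaluate_resubstitution()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eval_report <- function(eval, prefix) {
  jsonlite::write_json(list(terms = eval$terms, classes = eval$classes,
                            pr = eval$pr),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(eval$terms, paste0(prefix, "_terms.csv"), row.names = FALSE)
  utils::write.csv(eval$pr, paste0(prefix, "_pr.csv"), row.names = FALSE)
  invisible(prefix)
}
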