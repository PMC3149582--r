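# The canonical synthetic leaf study: generation, feature extraction,
# semantic-map training and resubstitution evaluation under one set of
# documented conditions.

#' Run the standard synthetic leaf study end to end
#'
#' Generates the balanced 8-template training set of
#' [leaf_study_templates()] (`8 * n_per_class` images), extracts the
#' 452-feature vectors with [leaf_study_config()], trains a semantic map
#' (interval rules of up to two conditions, best-first feature selection
#' with a per-term contrast guarantee), and evaluates resubstitution
#' retrieval.
#'
#' @param seed master seed for the image set.
#' @param n_per_class images per template (default 15, i.e. 120 images).
#' @param max_len,max_features,per_term_top,select training settings; the
#'   defaults are the study conditions.
#' @return list with `images`, `features`, `labels`, `map` (a
#'   `semantic_map`) and `eval` (a `pheno_eval`).
#' @seealso [evaluate_resubstitution()], [train_semantic_map()]
#' @export
run_leaf_study <- function(seed = 1L, n_per_class = 15L, max_len = 2L,
                           max_features = 12L, per_term_top = 5L,
                           select = "best_first") {
  images <- generate_training_set(n_per_class, leaf_study_templates(), seed = seed)
  features <- leaf_feature_matrix(images, config = leaf_study_config())
  labels <- phenotype_labels(images)
  map <- train_semantic_map(features, labels, max_len = max_len,
                            max_features = max_features,
                            per_term_top = per_term_top, select = select)
  eval <- evaluate_resubstitution(features, labels, map)
  list(images = images, features = features, labels = labels,
       map = map, eval = eval)
}

#' Run the standard synthetic fruit study end to end
#'
#' Generates fruit silhouettes from [fruit_study_templates()] (ten
#' templates: the eight shape classes at medium size plus small and large
#' round fruit), extracts the 56 morphometric features, trains a semantic
#' map for fruit shape and size, and evaluates resubstitution retrieval.
#'
#' @param seed master seed.
#' @param n_per_class images per template (default 5, i.e. 50 fruits).
#' @return list with `images`, `features`, `labels`, `map`, `eval`.
#' @export
run_fruit_study <- function(seed = 1L, n_per_class = 5L) {
  images <- generate_training_set(n_per_class, fruit_study_templates(), seed = seed)
  features <- fruit_feature_matrix(images)
  names(features)[names(features) == "fruit_id"] <- "image_id"
  labels <- phenotype_labels(images)
  map <- train_semantic_map(features, labels, max_len = 2L,
                            max_features = 10L, per_term_top = 3L,
                            select = "best_first")
  eval <- evaluate_resubstitution(features, labels, map)
  list(images = images, features = features, labels = labels,
       map = map, eval = eval)
}
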