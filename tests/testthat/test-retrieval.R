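# Semantic search, annotation, average precision, resubstitution protocol.

# Small hand-built map: two terms with disjoint single-feature intervals.
toy_map <- function() {
  fz <- fuzzify(parse_rules(c("{f1 ∈ [0.1, 0.3]} -> low",
                              "{f1 ∈ [0.7, 0.9]} -> high"),
                            semantic_class = "level"), slope_scale = 5)
  fz$support <- c(0.5, 0.5); fz$confidence <- c(1, 1)
  fz
}

toy_features <- function() {
  tibble::tibble(image_id = sprintf("im%d", 1:6),
                 f1 = c(0.2, 0.25, 0.5, 0.8, 0.85, 0.15))
}

test_that("single-term search ranks by semantic relevance with the id tie rule", {
  fz <- toy_map()
  fe <- toy_features()
  r <- semantic_search(fe, fz, "low")
  rel <- vapply(fe$f1, function(x) semantic_relevance(c(f1 = x), fz, "low"), numeric(1))
  expect_equal(r$image_id[1:3], fe$image_id[order(-rel, fe$image_id)][1:3])
  expect_true(all(diff(r$score) <= 1e-12))

  # ties broken by ascending image id
  fe2 <- tibble::tibble(image_id = c("b", "a"), f1 = c(0.2, 0.2))
  r2 <- semantic_search(fe2, fz, "low")
  expect_equal(r2$image_id, c("a", "b"))
})

test_that("fusion puts an image maximal for both query terms first", {
  fz <- fuzzify(parse_rules(c("{f1 ∈ [0.1, 0.3]} -> low",
                              "{f2 ∈ [0.6, 0.8]} -> warm"),
                            semantic_class = "mix"), 5)
  fe <- tibble::tibble(image_id = c("both", "only_low", "only_warm", "neither"),
                       f1 = c(0.2, 0.2, 0.95, 0.95),
                       f2 = c(0.7, 0.05, 0.7, 0.05))
  for (fusion in c("sum", "product")) {
    r <- semantic_search(fe, fz, c("low", "warm"), fusion = fusion)
    expect_equal(r$image_id[1], "both")
    expect_equal(r$image_id[4], "neither")
  }
  expect_warning(semantic_search(fe, fz, c("low", "nope")), "dropped")
  expect_error(suppressWarnings(semantic_search(fe, fz, "nope")), "none of the query terms")
})

test_that("annotation returns positive-relevance terms sorted", {
  fz <- toy_map()
  ann <- annotate_image(c(f1 = 0.2), fz)
  expect_equal(ann$term[1], "low")
  expect_gte(ann$relevance[1], 0.99)
  expect_true(all(diff(ann$relevance) <= 0))
  expect_true(all(ann$term %in% fz$consequent))
  # a vector far from every support region: nothing above threshold
  far <- annotate_image(c(f1 = 50), fz, threshold = 1e-6)
  expect_equal(nrow(far), 0)
})

test_that("average precision matches hand computation and brute force", {
  expect_equal(average_precision(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(average_precision(c("r1", "n", "r2"), c("r1", "r2")), (1 + 2 / 3) / 2)
  expect_error(average_precision(c("a"), character(0)), "non-empty")

  # brute-force check over all orderings of 4 items with 2 relevant
  ids <- c("a", "b", "c", "d"); rel <- c("a", "b")
  perms <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j))) {
    perms[[length(perms) + 1]] <- ids[c(i, j, k, setdiff(1:4, c(i, j, k)))]
  }
  for (p in perms) {
    ranks <- match(rel, p)
    oracle <- mean(vapply(sort(ranks), function(r) sum(ranks <= r) / r, numeric(1)))
    expect_equal(average_precision(p, rel), oracle)
  }

  # permuting non-relevant items below the last relevant rank leaves AP fixed
  ranked <- c("r1", "n1", "r2", "n2", "n3")
  expect_equal(average_precision(ranked, c("r1", "r2")),
               average_precision(c("r1", "n1", "r2", "n3", "n2"), c("r1", "r2")))
})

test_that("resubstitution on separable data gives MAP 1 and sane PR curves", {
  fe <- toy_features()
  labels <- tibble::tibble(
    image_id = fe$image_id, semantic_class = "level",
    term = ifelse(fe$f1 < 0.5, "low", ifelse(fe$f1 > 0.6, "high", "mid")),
    degree = "moderate")
  map <- train_semantic_map(fe, labels, min_support = 0.15,
                            min_confidence = 0.9, select = FALSE, n_bins = 5)
  ev <- evaluate_resubstitution(fe, labels, map)
  expect_true(all(ev$terms$ap == 1))
  expect_true(all(ev$classes$map == 1))
  # interpolated precision is non-increasing in recall
  for (t in unique(ev$pr$term)) {
    p <- ev$pr$precision[ev$pr$term == t]
    expect_true(all(diff(p) <= 1e-12))
  }
  g <- glance(ev)
  expect_equal(g$macro_map, 1)
  expect_s3_class(tidy(ev), "tbl_df")
})

test_that("shuffled labels drive MAP to chance prevalence", {
  set.seed(7)
  n <- 60
  fe <- tibble::tibble(image_id = sprintf("i%02d", 1:n), f1 = runif(n))
  fe$f1[1:30] <- runif(30, 0, 0.45); fe$f1[31:60] <- runif(30, 0.55, 1)
  labels <- tibble::tibble(image_id = fe$image_id, semantic_class = "cls",
                           term = rep(c("a", "b"), each = 30), degree = "few")
  map <- train_semantic_map(fe, labels, select = FALSE, min_confidence = 0.7)
  maps <- vapply(1:20, function(s) {
    set.seed(s)
    shuffled <- labels
    shuffled$term <- sample(shuffled$term)
    suppressWarnings(evaluate_resubstitution(fe, shuffled, map)$classes$map)
  }, numeric(1))
  # null model: AP of a random ranking concentrates near the prevalence 0.5
  expect_lt(abs(mean(maps) - 0.5), 3 * stats::sd(maps) / sqrt(20) + 0.05)
})

test_that("well-separated classes out-score overlapping ones in MAP", {
  set.seed(11)
  n <- 80
  color_term <- rep(c("redish", "blueish"), each = n / 2)
  size_term <- rep(c("smallish", "biggish"), times = n / 2)
  fe <- tibble::tibble(
    image_id = sprintf("i%02d", 1:n),
    # color feature: disjoint term ranges
    c1 = ifelse(color_term == "redish", runif(n, 0, 0.4), runif(n, 0.6, 1)),
    # size feature: heavily overlapping term ranges
    s1 = ifelse(size_term == "smallish", runif(n, 0, 0.6), runif(n, 0.4, 1)))
  labels <- dplyr::bind_rows(
    tibble::tibble(image_id = fe$image_id, semantic_class = "color",
                   term = color_term, degree = "moderate"),
    tibble::tibble(image_id = fe$image_id, semantic_class = "size",
                   term = size_term, degree = "moderate"))
  map <- train_semantic_map(fe, labels, select = FALSE, min_confidence = 0.7)
  ev <- suppressWarnings(evaluate_resubstitution(fe, labels, map))
  expect_gt(ev$classes$map[ev$classes$semantic_class == "color"],
            ev$classes$map[ev$classes$semantic_class == "size"])
})
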