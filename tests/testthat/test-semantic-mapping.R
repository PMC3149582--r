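# Rule mining, fuzzification, possibility distributions, feature selection.

test_that("rescaling maps to [0,1] and the stored scaling reapplies", {
  tb <- tibble::tibble(image_id = c("a", "b", "c"), f1 = c(2, 4, 6), f2 = c(5, 5, 5))
  sc <- rescale_features(tb)
  expect_equal(sc$f1, c(0, 0.5, 1))
  expect_equal(sc$f2, c(0, 0, 0))  # constant feature
  new <- apply_scaling(tibble::tibble(image_id = "d", f1 = 5, f2 = 9),
                       attr(sc, "scaling"))
  expect_equal(new$f1, 0.75)
})

test_that("feature selection keeps one of two duplicated features and skips noise", {
  set.seed(5)
  n <- 60
  term <- rep(c("alpha", "beta"), each = n / 2)
  f1 <- ifelse(term == "alpha", runif(n, 0, 0.4), runif(n, 0.6, 1))
  tb <- tibble::tibble(image_id = sprintf("i%02d", 1:n), f1 = f1, f2 = f1,
                       n1 = runif(n), n2 = runif(n))
  labels <- tibble::tibble(image_id = tb$image_id, semantic_class = "cls",
                           term = term, degree = "few")
  sel <- select_features(tb, labels, "cls", method = "greedy_stepwise")
  expect_equal(sum(c("f1", "f2") %in% sel), 1)  # correlation penalty drops the twin
  expect_error(select_features(tb, labels, "nope"), "not present")

  # pure-noise features are rarely selected
  hits <- vapply(1:20, function(s) {
    set.seed(s + 100)
    noise <- matrix(runif(n * 4), n)
    colnames(noise) <- paste0("z", 1:4)
    tbl <- dplyr::bind_cols(tb[c("image_id", "f1")], tibble::as_tibble(noise))
    any(paste0("z", 1:4) %in% select_features(tbl, labels, "cls"))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("greedy selection reaches at least 90% of the exhaustive merit", {
  ratios <- vapply(1:20, function(s) {
    d <- random_table(s, 30, 6)
    g <- select_features(d$features, d$labels, "cls", method = "greedy_stepwise",
                         per_term_top = 0)
    e <- select_features(d$features, d$labels, "cls", method = "exhaustive")
    attr(g, "merit") / attr(e, "merit")
  }, numeric(1))
  expect_true(all(ratios >= 0.9))
})

test_that("discretization carries intervals and round-trips membership", {
  tb <- tibble::tibble(image_id = letters[1:5], f = c(0, 0.25, 0.5, 0.75, 1))
  d <- discretize(tb, 4)
  expect_equal(as.integer(d$items[, "f"]), c(1L, 2L, 3L, 4L, 4L))  # final bin closed
  # every value lies inside its assigned interval
  for (i in 1:5) {
    b <- d$bins[d$bins$bin == d$items[i, "f"], ]
    x <- tb$f[i]
    expect_true(x >= b$lo && (x < b$hi || (x == b$hi && b$bin == 4)))
  }
  # equal frequency on 8 distinct values, 4 bins -> 2 per bin
  tb8 <- tibble::tibble(image_id = letters[1:8], f = (1:8) / 8)
  d8 <- discretize(tb8, 4, scheme = "equal_frequency")
  expect_equal(unname(table(d8$items[, "f"])), rep(2L, 4), ignore_attr = TRUE)
  # constant feature collapses with a warning
  tbc <- tibble::tibble(image_id = letters[1:4], f = rep(0.3, 4))
  expect_warning(discretize(tbc, 4, scheme = "equal_frequency"), "constant")
  expect_error(discretize(tb, 1), "n_bins")
})

test_that("the miner returns the textbook separable rule", {
  tb <- tibble::tibble(image_id = sprintf("i%02d", 1:10),
                       f1 = c(seq(0.02, 0.42, length.out = 5),
                              seq(0.55, 0.95, length.out = 5)))
  labels <- tibble::tibble(image_id = tb$image_id, semantic_class = "cls",
                           term = rep(c("A", "B"), each = 5), degree = "moderate")
  rules <- mine_rules(discretize(tb, 2), labels, "cls",
                      min_support = 0.3, min_confidence = 0.9, max_len = 1)
  a_rules <- rules[rules$consequent == "A", ]
  expect_gte(nrow(a_rules), 1)
  top <- a_rules[1, ]
  expect_equal(top$antecedent[[1]]$lo, 0)
  expect_equal(top$antecedent[[1]]$hi, 0.5)
  expect_equal(top$support, 0.5)
  expect_equal(top$confidence, 1.0)
})

test_that("min_support = 0.9 on balanced two-class data yields no rules", {
  d <- random_table(3, 20, 2)
  expect_warning(
    rules <- mine_rules(discretize(d$features, 4), d$labels, "cls",
                        min_support = 0.9, min_confidence = 0.5),
    "mining skipped")
  expect_equal(nrow(rules), 0)
})

test_that("miner output equals brute-force enumeration on random tables", {
  for (s in 1:12) {
    n_feats <- sample(2:4, 1)
    n_bins <- sample(2:4, 1)
    n_rows <- sample(10:30, 1)
    d <- random_table(s, n_rows, n_feats)
    mined <- suppressWarnings(
      mine_rules(discretize(d$features, n_bins), d$labels, "cls",
                 min_support = 0.2, min_confidence = 0.7, max_len = 2))
    oracle <- brute_force_rules(d$features, d$labels, "cls", n_bins,
                                min_support = 0.2, min_confidence = 0.7, max_len = 2)
    expect_identical(rule_keys(mined), oracle)
  }
})

test_that("mining a class without two supported terms warns and returns nothing", {
  d <- random_table(9, 20, 2)
  d$labels$term <- "alpha"
  expect_warning(r <- mine_rules(discretize(d$features, 4), d$labels, "cls"),
                 "mining skipped")
  expect_equal(nrow(r), 0)
})

test_that("the worked rule round-trips through text and JSON", {
  txt <- "{F006 ∈ [0.09, 0.16] ∧ F399 ∈ [0.12, 0.21]} -> elliptical_lesions"
  rules <- parse_rules(txt, semantic_class = "lesion_shape")
  expect_equal(rules$consequent, "elliptical_lesions")
  a <- rules$antecedent[[1]]
  expect_equal(a$feature, c("F006", "F399"))
  expect_equal(a$lo, c(0.09, 0.12))
  expect_equal(a$hi, c(0.16, 0.21))
  expect_equal(parse_rules(format_rules(rules))$antecedent[[1]], a)

  fz <- fuzzify(rules, slope_scale = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rules_json(fz, path)
  back <- read_rules_json(path)
  expect_s3_class(back, "fuzzy_rules")
  expect_equal(back$antecedent[[1]], fz$antecedent[[1]])
  expect_equal(back$consequent, fz$consequent)
})

test_that("fuzzification computes center, width and slope", {
  rules <- parse_rules("{F006 ∈ [0.09, 0.16]} -> x")
  fz <- fuzzify(rules, slope_scale = 5)
  a <- fz$antecedent[[1]]
  expect_equal(a$lambda1, 0.125)
  expect_equal(a$lambda2, 0.07)
  expect_equal(a$lambda3, 5 / 0.07)
  fz2 <- fuzzify(rules, slope_scale = 10)
  expect_equal(fz2$antecedent[[1]]$lambda3, 2 * a$lambda3)  # slope doubles
  expect_equal(nrow(fz), nrow(rules))  # rule count preserved

  degenerate <- rules
  degenerate$antecedent[[1]]$hi <- degenerate$antecedent[[1]]$lo
  expect_error(fuzzify(degenerate), "zero-width")
})

test_that("the possibility function obeys its limit properties", {
  expect_equal(possibility(0.125, 0.125, 0.07, 70), 1)  # exactly 1 at the center

  # steep slope approximates the crisp indicator away from the edges
  l1 <- 0.5; l2 <- 0.2; l3 <- 1e4
  xs <- seq(0, 1, by = 0.001)
  inside <- xs > l1 - l2 / 2 + 0.005 & xs < l1 + l2 / 2 - 0.005
  outside <- xs < l1 - l2 / 2 - 0.005 | xs > l1 + l2 / 2 + 0.005
  p <- possibility(xs, l1, l2, l3)
  expect_true(all(abs(p[inside] - 1) < 1e-3))
  expect_true(all(p[outside] < 1e-3))

  # monotone decay away from the interval, vanishing in the tails
  p2 <- possibility(seq(0.6, 3, by = 0.1), 0.5, 0.2, 20)
  expect_true(all(diff(p2) <= 1e-12))
  expect_lt(possibility(50, 0.5, 0.2, 20), 1e-10)

  # a far-away measurement has near-zero relevance for the reference
  # interval [0.107, 0.196]
  cond_l1 <- (0.107 + 0.196) / 2
  cond_l2 <- 0.196 - 0.107
  expect_lt(possibility(0.96, cond_l1, cond_l2, 5 / cond_l2), 0.05)

  # inside the crisp interval the possibility never drops below the edges
  edge <- possibility(0.107, cond_l1, cond_l2, 5 / cond_l2)
  interior <- possibility(seq(0.11, 0.19, by = 0.005), cond_l1, cond_l2, 5 / cond_l2)
  expect_true(all(interior >= edge - 1e-12))
})

test_that("rule and semantic relevance combine conditions as t-norms", {
  fz <- fuzzify(parse_rules("{f1 ∈ [0.2, 0.4] ∧ f2 ∈ [0.6, 0.8]} -> t"), 5)
  v <- c(f1 = 0.3, f2 = 0.7)  # both centers
  expect_equal(rule_relevance(v, fz[1, ]), 1)
  # one condition far outside dominates the min t-norm
  v2 <- c(f1 = 0.3, f2 = 3)
  expect_lt(rule_relevance(v2, fz[1, ]), 1e-6)
  expect_error(rule_relevance(c(f1 = 0.3), fz[1, ]), "missing")

  # min >= product pointwise
  set.seed(2)
  for (i in 1:25) {
    v3 <- c(f1 = runif(1), f2 = runif(1))
    expect_gte(rule_relevance(v3, fz[1, ], "min"),
               rule_relevance(v3, fz[1, ], "product"))
  }

  # semantic relevance: max over rules, 0 without rules, monotone in rules
  fz2 <- fuzzify(parse_rules(c("{f1 ∈ [0.2, 0.4]} -> t", "{f2 ∈ [0.6, 0.8]} -> t")), 5)
  v4 <- c(f1 = 0.9, f2 = 0.7)
  expect_equal(semantic_relevance(v4, fz2, "t"),
               max(rule_relevance(v4, fz2[1, ]), rule_relevance(v4, fz2[2, ])))
  expect_equal(semantic_relevance(v4, fz2, "absent_term"), 0)
  expect_gte(semantic_relevance(v4, fz2, "t"),
             semantic_relevance(v4, fz2[1, ], "t"))
})

test_that("mined intervals recover a class-specific generative range", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    term <- rep(c("c", "d"), each = n / 2)
    f <- ifelse(term == "c", runif(n, 0.15, 0.55), runif(n, 0.65, 0.95))
    tb <- tibble::tibble(image_id = sprintf("i%03d", 1:n), f = f,
                         g = runif(n), h = runif(n))
    labels <- tibble::tibble(image_id = tb$image_id, semantic_class = "cls",
                             term = term, degree = "moderate")
    rules <- mine_rules(discretize(tb, 10), labels, "cls",
                        min_support = 0.05, min_confidence = 0.8, max_len = 2)
    top <- rules[rules$consequent == "c", ][1, ]
    a <- top$antecedent[[1]]
    a <- a[a$feature == "f", ]
    if (nrow(a) != 1) return(FALSE)
    overlap <- max(0, min(a$hi, 0.55) - max(a$lo, 0.15))
    overlap / (0.55 - 0.15) >= 0.9
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("train_semantic_map wires selection, mining and fuzzification", {
  d <- random_table(21, 40, 3)
  m <- train_semantic_map(d$features, d$labels, min_support = 0.1,
                          min_confidence = 0.8, select = FALSE)
  expect_s3_class(m, "semantic_map")
  expect_s3_class(m$rules, "fuzzy_rules")
  expect_gt(nrow(m$rules), 0)
  expect_true(all(c("lambda1", "lambda2", "lambda3") %in%
                    names(m$rules$antecedent[[1]])))
  g <- glance(m)
  expect_equal(g$n_rules, nrow(m$rules))
  td <- tidy(m)
  expect_true(all(c("feature", "lo", "hi", "lambda1") %in% names(td)))
})
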