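# Semantic mapping: mine crisp quantitative class-association rules linking
# feature intervals to semantic terms, then fuzzify the antecedents into
# possibility distributions so relevance becomes graded.

# -- rescaling ----------------------------------------------------------------

#' Min-max rescale features to [0, 1]
#'
#' Per-feature min-max over the training table; the scaling parameters are
#' kept (attribute `scaling`) so new images can be mapped into the same
#' space at inference time. Constant features rescale to 0.
#'
#' @param features tibble with an id column (`image_id` or `fruit_id`) and
#'   numeric feature columns.
#' @return rescaled tibble with attribute `scaling` (tibble: feature, lo, hi).
#' @export
rescale_features <- function(features) {
  id_col <- intersect(c("image_id", "fruit_id"), names(features))
  num <- setdiff(names(features), id_col)
  lo <- vapply(features[num], min, numeric(1))
  hi <- vapply(features[num], max, numeric(1))
  out <- features
  for (j in num) {
    rng <- hi[j] - lo[j]
    out[[j]] <- if (rng > 0) (features[[j]] - lo[j]) / rng else rep(0, nrow(features))
  }
  attr(out, "scaling") <- tibble(feature = num, lo = unname(lo), hi = unname(hi))
  out
}

#' Apply a stored scaling to new features
#'
#' @param features tibble of raw features.
#' @param scaling tibble from [rescale_features()]'s `scaling` attribute.
#' @return rescaled tibble (values may fall outside `[0,1]` if the new data
#'   exceed the training range; they are left unclipped so the possibility
#'   tails handle them).
#' @export
apply_scaling <- function(features, scaling) {
  out <- features
  for (i in seq_len(nrow(scaling))) {
    f <- scaling$feature[i]
    if (!f %in% names(out)) next
    rng <- scaling$hi[i] - scaling$lo[i]
    out[[f]] <- if (rng > 0) (features[[f]] - scaling$lo[i]) / rng else rep(0, nrow(features))
  }
  out
}

# -- feature selection --------------------------------------------------------

# Correlation-based merit of a feature subset: mean feature-class
# correlation penalized by mean inter-feature correlation.
cfs_merit <- function(rcf, rff, subset) {
  k <- length(subset)
  mean_rcf <- mean(rcf[subset])
  mean_rff <- if (k > 1) mean(rff[subset, subset][upper.tri(diag(k))]) else 0
  (k * mean_rcf) / sqrt(k + k * (k - 1) * mean_rff)
}

#' Select discriminative, non-redundant features for a semantic class
#'
#' Correlation-based subset selection: the merit of a subset is its mean
#' feature-to-class correlation (maximum one-vs-rest point-biserial
#' correlation over the class's terms) penalized by the mean absolute
#' correlation between the selected features, so duplicated or highly
#' correlated features are excluded. Deterministic given the table.
#'
#' @param features tibble with id column and numeric features (any scale).
#' @param labels tibble with `image_id`, `semantic_class`, `term`, `degree`.
#' @param semantic_class the class to separate (e.g. `"lesion_color"`).
#' @param method `"greedy_stepwise"` (forward selection), `"best_first"`
#'   (forward with backtracking, stale limit 5), or `"exhaustive"` (all
#'   subsets; at most 15 candidate features).
#' @param max_features cap on the subset size.
#' @param per_term_top in addition to the merit search, guarantee each term
#'   its `per_term_top` most discriminative features by single-bin contrast
#'   (the largest difference, over ten equal-width bins, between the bin
#'   occupancy of the term's rows and the remaining rows). Unlike a linear
#'   correlation, the contrast also detects interval signatures that sit in
#'   the middle of a feature's range, which is what interval-valued rules
#'   can express.
#' @return character vector of selected feature names, with the achieved
#'   merit in attribute `merit`.
#' @export
select_features <- function(features, labels, semantic_class,
                            method = c("greedy_stepwise", "best_first", "exhaustive"),
                            max_features = 8L, per_term_top = 1L) {
  method <- match.arg(method)
  id_col <- intersect(c("image_id", "fruit_id"), names(features))[1]
  lab <- labels[labels$semantic_class == semantic_class & labels$degree != "none", ]
  if (nrow(lab) == 0L) abort(paste0("semantic class not present in labels: ", semantic_class))
  terms <- unique(lab$term)
  X <- as.matrix(features[setdiff(names(features), id_col)])
  ids <- features[[id_col]]
  # feature-class correlation: max one-vs-rest |cor| over terms
  rcf_mat <- vapply(terms, function(t) {
    y <- as.numeric(ids %in% lab$image_id[lab$term == t])
    if (stats::sd(y) == 0) return(rep(0, ncol(X)))
    r <- suppressWarnings(abs(stats::cor(X, y)))
    r[is.na(r)] <- 0
    as.numeric(r)
  }, numeric(ncol(X)))
  rcf <- apply(rcf_mat, 1, max)
  names(rcf) <- colnames(X)
  p <- ncol(X)
  if (method == "exhaustive" && p > 15L) {
    abort("exhaustive search permitted only for <= 15 candidate features")
  }
  rff <- suppressWarnings(abs(stats::cor(X)))
  rff[is.na(rff)] <- 0
  if (method == "exhaustive") {
    best <- NULL; best_m <- -Inf
    for (k in 1:min(p, max_features)) {
      for (s in utils::combn(p, k, simplify = FALSE)) {
        m <- cfs_merit(rcf, rff, s)
        if (m > best_m + 1e-12) { best_m <- m; best <- s }
      }
    }
    sel <- best
  } else {
    stale_limit <- if (method == "best_first") 5L else 1L
    sel <- integer(0); best_m <- -Inf; stale <- 0L
    repeat {
      cand <- setdiff(seq_len(p), sel)
      if (length(cand) == 0L || length(sel) >= max_features) break
      merits <- vapply(cand, function(j) cfs_merit(rcf, rff, c(sel, j)), numeric(1))
      j <- cand[which.max(merits)]
      if (max(merits) > best_m + 1e-12) {
        best_m <- max(merits); sel <- c(sel, j); stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= stale_limit) break
        sel <- c(sel, j)  # tentative expansion (best-first keeps exploring)
      }
    }
    # drop any tentative tail that did not improve the merit
    while (length(sel) > 1 &&
           cfs_merit(rcf, rff, sel) < cfs_merit(rcf, rff, sel[-length(sel)]) - 1e-12) {
      sel <- sel[-length(sel)]
    }
    # guarantee every term its most discriminative features (by single-bin
    # contrast), so no term of the class is left without usable dimensions
    Xs <- apply(X, 2, function(x) {
      r <- range(x)
      if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
    })
    bins10 <- matrix(pmin(pmax(floor(10 * Xs) + 1L, 1L), 10L), nrow(X), p)
    for (t in terms) {
      in_t <- ids %in% lab$image_id[lab$term == t]
      contrast <- vapply(seq_len(p), function(j) {
        tb_t <- tabulate(bins10[in_t, j], 10) / sum(in_t)
        tb_r <- tabulate(bins10[!in_t, j], 10) / sum(!in_t)
        max(abs(tb_t - tb_r))
      }, numeric(1))
      best_t <- order(-contrast, seq_len(p))[seq_len(min(per_term_top, p))]
      sel <- union(sel, best_t)
    }
  }
  out <- sort(colnames(X)[sel])
  attr(out, "merit") <- cfs_merit(rcf, rff, sel)
  out
}

# -- discretization -----------------------------------------------------------

#' Discretize rescaled features into interval-carrying bins
#'
#' Each feature value is mapped to a bin item carrying its interval
#' `[lo, hi)`; the final bin is closed. `equal_width` cuts `[0, 1]` into
#' `n_bins` fixed-width bins; `equal_frequency` uses sample quantiles (a
#' constant feature collapses to a single bin with a warning).
#'
#' @param features rescaled tibble (see [rescale_features()]).
#' @param n_bins number of bins (>= 2).
#' @param scheme `"equal_width"` or `"equal_frequency"`.
#' @return object of class `pheno_discretized`: list with `items` (n x p
#'   matrix of 1-based bin indices), `bins` (tibble: feature, bin, lo, hi),
#'   `ids`, `n_bins`, `scheme`.
#' @export
discretize <- function(features, n_bins = 10L, scheme = c("equal_width", "equal_frequency")) {
  scheme <- match.arg(scheme)
  if (n_bins < 2L) abort("n_bins must be >= 2")
  id_col <- intersect(c("image_id", "fruit_id"), names(features))
  num <- setdiff(names(features), id_col)
  ids <- if (length(id_col)) features[[id_col[1]]] else as.character(seq_len(nrow(features)))
  items <- matrix(NA_integer_, nrow(features), length(num), dimnames = list(NULL, num))
  bins <- list()
  for (j in num) {
    x <- features[[j]]
    if (scheme == "equal_width") {
      edges <- seq(0, 1, length.out = n_bins + 1)
    } else {
      # edges at midpoints between boundary order statistics, so bins stay
      # half-open [lo, hi) and balanced for distinct values
      xs <- sort(x)
      if (length(unique(xs)) == 1L) {
        warn(paste0("constant feature under equal_frequency: ", j, " (single bin)"))
        edges <- c(min(0, xs[1]), max(1, xs[1]))
      } else {
        pos <- round(seq_len(n_bins - 1) * length(xs) / n_bins)
        inner <- (xs[pos] + xs[pmin(pos + 1L, length(xs))]) / 2
        edges <- unique(c(min(0, xs[1]), inner, max(1, xs[length(xs)])))
      }
    }
    nb <- length(edges) - 1L
    bi <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
    bi <- pmin(pmax(bi, 1L), nb)
    items[, j] <- bi
    bins[[j]] <- tibble(feature = j, bin = seq_len(nb),
                        lo = edges[-length(edges)], hi = edges[-1])
  }
  structure(list(items = items, bins = bind_rows(bins), ids = ids,
                 n_bins = n_bins, scheme = scheme),
            class = "pheno_discretized")
}

# -- rule mining --------------------------------------------------------------

empty_rules <- function() {
  structure(
    tibble(rule_id = integer(), semantic_class = character(),
           consequent = character(), support = numeric(),
           confidence = numeric(), length = integer(), antecedent = list()),
    class = c("crisp_rules", class(tibble())))
}

#' Mine quantitative class-association rules
#'
#' Enumerates every rule `A -> term` whose antecedent is a conjunction of at
#' most `max_len` per-feature intervals (each interval a run of adjacent
#' bins; the full-range interval is excluded as uninformative), whose
#' support (fraction of rows matching both antecedent and term) is at least
#' `min_support`, and whose confidence is at least `min_confidence`. The
#' search is a level-wise enumeration with anti-monotone support pruning,
#' output-identical to brute-force enumeration of all antecedents.
#'
#' A term is *relevant* for a row when the row carries the term with degree
#' other than `"none"`. Mining is skipped with a warning unless the class
#' has at least two distinct terms with at least `min_support * n` rows.
#'
#' @param disc a `pheno_discretized` from [discretize()].
#' @param labels tibble with `image_id`, `semantic_class`, `term`, `degree`.
#' @param semantic_class class whose terms become rule consequents.
#' @param min_support,min_confidence thresholds in `(0, 1]`.
#' @param max_len maximum antecedent length.
#' @param distinct_masks when `TRUE`, candidate intervals of a feature that
#'   match exactly the same training rows (they differ only across empty
#'   bins) are collapsed to the narrowest such interval. The returned rule
#'   set is then a reduced but row-equivalent family; leave `FALSE` for the
#'   complete enumeration.
#' @return a `crisp_rules` tibble: `rule_id`, `semantic_class`, `consequent`,
#'   `support`, `confidence`, `length`, `antecedent` (list column of
#'   tibbles: feature, lo, hi), sorted by confidence then support.
#' @export
mine_rules <- function(disc, labels, semantic_class,
                       min_support = 0.05, min_confidence = 0.8, max_len = 3L,
                       distinct_masks = FALSE) {
  stopifnot(inherits(disc, "pheno_discretized"))
  if (min_support <= 0 || min_support > 1 || min_confidence <= 0 || min_confidence > 1) {
    abort("thresholds must lie in (0, 1]")
  }
  lab <- labels[labels$semantic_class == semantic_class & labels$degree != "none", ]
  n <- nrow(disc$items)
  terms <- sort(unique(lab$term))
  big <- vapply(terms, function(t) sum(disc$ids %in% lab$image_id[lab$term == t]),
                numeric(1))
  ok_terms <- terms[big >= min_support * n]
  if (length(ok_terms) < 2L) {
    warn(sprintf("semantic class '%s' lacks two terms with support >= %g; mining skipped",
                 semantic_class, min_support))
    return(empty_rules())
  }
  feats <- colnames(disc$items)
  # per-feature candidate intervals: all runs of adjacent bins except the
  # full range, as row masks
  cond_list <- list()
  for (f in feats) {
    fb <- disc$bins[disc$bins$feature == f, ]
    nb <- nrow(fb)
    bi <- disc$items[, f]
    seen <- character(0)
    for (w in 0:(nb - 1L)) {       # narrow intervals first
      for (i in seq_len(nb - w)) {
        j <- i + w
        if (i == 1L && j == nb) next
        mask <- bi >= i & bi <= j
        if (distinct_masks) {
          key <- paste(which(mask), collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
        }
        cond_list[[length(cond_list) + 1L]] <- list(
          feature = f, lo = fb$lo[i], hi = fb$hi[j], mask = mask)
      }
    }
  }
  cond_feat <- vapply(cond_list, `[[`, character(1), "feature")
  feat_rank <- match(cond_feat, feats)
  min_count <- min_support * n
  # accumulators kept flat for speed; antecedents materialized once at the end
  acc <- new.env(parent = emptyenv())
  acc$consequent <- character(0); acc$support <- numeric(0)
  acc$confidence <- numeric(0); acc$conds <- list()
  for (t in ok_terms) {
    target <- disc$ids %in% lab$image_id[lab$term == t]
    recurse <- function(mask, cond_idx, last_rank) {
      for (ci in which(feat_rank > last_rank)) {
        m2 <- mask & cond_list[[ci]]$mask
        hit <- sum(m2 & target)
        if (hit < min_count) next
        idx2 <- c(cond_idx, ci)
        conf <- hit / sum(m2)
        if (conf >= min_confidence) {
          k <- length(acc$conds) + 1L
          acc$consequent[k] <- t
          acc$support[k] <- hit / n
          acc$confidence[k] <- conf
          acc$conds[[k]] <- idx2
        }
        if (length(idx2) < max_len) recurse(m2, idx2, feat_rank[ci])
      }
    }
    recurse(rep(TRUE, n), integer(0), 0L)
  }
  if (length(acc$conds) == 0L) return(empty_rules())
  ante_list <- lapply(acc$conds, function(idx) {
    tibble::new_tibble(list(
      feature = cond_feat[idx],
      lo = vapply(cond_list[idx], `[[`, numeric(1), "lo"),
      hi = vapply(cond_list[idx], `[[`, numeric(1), "hi")), nrow = length(idx))
  })
  out <- tibble(semantic_class = semantic_class, consequent = acc$consequent,
                support = acc$support, confidence = acc$confidence,
                length = vapply(ante_list, nrow, integer(1)),
                antecedent = ante_list)
  key <- vapply(out$antecedent, function(a)
    paste(a$feature, sprintf("%.12g", a$lo), sprintf("%.12g", a$hi), collapse = ";"),
    character(1))
  out <- out[order(-out$confidence, -out$support, out$length, out$consequent, key), ]
  out <- mutate(out, rule_id = row_number(), .before = 1)
  structure(out, class = c("crisp_rules", class(tibble())))
}

# Database-coverage rule selection: walk rules per term in confidence /
# support order and keep a rule only when it crisp-matches at least one
# relevant training row no already-kept rule matches.
prune_by_coverage <- function(rules, scaled, labels, max_rules_per_term) {
  id_col <- intersect(c("image_id", "fruit_id"), names(scaled))[1]
  ids <- scaled[[id_col]]
  rule_mask <- function(a) {
    m <- rep(TRUE, nrow(scaled))
    for (k in seq_len(nrow(a))) {
      x <- scaled[[a$feature[k]]]
      m <- m & x >= a$lo[k] & (x < a$hi[k] | (a$hi[k] >= 1 & x <= a$hi[k]))
    }
    m
  }
  keep <- logical(nrow(rules))
  for (t in unique(rules$consequent)) {
    rel <- ids %in% labels$image_id[labels$term == t & labels$degree != "none"]
    covered <- rep(FALSE, length(ids))
    n_kept <- 0L
    for (i in which(rules$consequent == t)) {
      if (n_kept >= max_rules_per_term) break
      m <- rule_mask(rules$antecedent[[i]])
      if (any(m & rel & !covered)) {
        keep[i] <- TRUE
        covered <- covered | m
        n_kept <- n_kept + 1L
      }
    }
  }
  out <- rules[keep, ]
  out$rule_id <- seq_len(nrow(out))
  structure(out, class = c("crisp_rules", class(tibble())))
}

# -- fuzzification ------------------------------------------------------------

#' Fuzzify crisp rules into possibility-distribution rules
#'
#' Each crisp interval `[lo, hi]` becomes a possibility distribution with
#' center `lambda1 = (lo + hi) / 2`, width `lambda2 = hi - lo`, and slope
#' `lambda3 = slope_scale / lambda2` (narrow intervals get steeper edges).
#'
#' @param rules a `crisp_rules` tibble from [mine_rules()].
#' @param slope_scale positive scale of the logistic edge slope.
#' @return a `fuzzy_rules` tibble; each antecedent tibble gains `lambda1`,
#'   `lambda2`, `lambda3`.
#' @export
fuzzify <- function(rules, slope_scale = 5) {
  stopifnot(slope_scale > 0)
  out <- rules
  out$antecedent <- lapply(rules$antecedent, function(a) {
    if (any(a$hi <= a$lo)) abort("zero-width interval cannot be fuzzified")
    mutate(a,
           lambda1 = (lo + hi) / 2,
           lambda2 = hi - lo,
           lambda3 = slope_scale / (hi - lo))
  })
  class(out) <- c("fuzzy_rules", setdiff(class(rules), "crisp_rules"))
  out
}

#' Possibility of a feature value under a fuzzified condition
#'
#' A renormalized product of two logistic edges: a rising edge at
#' `lambda1 - lambda2/2` and a falling edge at `lambda1 + lambda2/2`, both
#' with slope `lambda3`, divided by the product's value at `lambda1` so that
#' `possibility(lambda1) = 1` exactly. Monotone non-increasing away from the
#' interval and tending to 0 as `x` recedes; as `lambda3` grows it converges
#' to the crisp indicator of `[lambda1 - lambda2/2, lambda1 + lambda2/2]`.
#'
#' @param x feature value(s) on the rescaled `[0,1]` axis.
#' @param lambda1 center.
#' @param lambda2 width (> 0).
#' @param lambda3 slope (> 0).
#' @return possibility value(s) in `[0, 1]`.
#' @export
possibility <- function(x, lambda1, lambda2, lambda3) {
  stopifnot(all(lambda2 > 0), all(lambda3 > 0))
  lo <- lambda1 - lambda2 / 2
  hi <- lambda1 + lambda2 / 2
  raw <- stats::plogis(lambda3 * (x - lo)) * stats::plogis(-lambda3 * (x - hi))
  peak <- stats::plogis(lambda3 * lambda2 / 2)^2
  pmin(raw / peak, 1)
}

#' Relevance of a feature vector to one fuzzy rule
#'
#' Combines the per-condition possibilities with a t-norm: `"min"`
#' (default) or `"product"`.
#'
#' @param v named numeric vector or one-row tibble of rescaled features.
#' @param rule one row of a `fuzzy_rules` tibble (or a list with an
#'   `antecedent` tibble).
#' @param tnorm `"min"` or `"product"`.
#' @return relevance in `[0, 1]`.
#' @export
rule_relevance <- function(v, rule, tnorm = c("min", "product")) {
  tnorm <- match.arg(tnorm)
  a <- if (is.data.frame(rule$antecedent)) rule$antecedent else rule$antecedent[[1]]
  if (is.data.frame(v)) v <- unlist(v[1, sapply(v, is.numeric)])
  missing <- setdiff(a$feature, names(v))
  if (length(missing)) {
    abort(paste0("feature(s) missing from vector: ", paste(missing, collapse = ", ")))
  }
  p <- possibility(v[a$feature], a$lambda1, a$lambda2, a$lambda3)
  if (tnorm == "min") min(p) else prod(p)
}

#' Relevance of a feature vector to a semantic term
#'
#' Maximum relevance over the term's rules; 0 when the term has no rules.
#'
#' @param v named numeric vector or one-row tibble of rescaled features.
#' @param rules a `fuzzy_rules` tibble.
#' @param term semantic term; defaults to using all rules in `rules`.
#' @param tnorm passed to [rule_relevance()].
#' @return relevance in `[0, 1]`.
#' @export
semantic_relevance <- function(v, rules, term = NULL, tnorm = "min") {
  rr <- if (is.null(term)) rules else rules[rules$consequent == term, ]
  if (nrow(rr) == 0L) return(0)
  max(vapply(seq_len(nrow(rr)), function(i)
    rule_relevance(v, rr[i, ], tnorm = tnorm), numeric(1)))
}

# Relevance of every row of a rescaled feature table to every term with
# rules: long tibble (image_id, term, relevance). Vectorized over rows.
relevance_scores <- function(features, rules, tnorm = "min") {
  id_col <- intersect(c("image_id", "fruit_id"), names(features))[1]
  ids <- features[[id_col]]
  terms <- unique(rules$consequent)
  out <- list()
  for (t in terms) {
    rr <- rules[rules$consequent == t, ]
    best <- rep(0, nrow(features))
    for (i in seq_len(nrow(rr))) {
      a <- rr$antecedent[[i]]
      p <- rep(1, nrow(features))
      for (k in seq_len(nrow(a))) {
        pk <- possibility(features[[a$feature[k]]], a$lambda1[k], a$lambda2[k], a$lambda3[k])
        p <- if (tnorm == "min") pmin(p, pk) else p * pk
      }
      best <- pmax(best, p)
    }
    out[[t]] <- tibble(image_id = ids, term = t, relevance = best)
  }
  bind_rows(out)
}

# -- rendering & serialization ------------------------------------------------

#' Render a rule in interval-conjunction syntax
#'
#' Produces strings like
#' `"{F006 ∈ [0.09, 0.16] ∧ F399 ∈ [0.12, 0.21]} -> elliptical_lesion"`.
#'
#' @param rules a `crisp_rules` or `fuzzy_rules` tibble.
#' @param digits significant digits for interval bounds.
#' @return character vector, one string per rule.
#' @export
format_rules <- function(rules, digits = 3) {
  vapply(seq_len(nrow(rules)), function(i) {
    a <- rules$antecedent[[i]]
    conds <- sprintf("%s ∈ [%s, %s]", a$feature,
                     formatC(a$lo, digits = digits, format = "fg"),
                     formatC(a$hi, digits = digits, format = "fg"))
    sprintf("{%s} -> %s", paste(conds, collapse = " ∧ "), rules$consequent[i])
  }, character(1))
}

#' Parse rules rendered by [format_rules()]
#'
#' @param text character vector of rule strings.
#' @param semantic_class class recorded on the parsed rules.
#' @return a `crisp_rules` tibble (support/confidence are `NA`: the text
#'   form does not carry them).
#' @export
parse_rules <- function(text, semantic_class = NA_character_) {
  rows <- lapply(seq_along(text), function(i) {
    s <- text[i]
    m <- regmatches(s, regexec("^\\{(.*)\\} *(->|→) *(.+)$", s))[[1]]
    if (length(m) == 0L) abort(paste0("cannot parse rule: ", s))
    conds <- strsplit(m[2], " *∧ *")[[1]]
    cm <- regmatches(conds, regexec(
      "^ *([A-Za-z0-9_]+) *∈ *\\[ *([-0-9.eE+]+) *, *([-0-9.eE+]+) *\\] *$", conds))
    if (any(vapply(cm, length, integer(1)) == 0L)) abort(paste0("cannot parse antecedent: ", s))
    ante <- tibble(feature = vapply(cm, `[`, character(1), 2),
                   lo = as.numeric(vapply(cm, `[`, character(1), 3)),
                   hi = as.numeric(vapply(cm, `[`, character(1), 4)))
    tibble(rule_id = i, semantic_class = semantic_class,
           consequent = trimws(m[4]), support = NA_real_,
           confidence = NA_real_, length = nrow(ante), antecedent = list(ante))
  })
  structure(bind_rows(rows), class = c("crisp_rules", class(tibble())))
}

#' Write rules to JSON (round-trip stable)
#'
#' @param rules a `crisp_rules` or `fuzzy_rules` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules_json <- function(rules, path) {
  payload <- list(
    fuzzy = inherits(rules, "fuzzy_rules"),
    rules = lapply(seq_len(nrow(rules)), function(i) {
      list(semantic_class = rules$semantic_class[i],
           consequent = rules$consequent[i],
           support = rules$support[i],
           confidence = rules$confidence[i],
           antecedent = rules$antecedent[[i]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read rules written by [write_rules_json()]
#'
#' @param path JSON path.
#' @return a `crisp_rules` or `fuzzy_rules` tibble.
#' @export
read_rules_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  rs <- payload$rules
  n <- length(rs$consequent)
  ante <- rs$antecedent
  if (is.data.frame(ante)) ante <- list(ante)
  out <- tibble(
    rule_id = seq_len(n),
    semantic_class = as.character(rs$semantic_class),
    consequent = as.character(rs$consequent),
    support = as.numeric(rs$support),
    confidence = as.numeric(rs$confidence),
    length = vapply(ante, nrow, integer(1)),
    antecedent = lapply(ante, as_tibble)
  )
  cls <- if (isTRUE(payload$fuzzy)) "fuzzy_rules" else "crisp_rules"
  structure(out, class = c(cls, class(tibble())))
}

# -- end-to-end trainer -------------------------------------------------------

#' Train a semantic map: select, discretize, mine, fuzzify
#'
#' Convenience pipeline over a feature table and labels: rescales features,
#' then per semantic class selects features, mines crisp rules and fuzzifies
#' them. The returned map carries the scaling so new raw feature vectors can
#' be scored directly.
#'
#' @param features raw feature tibble (id column + numeric features).
#' @param labels tibble with `image_id`, `semantic_class`, `term`, `degree`.
#' @param classes semantic classes to map; default all classes in `labels`.
#' @param n_bins,scheme passed to [discretize()].
#' @param min_support,min_confidence,max_len passed to [mine_rules()].
#' @param slope_scale passed to [fuzzify()].
#' @param select method for [select_features()], or `FALSE` to use all
#'   features.
#' @param max_features cap for [select_features()].
#' @param max_rules_per_term keep at most this many rules per consequent
#'   term; `Inf` keeps the complete set. Mining enumerates every qualifying
#'   rule, which on cleanly separable data is combinatorially large; the map
#'   retains a concise subset chosen by database coverage (the selection
#'   used by classic class-association-rule classifiers): rules are taken in
#'   confidence-then-support order and kept only when they match at least
#'   one relevant training image not matched by an already-kept rule, so
#'   redundant interval variants collapse and every coverable training image
#'   keeps a covering rule.
#' @param per_term_top passed to [select_features()].
#' @return object of class `semantic_map`: list with `rules` (fuzzy),
#'   `crisp_rules`, `scaling`, `selected` (per-class feature sets), and the
#'   mining parameters.
#' @export
train_semantic_map <- function(features, labels, classes = NULL,
                               n_bins = 10L, scheme = "equal_width",
                               min_support = 0.05, min_confidence = 0.8,
                               max_len = 3L, slope_scale = 5,
                               select = "greedy_stepwise", max_features = 6L,
                               max_rules_per_term = 25L, per_term_top = 1L) {
  classes <- classes %||% unique(labels$semantic_class)
  scaled <- rescale_features(features)
  scaling <- attr(scaled, "scaling")
  id_col <- intersect(c("image_id", "fruit_id"), names(features))[1]
  crisp <- list(); selected <- list()
  for (cl in classes) {
    feats <- if (identical(select, FALSE)) {
      setdiff(names(features), id_col)
    } else {
      select_features(scaled, labels, cl, method = select,
                      max_features = max_features, per_term_top = per_term_top)
    }
    selected[[cl]] <- feats
    disc <- discretize(scaled[c(id_col, feats)], n_bins = n_bins, scheme = scheme)
    mined <- mine_rules(disc, labels, cl, min_support = min_support,
                        min_confidence = min_confidence, max_len = max_len,
                        distinct_masks = TRUE)
    if (nrow(mined) > 0) {
      mined <- prune_by_coverage(mined, scaled, labels, max_rules_per_term)
    }
    crisp[[cl]] <- mined
  }
  crisp_all <- structure(bind_rows(crisp), class = c("crisp_rules", class(tibble())))
  crisp_all$rule_id <- seq_len(nrow(crisp_all))
  fuzzy <- if (nrow(crisp_all)) fuzzify(crisp_all, slope_scale) else
    structure(crisp_all, class = c("fuzzy_rules", class(tibble())))
  structure(list(rules = fuzzy, crisp_rules = crisp_all, scaling = scaling,
                 selected = selected,
                 params = list(n_bins = n_bins, scheme = scheme,
                               min_support = min_support,
                               min_confidence = min_confidence,
                               max_len = max_len, slope_scale = slope_scale)),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  cat(sprintf("<semantic_map: %d fuzzy rules for %d terms in %d classes>\n",
              nrow(x$rules), length(unique(x$rules$consequent)),
              length(unique(x$rules$semantic_class))))
  invisible(x)
}
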