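# Independent oracles and small fixture builders used across the suite.

# Brute-force class-association rule miner: enumerates every antecedent as a
# conjunction of per-feature contiguous-bin intervals (full-range intervals
# excluded) by direct expansion, and scores support/confidence by filtering
# the rescaled feature table with interval membership. Independent of the
# package's level-wise search.
brute_force_rules <- function(features, labels, semantic_class, n_bins,
                              min_support, min_confidence, max_len) {
  id_col <- intersect(c("image_id", "fruit_id"), names(features))[1]
  feats <- setdiff(names(features), id_col)
  ids <- features[[id_col]]
  n <- nrow(features)
  edges <- seq(0, 1, length.out = n_bins + 1)
  intervals <- list()
  for (f in feats) {
    for (i in seq_len(n_bins)) {
      for (j in i:n_bins) {
        if (i == 1 && j == n_bins) next
        intervals[[length(intervals) + 1]] <- list(feature = f, lo = edges[i], hi = edges[j + 1])
      }
    }
  }
  matches <- function(cond) {
    x <- features[[cond$feature]]
    if (cond$hi >= 1) x >= cond$lo & x <= cond$hi else x >= cond$lo & x < cond$hi
  }
  lab <- labels[labels$semantic_class == semantic_class & labels$degree != "none", ]
  terms <- sort(unique(lab$term))
  big <- vapply(terms, function(t) sum(ids %in% lab$image_id[lab$term == t]), numeric(1))
  terms <- terms[big >= min_support * n]
  if (length(terms) < 2) return(character(0))
  out <- character(0)
  ifeat <- vapply(intervals, function(c) c$feature, character(1))
  for (t in terms) {
    target <- ids %in% lab$image_id[lab$term == t]
    for (k in seq_len(max_len)) {
      combos <- utils::combn(length(intervals), k, simplify = FALSE)
      for (cmb in combos) {
        if (anyDuplicated(ifeat[cmb])) next
        m <- Reduce(`&`, lapply(intervals[cmb], matches))
        hit <- sum(m & target)
        if (hit < min_support * n) next
        if (hit / sum(m) < min_confidence) next
        conds <- intervals[cmb]
        ord <- order(vapply(conds, function(c) c$feature, character(1)))
        out <- c(out, paste0(t, "|", paste(vapply(conds[ord], function(c)
          sprintf("%s[%.10g,%.10g]", c$feature, c$lo, c$hi), character(1)),
          collapse = "&")))
      }
    }
  }
  sort(out)
}

# Canonical key set of a mined crisp_rules tibble, comparable with the
# oracle's output.
rule_keys <- function(rules) {
  if (nrow(rules) == 0) return(character(0))
  sort(vapply(seq_len(nrow(rules)), function(i) {
    a <- rules$antecedent[[i]]
    a <- a[order(a$feature), ]
    paste0(rules$consequent[i], "|", paste(sprintf("%s[%.10g,%.10g]",
                                                   a$feature, a$lo, a$hi), collapse = "&"))
  }, character(1)))
}

# Random small training table (features already in [0,1]) with a two-term
# label column; rows get class-dependent shifts so some rules exist.
random_table <- function(seed, n_rows, n_feats) {
  set.seed(seed)
  term <- sample(c("alpha", "beta"), n_rows, replace = TRUE)
  X <- matrix(runif(n_rows * n_feats), n_rows, n_feats)
  X[term == "alpha", 1] <- runif(sum(term == "alpha"), 0, 0.6)
  X[term == "beta", 1] <- runif(sum(term == "beta"), 0.4, 1)
  features <- tibble::as_tibble(as.data.frame(X))
  names(features) <- sprintf("F%03d", seq_len(n_feats))
  features <- dplyr::mutate(features, image_id = sprintf("im%03d", seq_len(n_rows)),
                            .before = 1)
  labels <- tibble::tibble(image_id = features$image_id, semantic_class = "cls",
                           term = term, degree = "moderate")
  list(features = features, labels = labels)
}

# Rasterize a filled ellipse mask (axis-aligned), for geometry oracles.
ellipse_mask <- function(a, b, pad = 4) {
  cx <- a + pad; cy <- b + pad
  nr <- 2 * (b + pad) + 1; nc <- 2 * (a + pad) + 1
  xs <- 0:(nc - 1); ys <- 0:(nr - 1)
  outer(ys, xs, function(y, x) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
}

# Tissue-label matrix from a list of masks: 3 = necrotic, 2 = chlorotic,
# over a "leaf" covering everything (1).
labels_from_masks <- function(nr, nc, necrotic = list(), chlorotic = list()) {
  m <- matrix(1L, nr, nc)
  for (msk in necrotic) m[msk] <- 3L
  for (msk in chlorotic) m[msk] <- 2L
  m
}
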