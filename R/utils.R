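# Internal helpers shared across modules: seeded evaluation, color space
# conversion, and 8-connected component labeling.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# n x 3 RGB matrix (values in [0,1]) -> n x 3 matrix with columns
# h (degrees in [0, 360)), s, v in [0,1].
rgb_to_hsv_deg <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 3)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
  out <- t(hsv)
  out[, 1] <- (out[, 1] * 360) %% 360
  colnames(out) <- c("h", "s", "v")
  out
}

# n x 3 sRGB matrix in [0,1] -> n x 3 CIE L*a*b* (D65 white point).
rgb_to_lab <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 3)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

# Flatten an H x W x 3 image array to an n x 3 matrix for a pixel index set.
pixels_rgb <- function(img, idx) {
  hw <- dim(img)[1] * dim(img)[2]
  cbind(img[idx], img[idx + hw], img[idx + 2L * hw])
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected; diagonally adjacent labels are merged exactly with union-find
# over the (small) label set, then relabeled 1..k.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  new_id <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- new_id[lab[lab > 0L]]
  lab
}

# Fill interior holes of a logical mask.
fill_holes <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  filled <- EBImage::fillHull(m)
  matrix(as.integer(filled) > 0L, nrow(mask), ncol(mask))
}

# Exposed 4-edge count of a pixel set given as linear indices into an
# nr x nc grid: 4*area minus twice the number of 4-adjacent pairs.
edge_perimeter <- function(idx, nr, nc) {
  if (length(idx) == 0L) return(0)
  present <- logical(nr * nc)
  present[idx] <- TRUE
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  right <- idx[co < nc & present[pmin(idx + nr, nr * nc)]]
  down <- idx[r < nr & present[idx + 1L]]
  4 * length(idx) - 2 * (length(right) + length(down))
}

# Maximum pairwise (Feret) diameter of a pixel set, computed on convex hull
# vertices of pixel centers; >= 1 by convention for non-empty sets.
feret_diameter <- function(x, y) {
  n <- length(x)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  if (n > 3L) {
    h <- grDevices::chull(x, y)
    x <- x[h]; y <- y[h]
  }
  d <- max(stats::dist(cbind(x, y)))
  max(d, 1)
}

# Run-length encode a logical matrix (column-major) for JSON sidecars.
rle_encode <- function(mask) {
  r <- rle(as.integer(mask))
  list(dims = dim(mask), values = r$values, lengths = r$lengths)
}

rle_decode <- function(enc) {
  v <- inverse.rle(list(values = as.integer(enc$values),
                        lengths = as.integer(enc$lengths)))
  matrix(v > 0L, enc$dims[[1]], enc$dims[[2]])
}

`%||%` <- rlang::`%||%`
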