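# Synthetic maize-style leaf images with pixel-level ground truth.
#
# The generator emulates the statistical structure the semantic-mapping
# method assumes: lesions of a controlled tissue class (necrotic brown /
# chlorotic yellow), size class (disjoint area ranges), shape class
# (elliptical vs irregular, with separated roundness ranges) and spatial
# pattern, drawn on an elongated leaf blade over a solid background.

# -- class-range configuration ------------------------------------------------

#' Synthetic leaf generator configuration
#'
#' Class ranges used by [generate_leaf()]. Lesion size classes map to
#' pairwise-disjoint area ranges (px^2); elliptical lesions draw an axis
#' ratio from `elliptical_axis_ratio` (roundness equals the axis ratio, so
#' the range also fixes the roundness band); irregular lesions perturb a
#' disk radially with relative amplitude from `irregular_amplitude`, which
#' pushes roundness well below the elliptical band. Coverage degree is a
#' monotone step function of lesion count with thresholds
#' `coverage_breaks` (few <= first, moderate <= second, extensive above).
#'
#' The default area bands sit inside distinct bins of the default size
#' histogram (bin width = leaf area / 120 for the standard blade), so that a
#' pairwise-merged lesion of one class never lands in another class's band.
#'
#' @param size_ranges named list of `c(lo, hi)` area ranges in px^2.
#' @param elliptical_axis_ratio range of minor/major axis ratio.
#' @param irregular_amplitude range of relative radial perturbation.
#' @param coverage_breaks two increasing integer thresholds on lesion count.
#' @param tissue_colors,lesion_colors named RGB triples in `[0,1]`.
#' @param noise_sd per-pixel Gaussian color noise (clipped to `[0,1]`).
#' @return a named list, to pass as `config` to [generate_leaf()].
#' @export
leaf_config <- function(size_ranges = list(small = c(40, 180),
                                           medium = c(240, 410),
                                           large = c(1320, 1480)),
                        elliptical_axis_ratio = c(0.71, 0.76),
                        irregular_amplitude = c(0.7, 0.95),
                        coverage_breaks = c(2L, 12L),
                        tissue_colors = list(green = c(0.20, 0.55, 0.20),
                                             yellow = c(0.80, 0.74, 0.25),
                                             brown = c(0.45, 0.30, 0.15)),
                        lesion_colors = list(brown_necrotic = c(0.46, 0.27, 0.11),
                                             yellow_chlorotic = c(0.86, 0.80, 0.20)),
                        noise_sd = 0.008) {
  lo <- vapply(size_ranges, `[`, numeric(1), 1)
  hi <- vapply(size_ranges, `[`, numeric(1), 2)
  ord <- c("small", "medium", "large")
  stopifnot(setequal(names(size_ranges), ord))
  lo <- lo[ord]; hi <- hi[ord]
  if (any(lo >= hi) || any(hi[-3] >= lo[-1])) {
    abort("size-class area ranges must be disjoint and ordered small < medium < large")
  }
  if (length(coverage_breaks) != 2L || diff(coverage_breaks) <= 0) {
    abort("coverage_breaks must be two increasing thresholds")
  }
  list(size_ranges = size_ranges[ord],
       elliptical_axis_ratio = elliptical_axis_ratio,
       irregular_amplitude = irregular_amplitude,
       coverage_breaks = as.integer(coverage_breaks),
       tissue_colors = tissue_colors,
       lesion_colors = lesion_colors,
       noise_sd = noise_sd)
}

#' Coverage degree implied by a lesion count
#'
#' @param n integer lesion count(s).
#' @param breaks the two thresholds from [leaf_config()].
#' @return character vector in `none`, `few`, `moderate`, `extensive`.
#' @export
coverage_degree <- function(n, breaks = leaf_config()$coverage_breaks) {
  out <- rep("extensive", length(n))
  out[n <= breaks[2]] <- "moderate"
  out[n <= breaks[1]] <- "few"
  out[n == 0] <- "none"
  out
}

# -- specs --------------------------------------------------------------------

#' Specification of one synthetic leaf image
#'
#' A fully deterministic description of a leaf image: identical specs
#' (including `seed`) produce bit-identical rasters.
#'
#' @param lesion_count integer >= 0.
#' @param lesion_color_class `"brown_necrotic"` or `"yellow_chlorotic"`.
#' @param lesion_size_class `"small"`, `"medium"` or `"large"`.
#' @param lesion_shape_class `"elliptical"` or `"irregular"`.
#' @param spatial_pattern `"uniform"`, `"clustered"`, `"tip_biased"`,
#'   `"base_biased"`, or `"spaced"` (uniform positions with hard-core
#'   inhibition: lesions are rejected until they touch no earlier lesion,
#'   guaranteeing contact-free placement; all other patterns allow touching
#'   and overlap).
#' @param leaf_tissue_class `"green"`, `"yellow"` or `"brown"`.
#' @param image_size `c(width, height)` in pixels; the leaf blade runs along
#'   the horizontal axis, base at the left.
#' @param background_color solid background RGB triple in `[0,1]`.
#' @param seed integer RNG seed.
#' @param config class ranges from [leaf_config()].
#' @return an object of class `leaf_spec`.
#' @export
leaf_spec <- function(lesion_count = 8,
                      lesion_color_class = c("brown_necrotic", "yellow_chlorotic"),
                      lesion_size_class = c("medium", "small", "large"),
                      lesion_shape_class = c("elliptical", "irregular"),
                      spatial_pattern = c("uniform", "clustered", "tip_biased",
                                          "base_biased", "spaced"),
                      leaf_tissue_class = c("green", "yellow", "brown"),
                      image_size = c(360L, 120L),
                      background_color = c(0.10, 0.15, 0.55),
                      seed = 1L,
                      config = leaf_config()) {
  lesion_count <- as.integer(lesion_count)
  if (is.na(lesion_count) || lesion_count < 0L) abort("lesion_count must be a non-negative integer")
  spec <- list(
    kind = "leaf",
    image_size = as.integer(image_size),
    background_color = background_color,
    leaf_tissue_class = match.arg(leaf_tissue_class),
    lesion_count = lesion_count,
    lesion_color_class = match.arg(lesion_color_class),
    lesion_size_class = match.arg(lesion_size_class),
    lesion_shape_class = match.arg(lesion_shape_class),
    spatial_pattern = match.arg(spatial_pattern),
    coverage_degree = coverage_degree(lesion_count, config$coverage_breaks),
    seed = as.integer(seed),
    config = config
  )
  structure(spec, class = "leaf_spec")
}

# -- leaf blade geometry ------------------------------------------------------

# Logical leaf mask: an elongated blade with a long horizontal axis, broader
# near the base (left) and tapering to the tip (right).
leaf_blade_mask <- function(W, H) {
  x0 <- round(0.03 * W); x1 <- round(0.97 * W)
  cy <- (H - 1) / 2
  xs <- 0:(W - 1)
  u <- (xs - x0) / (x1 - x0)
  half <- ifelse(u >= 0 & u <= 1, 0.42 * H * sin(pi * pmin(pmax(u, 0), 1)^0.85)^0.55, -1)
  ys <- 0:(H - 1)
  outer(ys, xs, function(y, x) abs(y - cy) <= half[x + 1])
}

# -- lesion stamps ------------------------------------------------------------

# Build one lesion pixel mask (as linear indices into an nr x nc grid)
# centered at (cx, cy) [0-based], with target area A. Returns NULL when the
# stamp does not fit inside the leaf mask.
stamp_lesion <- function(shape_class, A, cx, cy, leaf, config) {
  nr <- nrow(leaf); nc <- ncol(leaf)
  if (shape_class == "elliptical") {
    q <- runif(1, config$elliptical_axis_ratio[1], config$elliptical_axis_ratio[2])
    a <- sqrt(A / (pi * q)); b <- q * a
    th <- runif(1, 0, pi)
    r_ext <- ceiling(a) + 1L
    xs <- max(0, floor(cx - r_ext)):min(nc - 1, ceiling(cx + r_ext))
    ys <- max(0, floor(cy - r_ext)):min(nr - 1, ceiling(cy + r_ext))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- u^2 + v^2 <= 1
  } else {
    amp <- runif(1, config$irregular_amplitude[1], config$irregular_amplitude[2])
    # even harmonics only: the perturbation is symmetric across the center,
    # so the maximum diameter always sees the full amplitude and roundness
    # stays well below the elliptical band
    ph <- runif(3, 0, 2 * pi)
    w <- runif(3, 0.3, 1)
    zraw <- function(phi) {
      w[1] * cos(2 * phi + ph[1]) + w[2] * cos(4 * phi + ph[2]) +
        w[3] * cos(6 * phi + ph[3])
    }
    zmax <- max(abs(zraw(seq(0, 2 * pi, length.out = 512))))
    zfun <- function(phi) zraw(phi) / zmax
    r0 <- sqrt(A / pi)
    # one calibration pass so the realized area tracks the target
    phi_g <- seq(0, 2 * pi, length.out = 360)
    mean_r2 <- mean((1 + amp * zfun(phi_g))^2)
    r0 <- r0 / sqrt(mean_r2)
    r_ext <- ceiling(r0 * (1 + amp)) + 1L
    xs <- max(0, floor(cx - r_ext)):min(nc - 1, ceiling(cx + r_ext))
    ys <- max(0, floor(cy - r_ext)):min(nr - 1, ceiling(cy + r_ext))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    inside <- rho <= r0 * (1 + amp * zfun(phi))
  }
  if (!any(inside)) return(NULL)
  rows <- ((ys[row(inside)[inside]]) + 1L)
  cols <- ((xs[col(inside)[inside]]) + 1L)
  idx <- rows + (cols - 1L) * nr
  if (!all(leaf[idx])) return(NULL)  # must lie fully inside the blade
  idx
}

# Sample a candidate lesion centroid (0-based x, y) for a spatial pattern.
sample_centroid <- function(pattern, leaf, centers = NULL) {
  nr <- nrow(leaf)
  fg <- which(leaf)
  if (pattern %in% c("uniform", "spaced")) {
    i <- fg[sample.int(length(fg), 1)]
  } else if (pattern == "clustered") {
    ctr <- centers[sample.int(nrow(centers), 1), ]
    repeat {
      x <- round(ctr[1] + rnorm(1, 0, 18))
      y <- round(ctr[2] + rnorm(1, 0, 10))
      if (x >= 0 && y >= 0 && x < ncol(leaf) && y < nr && leaf[y + 1, x + 1]) {
        i <- (y + 1) + x * nr
        break
      }
    }
  } else {
    u <- if (pattern == "tip_biased") rbeta(1, 4, 1.6) else rbeta(1, 1.6, 4)
    cols_occ <- which(colSums(leaf) > 0)
    x <- cols_occ[1] + floor(u * (length(cols_occ) - 1))
    rows_occ <- which(leaf[, x])
    y <- rows_occ[sample.int(length(rows_occ), 1)] - 1L
    i <- (y + 1) + (x - 1L) * nr
  }
  i <- unname(i)
  c(x = ((i - 1L) %/% nr), y = ((i - 1L) %% nr))
}

# -- generator ----------------------------------------------------------------

#' Generate a synthetic leaf image with ground truth
#'
#' Draws `spec$lesion_count` lesions of the configured color, size and shape
#' class on an elongated leaf blade over a solid background. Identical specs
#' yield bit-identical output. Lesions may touch or overlap (no rejection of
#' contact), so downstream segmentation can exercise component merging.
#'
#' @param spec a [leaf_spec()].
#' @return an object of class `leaf_image`: a list with `image` (H x W x 3
#'   array in `[0,1]`), `id`, `protocol` (background color), `labels`
#'   (tibble: semantic_class, term, degree), and `truth` (leaf mask, lesion
#'   tibble with per-lesion geometry, per-lesion pixel index sets).
#' @seealso [generate_fruit()], [generate_training_set()]
#' @export
generate_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  cfg <- spec$config
  W <- spec$image_size[1]; H <- spec$image_size[2]
  with_local_seed(spec$seed, {
    leaf <- leaf_blade_mask(W, H)
    nr <- H
    rng <- cfg$size_ranges[[spec$lesion_size_class]]
    n <- spec$lesion_count
    # packing limit: lesions may overlap, but the requested count must not
    # exceed the blade's area budget
    if (n * mean(rng) > 0.6 * sum(leaf)) {
      abort(sprintf(
        "lesion_count %d of size class '%s' exceeds the leaf packing limit",
        n, spec$lesion_size_class), class = "phenomap_placement_error")
    }
    centers <- NULL
    if (spec$spatial_pattern == "clustered" && n > 0) {
      k <- max(1L, ceiling(n / 8))
      fg <- which(leaf)
      ci <- fg[sample.int(length(fg), k)]
      centers <- cbind(x = (ci - 1L) %/% nr, y = (ci - 1L) %% nr)
    }
    masks <- vector("list", n)
    info <- vector("list", n)
    # occupancy of already-placed lesions, dilated by one pixel in the
    # 8-neighborhood, for the hard-core "spaced" pattern
    occupied <- if (spec$spatial_pattern == "spaced") {
      matrix(FALSE, nr, W)
    } else NULL
    if (n > 0) {
      for (i in seq_len(n)) {
        A <- runif(1, rng[1], rng[2])
        placed <- FALSE
        for (try in seq_len(200L)) {
          ctr <- sample_centroid(spec$spatial_pattern, leaf, centers)
          idx <- stamp_lesion(spec$lesion_shape_class, A, ctr[["x"]], ctr[["y"]], leaf, cfg)
          if (!is.null(idx) && length(idx) >= 3L &&
              (is.null(occupied) || !any(occupied[idx]))) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort(sprintf(
            "unable to place lesion %d of %d inside the leaf (packing limit reached)",
            i, n), class = "phenomap_placement_error")
        }
        masks[[i]] <- idx
        rows <- ((idx - 1L) %% nr)
        cols <- ((idx - 1L) %/% nr)
        if (!is.null(occupied)) {
          # mark the lesion plus its 8-neighborhood as occupied
          for (dr in -1:1) for (dc in -1:1) {
            r2 <- rows + dr; c2 <- cols + dc
            ok <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < W
            occupied[(r2[ok] + 1L) + c2[ok] * nr] <- TRUE
          }
        }
        info[[i]] <- tibble(
          lesion_id = i,
          tissue_class = if (spec$lesion_color_class == "brown_necrotic") "necrotic" else "chlorotic",
          area = length(idx),
          centroid_x = mean(cols),
          centroid_y = mean(rows),
          target_area = A
        )
      }
    }
    # compose raster
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_color[ch]
    tis <- cfg$tissue_colors[[spec$leaf_tissue_class]]
    leaf_idx <- which(leaf)
    hw <- H * W
    for (ch in 1:3) img[leaf_idx + (ch - 1L) * hw] <- tis[ch]
    les_col <- cfg$lesion_colors[[spec$lesion_color_class]]
    for (i in seq_len(n)) {
      for (ch in 1:3) img[masks[[i]] + (ch - 1L) * hw] <- les_col[ch]
    }
    if (cfg$noise_sd > 0) {
      noise_idx <- rep(leaf_idx, times = 3) + rep(0:2, each = length(leaf_idx)) * hw
      img[noise_idx] <- img[noise_idx] + rnorm(length(noise_idx), 0, cfg$noise_sd)
      img <- clip01(img)
    }
    lesions <- if (n > 0) bind_rows(info) else
      tibble(lesion_id = integer(), tissue_class = character(), area = integer(),
             centroid_x = numeric(), centroid_y = numeric(), target_area = numeric())
    structure(list(
      image = img,
      id = sprintf("leaf_%s_%d", spec$lesion_color_class, spec$seed),
      protocol = list(background_color = spec$background_color, kind = "solid_background"),
      labels = leaf_labels(spec),
      spec = spec,
      truth = list(leaf_mask = leaf, lesions = lesions, lesion_masks = masks)
    ), class = c("leaf_image", "pheno_image"))
  })
}

# Semantic labels with degree-of-appearance codes implied by the spec.
leaf_labels <- function(spec) {
  deg <- spec$coverage_degree
  if (spec$lesion_count == 0L) {
    return(tibble(semantic_class = "lesion_coverage", term = "none", degree = "none"))
  }
  color_term <- if (spec$lesion_color_class == "brown_necrotic") "brown_lesions" else "yellow_lesions"
  tibble(
    semantic_class = c("lesion_coverage", "lesion_color", "lesion_size", "lesion_shape"),
    term = c(deg, color_term,
             paste0(spec$lesion_size_class, "_lesions"),
             paste0(spec$lesion_shape_class, "_lesions")),
    degree = deg
  )
}

#' Per-lesion binary mask from ground truth
#'
#' @param x a `leaf_image`.
#' @param i lesion index.
#' @return logical matrix of the image size.
#' @export
lesion_mask <- function(x, i) {
  stopifnot(inherits(x, "leaf_image"))
  m <- matrix(FALSE, dim(x$image)[1], dim(x$image)[2])
  m[x$truth$lesion_masks[[i]]] <- TRUE
  m
}

#' @export
print.leaf_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<leaf_image %s: %dx%d px, %d lesions (%s, %s, %s), pattern %s>\n",
              x$id, d[2], d[1], nrow(x$truth$lesions),
              x$spec$lesion_color_class, x$spec$lesion_size_class,
              x$spec$lesion_shape_class, x$spec$spatial_pattern))
  invisible(x)
}
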