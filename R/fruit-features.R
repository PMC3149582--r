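# Fruit morphometrics: a re-implementation of the 56 Tomato-Analyzer-style
# features (geometry, shape indices, color averages, 37-bin hue histogram in
# CIE LCh space).

#' Measure a single fruit
#'
#' Geometry comes from the binary foreground mask: the axis-aligned bounding
#' box gives maximum width and height; the widths/heights at the middle of
#' the box give the "at middle" measures; curved height is the arc length of
#' the vertical medial curve (per-row span centers). Color averages are over
#' foreground pixels.
#'
#' @param image a `fruit_image`, an H x W x 3 RGB array (foreground = pixels
#'   away from `background_color`), or a logical mask (geometry only).
#' @param background_color RGB triple for bare arrays.
#' @param tol RGB distance threshold for foreground.
#' @return object of class `fruit_measurements`: a named list with
#'   `perimeter`, `area`, `width_mid_height`, `max_width`,
#'   `height_mid_width`, `max_height`, `curved_height`, `shape_index_1`,
#'   `shape_index_2`, `curved_shape_index`, `avg_r/g/b`, `avg_luminosity`,
#'   `avg_L/a/b`, `avg_hue` (degrees, CIE LCh), `avg_chroma`, and
#'   `hcl_histogram` (37 normalized hue bins).
#' @export
measure_fruit <- function(image, background_color = NULL, tol = 0.15) {
  img <- NULL
  if (is.logical(image) && is.matrix(image)) {
    mask <- image
  } else {
    img <- as_image_array(image)
    bg <- background_color %||%
      (if (inherits(image, "pheno_image")) image$protocol$background_color else NULL)
    if (is.null(bg)) abort("background_color is required for a bare image array")
    d2 <- (img[, , 1] - bg[1])^2 + (img[, , 2] - bg[2])^2 + (img[, , 3] - bg[3])^2
    mask <- d2 > tol^2
  }
  if (!any(mask)) abort("empty mask: no fruit foreground")
  lab <- label_components(mask)
  if (max(lab) > 1L) abort("expected single fruit: mask has multiple components")
  nr <- nrow(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rmin <- min(rows); rmax <- max(rows)
  cmin <- min(cols); cmax <- max(cols)
  max_height <- rmax - rmin + 1L
  max_width <- cmax - cmin + 1L
  mid_row <- rmin + (max_height - 1L) %/% 2L
  mid_col <- cmin + (max_width - 1L) %/% 2L
  crow <- cols[rows == mid_row]
  ccol <- rows[cols == mid_col]
  width_mid_height <- max(crow) - min(crow) + 1L
  height_mid_width <- max(ccol) - min(ccol) + 1L
  # medial curve: center of the horizontal span in each occupied row
  ctr <- vapply(rmin:rmax, function(r) {
    cc <- cols[rows == r]
    if (length(cc) == 0L) NA_real_ else (min(cc) + max(cc)) / 2
  }, numeric(1))
  ctr <- ctr[!is.na(ctr)]
  curved_height <- if (length(ctr) > 1L) sum(sqrt(1 + diff(ctr)^2)) + 1 else 1
  out <- list(
    perimeter = edge_perimeter(idx, nr, ncol(mask)),
    area = length(idx),
    width_mid_height = width_mid_height,
    max_width = max_width,
    height_mid_width = height_mid_width,
    max_height = max_height,
    curved_height = curved_height,
    shape_index_1 = shape_index_1(max_width, max_height),
    shape_index_2 = shape_index_2(width_mid_height, height_mid_width),
    curved_shape_index = curved_shape_index(width_mid_height, curved_height)
  )
  if (!is.null(img)) {
    px <- pixels_rgb(img, idx)
    lab3 <- rgb_to_lab(px)
    hue <- (atan2(lab3[, "b"], lab3[, "a"]) * 180 / pi) %% 360
    hcl <- hist_counts(hue, bin_spec(37, 0, 360))
    out <- c(out, list(
      avg_r = mean(px[, 1]), avg_g = mean(px[, 2]), avg_b = mean(px[, 3]),
      avg_luminosity = mean(0.299 * px[, 1] + 0.587 * px[, 2] + 0.114 * px[, 3]),
      avg_L = mean(lab3[, "L"]), avg_a = mean(lab3[, "a"]), avg_b_lab = mean(lab3[, "b"]),
      avg_hue = (atan2(mean(lab3[, "b"]), mean(lab3[, "a"])) * 180 / pi) %% 360,
      avg_chroma = mean(sqrt(lab3[, "a"]^2 + lab3[, "b"]^2)),
      hcl_histogram = hcl / sum(hcl)
    ))
  }
  structure(out, class = "fruit_measurements")
}

#' Fruit shape index 1: maximum height over maximum width
#'
#' Reported at two decimals, matching the print precision of published
#' measurement tables (a perfectly round fruit gives 1.00).
#'
#' @param max_width,max_height bounding-box extents in px.
#' @return numeric, rounded to 2 decimals.
#' @export
shape_index_1 <- function(max_width, max_height) {
  if (any(max_width <= 0)) abort("max_width must be positive")
  round(max_height / max_width, 2)
}

#' Fruit shape index 2: height at mid-width over width at mid-height
#'
#' @param width_mid_height,height_mid_width mid-slice extents in px.
#' @return numeric, rounded to 2 decimals.
#' @export
shape_index_2 <- function(width_mid_height, height_mid_width) {
  if (any(width_mid_height <= 0)) abort("width_mid_height must be positive")
  round(height_mid_width / width_mid_height, 2)
}

#' Curved shape index: curved height over width at mid-height
#'
#' @param width_mid_height mid-slice width in px.
#' @param curved_height medial-curve arc length in px.
#' @return numeric, rounded to 2 decimals.
#' @export
curved_shape_index <- function(width_mid_height, curved_height) {
  if (any(width_mid_height <= 0)) abort("width_mid_height must be positive")
  round(curved_height / width_mid_height, 2)
}

#' Block layout of the 56-feature fruit vector
#'
#' @return tibble with `start`, `end` (1-based inclusive), `description`.
#' @export
fruit_feature_layout <- function() {
  tibble(
    start = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 11L, 14L, 15L, 18L, 19L, 20L),
    end = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 10L, 13L, 14L, 17L, 18L, 19L, 56L),
    description = c("Fruit Perimeter", "Fruit Area",
                    "Width at Middle of Height", "Maximum Width",
                    "Height at Middle of Width", "Maximum Height",
                    "Curved Height", "Shape Index", "Average RGB",
                    "Average Luminosity", "Average L*a*b*", "Average Hue",
                    "Average Chroma", "HCL histogram")
  )
}

#' Extract the 56-feature fruit vector
#'
#' @param image a `fruit_image` or RGB array with `background_color`.
#' @param background_color RGB triple for bare arrays.
#' @param fruit_id id recorded in the output row.
#' @return one-row tibble: `fruit_id`, `G01`..`G56`; attribute `layout`.
#' @export
extract_fruit_features <- function(image, background_color = NULL, fruit_id = NULL) {
  fruit_id <- fruit_id %||%
    (if (inherits(image, "pheno_image")) image$id else "fruit")
  m <- measure_fruit(image, background_color = background_color)
  if (is.null(m$avg_r)) abort("extract_fruit_features needs a color image, not a bare mask")
  values <- c(m$perimeter, m$area, m$width_mid_height, m$max_width,
              m$height_mid_width, m$max_height, m$curved_height,
              m$shape_index_1, m$shape_index_2, m$curved_shape_index,
              m$avg_r, m$avg_g, m$avg_b, m$avg_luminosity,
              m$avg_L, m$avg_a, m$avg_b_lab, m$avg_hue, m$avg_chroma,
              m$hcl_histogram)
  stopifnot(length(values) == 56L)
  out <- as_tibble(as.list(setNames(values, sprintf("G%02d", 1:56))))
  out <- mutate(out, fruit_id = fruit_id, .before = 1)
  attr(out, "layout") <- fruit_feature_layout()
  out
}

#' Extract fruit features for a list of images
#'
#' @param images list of `fruit_image` objects.
#' @return tibble with one row per fruit.
#' @export
fruit_feature_matrix <- function(images) {
  bind_rows(lapply(images, extract_fruit_features))
}

#' @export
print.fruit_measurements <- function(x, ...) {
  cat(sprintf(paste0("<fruit_measurements: area %d px^2, %d x %d px bbox, ",
                     "shape indices %.2f / %.2f / %.2f>\n"),
              x$area, x$max_width, x$max_height,
              x$shape_index_1, x$shape_index_2, x$curved_shape_index))
  invisible(x)
}
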