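# Pre-processing stages of the leaf pipeline: isolate the leaf from the
# solid background, classify leaf pixels as necrotic / chlorotic / normal
# tissue by HSV gates, and extract per-lesion geometry from 8-connected
# components.

#' HSV tissue-classification gates
#'
#' Declared decision rule for lesion tissue: a leaf pixel is *necrotic*
#' (brown, dead tissue) when its hue falls in `necrotic_hue` degrees with
#' saturation at least `s_min` and value at most `necrotic_v_max`; otherwise
#' *chlorotic* (chlorophyll-deficient yellow) when hue falls in
#' `chlorotic_hue`; otherwise *normal*. Hue is in degrees in `[0, 360)`.
#'
#' @param necrotic_hue,chlorotic_hue `c(lo, hi)` hue gates in degrees.
#' @param s_min minimum saturation for either lesion class.
#' @param necrotic_v_max maximum value (brightness) for necrotic tissue.
#' @return named list of gates.
#' @export
tissue_gates <- function(necrotic_hue = c(0, 45), chlorotic_hue = c(45, 90),
                         s_min = 0.15, necrotic_v_max = 0.80) {
  list(necrotic_hue = necrotic_hue, chlorotic_hue = chlorotic_hue,
       s_min = s_min, necrotic_v_max = necrotic_v_max)
}

as_image_array <- function(image) {
  if (inherits(image, "pheno_image")) image$image else image
}

#' Segment the leaf from a solid background
#'
#' Pixels whose RGB distance to `background_color` exceeds `tol` are
#' foreground; the largest 8-connected component is kept and its interior
#' holes are filled.
#'
#' @param image a `leaf_image` or an H x W x 3 array in `[0,1]`.
#' @param background_color RGB triple; defaults to the image protocol.
#' @param tol Euclidean RGB distance threshold.
#' @return logical leaf mask (class `leaf_mask`) with attribute
#'   `pixel_count`.
#' @export
segment_leaf <- function(image, background_color = NULL, tol = 0.15) {
  bg <- background_color %||%
    (if (inherits(image, "pheno_image")) image$protocol$background_color else NULL)
  if (is.null(bg)) abort("background_color is required when image carries no protocol")
  img <- as_image_array(image)
  d2 <- (img[, , 1] - bg[1])^2 + (img[, , 2] - bg[2])^2 + (img[, , 3] - bg[3])^2
  fg <- d2 > tol^2
  if (!any(fg)) abort("empty foreground: image contains only background pixels")
  lab <- label_components(fg)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  mask <- fill_holes(lab == keep)
  structure(mask, class = c("leaf_mask", "matrix", "array"),
            pixel_count = sum(mask))
}

#' Classify leaf pixels into necrotic, chlorotic and normal tissue
#'
#' @param image a `leaf_image` or RGB array.
#' @param leaf_mask logical mask from [segment_leaf()].
#' @param gates HSV gates from [tissue_gates()].
#' @return integer matrix (class `tissue_labels`): 0 background, 1 normal,
#'   2 chlorotic, 3 necrotic.
#' @export
classify_tissue <- function(image, leaf_mask, gates = tissue_gates()) {
  img <- as_image_array(image)
  if (!any(leaf_mask)) abort("leaf_mask is empty")
  idx <- which(leaf_mask)
  hsv <- rgb_to_hsv_deg(pixels_rgb(img, idx))
  h <- hsv[, "h"]; s <- hsv[, "s"]; v <- hsv[, "v"]
  lab <- rep(1L, length(idx))
  nec <- h >= gates$necrotic_hue[1] & h < gates$necrotic_hue[2] &
    s >= gates$s_min & v <= gates$necrotic_v_max
  chl <- !nec & h >= gates$chlorotic_hue[1] & h < gates$chlorotic_hue[2] &
    s >= gates$s_min
  lab[chl] <- 2L
  lab[nec] <- 3L
  out <- matrix(0L, nrow(leaf_mask), ncol(leaf_mask))
  out[idx] <- lab
  structure(out, class = c("tissue_labels", "matrix", "array"),
            legend = c(background = 0L, normal = 1L, chlorotic = 2L, necrotic = 3L))
}

#' Extract lesions as 8-connected components per tissue class
#'
#' Touching regions of the same tissue class merge into a single lesion
#' (8-connectivity, so diagonal contact merges too). Components smaller than
#' `min_lesion_area` are discarded as speckle.
#'
#' @param tissue_labels matrix from [classify_tissue()].
#' @param min_lesion_area minimum component area in px^2.
#' @param image_id optional id recorded on the result.
#' @return a `lesion_set`: tibble with `lesion_id`, `tissue_class`, `area`,
#'   `centroid_x`, `centroid_y` (0-based pixel coordinates), `max_diameter`
#'   (Feret), `perimeter`, `roundness`; per-lesion pixel index sets are kept
#'   in attribute `pixels`.
#' @export
extract_lesions <- function(tissue_labels, min_lesion_area = 5, image_id = NA_character_) {
  nr <- nrow(tissue_labels); nc <- ncol(tissue_labels)
  rows <- list(); pix <- list()
  for (cls in c(necrotic = 3L, chlorotic = 2L)) {
    lab <- label_components(tissue_labels == cls)
    k <- max(lab)
    if (k == 0L) next
    idx_by <- split(which(lab > 0L), lab[lab > 0L])
    for (comp in idx_by) {
      if (length(comp) < min_lesion_area) next
      x <- (comp - 1L) %/% nr
      y <- (comp - 1L) %% nr
      d <- feret_diameter(x, y)
      ar <- length(comp)
      rows[[length(rows) + 1L]] <- tibble(
        tissue_class = names(which(c(necrotic = 3L, chlorotic = 2L) == cls)),
        area = ar,
        centroid_x = mean(x),
        centroid_y = mean(y),
        max_diameter = d,
        perimeter = edge_perimeter(comp, nr, nc),
        roundness = roundness(ar, d)
      )
      pix[[length(pix) + 1L]] <- comp
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(tissue_class = character(), area = integer(),
           centroid_x = numeric(), centroid_y = numeric(),
           max_diameter = numeric(), perimeter = numeric(), roundness = numeric())
  out <- mutate(out, lesion_id = row_number(), .before = 1)
  structure(out, class = c("lesion_set", class(out)),
            pixels = pix, dims = c(nr, nc), image_id = image_id)
}

#' Write a tissue label raster as an indexed grayscale PNG
#'
#' Mirrors the standard visualization: black background, dark-gray normal
#' tissue, light-gray chlorosis, white necrosis.
#'
#' @param tissue_labels matrix from [classify_tissue()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_tissue_png <- function(tissue_labels, path) {
  shade <- c(`0` = 0, `1` = 0.33, `2` = 0.66, `3` = 1)
  img <- matrix(shade[as.character(tissue_labels)], nrow(tissue_labels), ncol(tissue_labels))
  png::writePNG(img, path)
  invisible(path)
}
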