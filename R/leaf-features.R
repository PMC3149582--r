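# Feature extraction for leaf phenotypes: per-channel color histograms,
# lesion size / roundness / nearest-neighbor-distance histograms, spatial
# partition counts, and the full 452-feature vector with its fixed block
# layout.

#' Equi-width bin specification
#'
#' @param n_bins number of bins.
#' @param lo,hi range `[lo, hi)`; values equal to `hi` fall in the final bin
#'   (the final bin is closed).
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(n_bins, lo = 0, hi = 1) {
  stopifnot(n_bins >= 1, hi > lo)
  structure(list(n_bins = as.integer(n_bins), lo = lo, hi = hi), class = "bin_spec")
}

# Bin index (1-based) of values under a bin_spec; values outside [lo, hi]
# are clamped into the end bins.
bin_index <- function(x, bins) {
  i <- floor(bins$n_bins * (x - bins$lo) / (bins$hi - bins$lo)) + 1
  pmin(pmax(i, 1L), bins$n_bins)
}

# Fast internal histogram over a bin_spec -> numeric vector of counts.
hist_counts <- function(x, bins) {
  tabulate(bin_index(x, bins), nbins = bins$n_bins)
}

default_channel_bins <- function(channel) {
  switch(channel,
         H = bin_spec(15, 0, 360),
         R = , G = , B = , S = , V = bin_spec(16, 0, 1))
}

#' Per-channel color histogram of a pixel set
#'
#' @param pixels an n x 3 RGB matrix in `[0,1]` (rows are pixels), or a
#'   `pheno_image` together with `mask`.
#' @param channel one of `"R","G","B","H","S","V"`; hue is in degrees in
#'   `[0, 360)`.
#' @param bins a [bin_spec()]; defaults to the channel's standard binning
#'   (16 equi-width bins for R,G,B,S,V; 15 for H).
#' @param normalize divide counts by the pixel count so entries sum to 1.
#' @param mask optional logical mask selecting pixels when `pixels` is an
#'   image.
#' @return tibble with `bin` (0-based, matching the H0.../R0... naming
#'   convention), `lo`, `hi`, `value`.
#' @export
channel_histogram <- function(pixels, channel = c("R", "G", "B", "H", "S", "V"),
                              bins = NULL, normalize = TRUE, mask = NULL) {
  channel <- match.arg(channel)
  if (inherits(pixels, "pheno_image") || (is.array(pixels) && length(dim(pixels)) == 3L)) {
    img <- as_image_array(pixels)
    idx <- if (is.null(mask)) seq_len(dim(img)[1] * dim(img)[2]) else which(mask)
    pixels <- pixels_rgb(img, idx)
  }
  bins <- bins %||% default_channel_bins(channel)
  if (nrow(pixels) == 0L) {
    if (normalize) abort("cannot normalize a histogram of an empty pixel set")
    vals <- numeric(bins$n_bins)
  } else {
    x <- if (channel %in% c("R", "G", "B")) {
      pixels[, match(channel, c("R", "G", "B"))]
    } else {
      rgb_to_hsv_deg(pixels)[, match(channel, c("H", "S", "V"))]
    }
    vals <- hist_counts(x, bins)
    if (normalize) vals <- vals / sum(vals)
  }
  w <- (bins$hi - bins$lo) / bins$n_bins
  tibble(bin = 0:(bins$n_bins - 1),
         lo = bins$lo + w * (0:(bins$n_bins - 1)),
         hi = bins$lo + w * (1:bins$n_bins),
         value = vals)
}

#' Lesion roundness
#'
#' The ratio of a lesion's area to the area of the circle whose diameter is
#' the lesion's maximum (Feret) diameter: 1 for a disk, smaller for
#' elongated or ragged shapes. Clipped to at most 1 (rasterization can
#' overshoot slightly); a single-pixel lesion returns 1 by convention.
#'
#' @param area lesion area in px^2 (or a `lesion_set`).
#' @param max_diameter maximum pairwise pixel distance in px.
#' @return numeric in `(0, 1]`.
#' @export
roundness <- function(area, max_diameter = NULL) {
  if (inherits(area, "lesion_set")) {
    max_diameter <- area$max_diameter
    area <- area$area
  }
  out <- ifelse(max_diameter <= 1, 1, area / (pi * (max_diameter / 2)^2))
  pmin(out, 1)
}

lesion_hist <- function(lesions, tissue_class, bins, values) {
  sel <- lesions$tissue_class == tissue_class
  vals <- hist_counts(values[sel], bins)
  if (!any(sel)) vals <- numeric(bins$n_bins)
  w <- (bins$hi - bins$lo) / bins$n_bins
  tibble(bin = 0:(bins$n_bins - 1),
         lo = bins$lo + w * (0:(bins$n_bins - 1)),
         hi = bins$lo + w * (1:bins$n_bins),
         count = vals)
}

#' Histogram of lesion areas (unnormalized counts)
#'
#' @param lesions a `lesion_set` from [extract_lesions()].
#' @param tissue_class `"necrotic"` or `"chlorotic"`.
#' @param bins a [bin_spec()] over area in px^2.
#' @return tibble with `bin` (0-based), `lo`, `hi`, `count`.
#' @export
size_histogram <- function(lesions, tissue_class = c("necrotic", "chlorotic"),
                           bins = bin_spec(12, 0, 1000)) {
  tissue_class <- match.arg(tissue_class)
  lesion_hist(lesions, tissue_class, bins, lesions$area)
}

#' Histogram of lesion roundness (unnormalized counts)
#'
#' @inheritParams size_histogram
#' @param bins a [bin_spec()] over roundness in `[0,1]`.
#' @export
roundness_histogram <- function(lesions, tissue_class = c("necrotic", "chlorotic"),
                                bins = bin_spec(12, 0, 1)) {
  tissue_class <- match.arg(tissue_class)
  lesion_hist(lesions, tissue_class, bins, roundness(lesions$area, lesions$max_diameter))
}

#' Histogram of nearest-neighbor lesion distances
#'
#' One centroid-to-centroid Euclidean distance per lesion (its nearest
#' neighbor of the same tissue class), so the total count equals the lesion
#' count: leaves with more lesions carry more mass. With fewer than two
#' lesions there is no neighbor and the histogram is all zero.
#'
#' @inheritParams size_histogram
#' @param bins a [bin_spec()] over distance in px.
#' @export
nn_distance_histogram <- function(lesions, tissue_class = c("necrotic", "chlorotic"),
                                  bins = bin_spec(12, 0, 360)) {
  tissue_class <- match.arg(tissue_class)
  sel <- lesions$tissue_class == tissue_class
  w <- (bins$hi - bins$lo) / bins$n_bins
  out <- tibble(bin = 0:(bins$n_bins - 1),
                lo = bins$lo + w * (0:(bins$n_bins - 1)),
                hi = bins$lo + w * (1:bins$n_bins),
                count = numeric(bins$n_bins))
  if (sum(sel) < 2L) return(out)
  d <- as.matrix(stats::dist(cbind(lesions$centroid_x[sel], lesions$centroid_y[sel])))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  out$count <- as.numeric(hist_counts(nn, bins))
  out
}

#' Lesion counts per equal-width partition along the leaf's long axis
#'
#' The leaf bounding box is cut into `k` equal-width vertical slices from
#' base to tip; lesions are counted by centroid. A centroid exactly on a
#' partition boundary goes to the lower-index partition.
#'
#' @param lesions a `lesion_set`.
#' @param leaf_mask logical mask from [segment_leaf()].
#' @param k number of partitions (>= 2).
#' @return tibble with `partition` (0-based, base first) and `count`;
#'   counts sum to the lesion count.
#' @export
spatial_partition_histogram <- function(lesions, leaf_mask, k = 4) {
  stopifnot(k >= 2)
  cols_occ <- which(colSums(leaf_mask) > 0)
  xmin <- min(cols_occ) - 1; xmax <- max(cols_occ) - 1  # 0-based
  w <- (xmax - xmin + 1) / k
  pos <- (lesions$centroid_x - xmin) / w
  idx <- ifelse(pos > 0 & pos == floor(pos), pos - 1, floor(pos))
  idx <- pmin(pmax(idx, 0), k - 1)
  tibble(partition = 0:(k - 1),
         count = tabulate(idx + 1, nbins = k))
}

# -- 452-feature layout -------------------------------------------------------

#' Block layout of the 452-feature leaf vector
#'
#' Sixteen blocks: RGB histograms (16+16+16 bins) over the entire leaf,
#' necrotic, chlorotic and non-lesion pixels; HSV histograms (15+16+16) over
#' the entire leaf, necrotic, non-lesion and chlorotic pixels (in that
#' order); then 12-bin size, roundness and nearest-neighbor-distance
#' histograms for necrotic and chlorotic lesions. Feature ids are
#' zero-padded `F001`..`F452`.
#'
#' @return tibble with `start`, `end` (1-based inclusive), `feature_class`,
#'   `region`, `n`.
#' @export
leaf_feature_layout <- function() {
  tibble(
    start = c(1L, 49L, 97L, 145L, 193L, 240L, 287L, 334L,
              381L, 393L, 405L, 417L, 429L, 441L),
    end = c(48L, 96L, 144L, 192L, 239L, 286L, 333L, 380L,
            392L, 404L, 416L, 428L, 440L, 452L),
    feature_class = c(rep("RGB histogram", 4), rep("HSV histogram", 4),
                      "Size histogram", "Size histogram",
                      "Roundness histogram", "Roundness histogram",
                      "NN distance histogram", "NN distance histogram"),
    region = c("entire", "necrotic", "chlorotic", "non_lesion",
               "entire", "necrotic", "non_lesion", "chlorotic",
               "necrotic", "chlorotic", "necrotic", "chlorotic",
               "necrotic", "chlorotic"),
    n = c(rep(48L, 4), rep(47L, 4), rep(12L, 6))
  )
}

#' Resolve a feature id to its layout block, channel and bin
#'
#' @param feature feature id like `"F006"` (or integer index).
#' @return one-row tibble: `feature`, `index`, `feature_class`, `region`,
#'   `channel`, `bin` (0-based within channel).
#' @export
describe_feature <- function(feature) {
  idx <- if (is.character(feature)) as.integer(sub("^F", "", feature)) else as.integer(feature)
  if (is.na(idx) || idx < 1L || idx > 452L) abort("feature index out of 1..452")
  lay <- leaf_feature_layout()
  b <- lay[lay$start <= idx & lay$end >= idx, ]
  off <- idx - b$start  # 0-based offset into block
  if (b$feature_class == "RGB histogram") {
    channel <- c("R", "G", "B")[off %/% 16 + 1]
    bin <- off %% 16
  } else if (b$feature_class == "HSV histogram") {
    if (off < 15) { channel <- "H"; bin <- off }
    else { channel <- c("S", "V")[(off - 15) %/% 16 + 1]; bin <- (off - 15) %% 16 }
  } else {
    channel <- NA_character_
    bin <- off
  }
  tibble(feature = sprintf("F%03d", idx), index = idx,
         feature_class = b$feature_class, region = b$region,
         channel = channel, bin = bin)
}

#' Leaf pipeline configuration
#'
#' Tunable parameters of [extract_leaf_features()]: segmentation tolerance,
#' tissue gates, minimum lesion area, and the histogram bin specifications.
#' Size bins span `[0, leaf_area * size_max_frac]`; nearest-neighbor bins
#' span `[0, leaf long-axis length]` (both data-independent given the leaf).
#'
#' @param tol RGB background distance threshold.
#' @param gates HSV gates from [tissue_gates()].
#' @param min_lesion_area minimum lesion component area, px^2.
#' @param n_size_bins,n_roundness_bins,n_nn_bins count-histogram bin counts.
#' @param size_max_frac area-range upper bound as a fraction of leaf area.
#' @param count_scale fixed reference count dividing the count histograms in
#'   post-processing (range normalization). A fixed scale keeps lesion
#'   frequency comparable across images — dividing by the per-image sum
#'   would erase the count information that coverage semantics depend on.
#' @return named list.
#' @export
leaf_pipeline_config <- function(tol = 0.15, gates = tissue_gates(),
                                 min_lesion_area = 5,
                                 n_size_bins = 12L, n_roundness_bins = 12L,
                                 n_nn_bins = 12L, size_max_frac = 0.1,
                                 count_scale = 50) {
  list(tol = tol, gates = gates, min_lesion_area = min_lesion_area,
       n_size_bins = n_size_bins, n_roundness_bins = n_roundness_bins,
       n_nn_bins = n_nn_bins, size_max_frac = size_max_frac,
       count_scale = count_scale)
}

# Normalized per-channel color histogram block over a pixel index set;
# zero block for an empty set.
color_block <- function(img, idx, space) {
  if (length(idx) == 0L) {
    return(numeric(if (space == "RGB") 48 else 47))
  }
  px <- pixels_rgb(img, idx)
  if (space == "RGB") {
    unlist(lapply(c("R", "G", "B"), function(ch) {
      v <- hist_counts(px[, match(ch, c("R", "G", "B"))], bin_spec(16, 0, 1))
      v / sum(v)
    }), use.names = FALSE)
  } else {
    hsv <- rgb_to_hsv_deg(px)
    h <- hist_counts(hsv[, "h"], bin_spec(15, 0, 360))
    s <- hist_counts(hsv[, "s"], bin_spec(16, 0, 1))
    v <- hist_counts(hsv[, "v"], bin_spec(16, 0, 1))
    c(h / sum(h), s / sum(s), v / sum(v))
  }
}

#' Extract the 452-feature leaf vector
#'
#' Runs the full pipeline on one image: background segmentation, tissue
#' classification, lesion extraction, then the fixed block layout of
#' [leaf_feature_layout()]. Color histograms are per-channel normalized;
#' size / roundness / nearest-neighbor count histograms are range-normalized
#' in post-processing (divided by the fixed reference count
#' `config$count_scale`, preserving lesion frequency across images), with
#' the raw counts retained in the `counts` attribute.
#'
#' @param image a `leaf_image` or RGB array (then `background_color` is
#'   required).
#' @param config a [leaf_pipeline_config()].
#' @param background_color RGB triple when `image` is a bare array.
#' @param image_id id recorded in the output row.
#' @return one-row tibble: `image_id`, `F001`..`F452`; attributes `layout`
#'   (the block layout) and `counts` (raw count histograms).
#' @export
extract_leaf_features <- function(image, config = leaf_pipeline_config(),
                                  background_color = NULL, image_id = NULL) {
  img <- as_image_array(image)
  image_id <- image_id %||%
    (if (inherits(image, "pheno_image")) image$id else "image")
  mask <- segment_leaf(image, background_color = background_color, tol = config$tol)
  tl <- classify_tissue(img, mask, config$gates)
  lesions <- extract_lesions(tl, config$min_lesion_area, image_id = image_id)

  idx_entire <- which(mask)
  idx_nec <- which(tl == 3L)
  idx_chl <- which(tl == 2L)
  idx_norm <- which(tl == 1L)

  leaf_area <- length(idx_entire)
  cols_occ <- which(colSums(mask) > 0)
  long_axis <- max(cols_occ) - min(cols_occ) + 1
  size_bins <- bin_spec(config$n_size_bins, 0, leaf_area * config$size_max_frac)
  round_bins <- bin_spec(config$n_roundness_bins, 0, 1)
  nn_bins <- bin_spec(config$n_nn_bins, 0, long_axis)

  norm_block <- function(counts) counts / config$count_scale
  counts <- list(
    size_necrotic = size_histogram(lesions, "necrotic", size_bins)$count,
    size_chlorotic = size_histogram(lesions, "chlorotic", size_bins)$count,
    roundness_necrotic = roundness_histogram(lesions, "necrotic", round_bins)$count,
    roundness_chlorotic = roundness_histogram(lesions, "chlorotic", round_bins)$count,
    nn_necrotic = nn_distance_histogram(lesions, "necrotic", nn_bins)$count,
    nn_chlorotic = nn_distance_histogram(lesions, "chlorotic", nn_bins)$count
  )
  values <- c(
    color_block(img, idx_entire, "RGB"),
    color_block(img, idx_nec, "RGB"),
    color_block(img, idx_chl, "RGB"),
    color_block(img, idx_norm, "RGB"),
    color_block(img, idx_entire, "HSV"),
    color_block(img, idx_nec, "HSV"),
    color_block(img, idx_norm, "HSV"),
    color_block(img, idx_chl, "HSV"),
    norm_block(counts$size_necrotic),
    norm_block(counts$size_chlorotic),
    norm_block(counts$roundness_necrotic),
    norm_block(counts$roundness_chlorotic),
    norm_block(counts$nn_necrotic),
    norm_block(counts$nn_chlorotic)
  )
  stopifnot(length(values) == 452L)
  out <- as_tibble(as.list(setNames(values, sprintf("F%03d", 1:452))))
  out <- mutate(out, image_id = image_id, .before = 1)
  attr(out, "layout") <- leaf_feature_layout()
  attr(out, "counts") <- counts
  out
}

#' Extract leaf features for a list of images
#'
#' @param images list of `leaf_image` objects.
#' @param config a [leaf_pipeline_config()].
#' @return tibble with one row per image (`image_id`, `F001`..`F452`).
#' @export
leaf_feature_matrix <- function(images, config = leaf_pipeline_config()) {
  bind_rows(lapply(images, extract_leaf_features, config = config))
}

#' Write a feature matrix as CSV with a layout manifest
#'
#' @param features tibble from [leaf_feature_matrix()] or
#'   [fruit_feature_matrix()].
#' @param path output CSV path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @param layout block layout; defaults to the leaf or fruit layout based on
#'   the feature count.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, layout = NULL) {
  layout <- layout %||%
    (if (ncol(features) - 1L == 452L) leaf_feature_layout() else fruit_feature_layout())
  utils::write.csv(features, path, row.names = FALSE)
  jsonlite::write_json(layout, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
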