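# Leaf feature extraction: histograms, roundness, layout contracts.

test_that("channel histograms bin and normalize correctly", {
  # uniform single-hue patch: all mass in one bin
  patch <- matrix(rep(c(1, 0, 0), each = 50), ncol = 3)  # pure red, hue 0
  h <- channel_histogram(patch, "H", bin_spec(10, 0, 360))
  expect_equal(h$value[1], 1)
  expect_equal(sum(h$value), 1)

  # half hue 30 deg, half hue 200 deg -> 0.5 in bins 0 and 5 (hand binning)
  col30 <- grDevices::col2rgb(grDevices::hsv(30 / 360, 1, 1)) / 255
  col200 <- grDevices::col2rgb(grDevices::hsv(200 / 360, 1, 1)) / 255
  px <- rbind(matrix(rep(col30, 20), ncol = 3, byrow = TRUE),
              matrix(rep(col200, 20), ncol = 3, byrow = TRUE))
  h2 <- channel_histogram(px, "H", bin_spec(10, 0, 360))
  expect_equal(h2$value[h2$bin == 0], 0.5)
  expect_equal(h2$value[h2$bin == 5], 0.5)

  # empty pixel set: error when normalizing, zero vector otherwise
  empty <- matrix(numeric(0), ncol = 3)
  expect_error(channel_histogram(empty, "R"), "empty pixel set")
  h0 <- channel_histogram(empty, "R", normalize = FALSE)
  expect_equal(sum(h0$value), 0)

  # any normalized output sums to 1
  set.seed(1)
  rnd <- matrix(runif(300), ncol = 3)
  for (ch in c("R", "G", "B", "H", "S", "V")) {
    expect_equal(sum(channel_histogram(rnd, ch)$value), 1, tolerance = 1e-9)
  }
})

test_that("roundness matches closed-form shape oracles", {
  disk <- ellipse_mask(40, 40)
  tl <- labels_from_masks(nrow(disk), ncol(disk), necrotic = list(disk))
  expect_equal(extract_lesions(tl)$roundness, 1.00, tolerance = 0.03)

  ell <- ellipse_mask(40, 20)
  tl2 <- labels_from_masks(nrow(ell), ncol(ell), necrotic = list(ell))
  expect_equal(extract_lesions(tl2)$roundness, 0.50, tolerance = 0.03)

  sq <- matrix(FALSE, 70, 70); sq[5:64, 5:64] <- TRUE  # square side 60
  tl3 <- labels_from_masks(70, 70, necrotic = list(sq))
  expect_equal(extract_lesions(tl3)$roundness, 2 / pi, tolerance = 0.05)

  # single-pixel convention
  expect_equal(roundness(1, 1), 1)
})

test_that("count histograms total the lesion count and split by class", {
  les <- structure(
    tibble::tibble(lesion_id = 1:7, tissue_class = rep("necrotic", 7),
                   area = c(rep(290, 7)), centroid_x = seq(10, 70, 10),
                   centroid_y = rep(5, 7), max_diameter = rep(20, 7),
                   perimeter = rep(60, 7), roundness = rep(0.9, 7)),
    class = c("lesion_set", class(tibble::tibble())))
  h <- size_histogram(les, "necrotic", bin_spec(12, 0, 1000))
  expect_equal(h$count[h$bin == 3], 7)  # 290 in [250, 333)
  expect_equal(sum(h$count), 7)
  expect_equal(sum(size_histogram(les, "chlorotic", bin_spec(12, 0, 1000))$count), 0)

  # three collinear lesions spaced 10 -> all NN distances 10
  les3 <- les[1:3, ]
  nn <- nn_distance_histogram(les3, "necrotic", bin_spec(12, 0, 120))
  expect_equal(nn$count[nn$bin == 1], 3)
  expect_equal(sum(nn$count), 3)

  # single lesion: no neighbor, zero vector
  expect_equal(sum(nn_distance_histogram(les[1, ], "necrotic")$count), 0)
})

test_that("dense leaves shift NN-distance mass to lower bins than sparse", {
  dense <- generate_leaf(leaf_spec(30, lesion_size_class = "small",
                                   spatial_pattern = "clustered", seed = 8))
  sparse <- generate_leaf(leaf_spec(30, lesion_size_class = "small",
                                    spatial_pattern = "uniform", seed = 8))
  mean_bin <- function(im) {
    les <- extract_lesions(classify_tissue(im, segment_leaf(im)))
    nn <- nn_distance_histogram(les, "necrotic", bin_spec(12, 0, 360))
    sum(nn$bin * nn$count) / sum(nn$count)
  }
  expect_lt(mean_bin(dense), mean_bin(sparse))
})

test_that("spatial partitions count lesions base to tip with the tie rule", {
  leaf <- matrix(TRUE, 30, 90)
  les <- tibble::tibble(centroid_x = c(5, 10, 20, 29), centroid_y = rep(5, 4))
  h <- spatial_partition_histogram(les, leaf, k = 3)
  expect_equal(h$count, c(4, 0, 0))
  expect_equal(sum(h$count), 4)

  # centroid exactly on a boundary goes to the lower-index partition
  les2 <- tibble::tibble(centroid_x = 30, centroid_y = 5)  # boundary at 90/3
  h2 <- spatial_partition_histogram(les2, leaf, k = 3)
  expect_equal(h2$count, c(1, 0, 0))

  # uniform pattern: each of k=4 partitions within 3 sigma of n/4
  im <- generate_leaf(leaf_spec(28, lesion_size_class = "small", seed = 44))
  gt <- im$truth$lesions
  h3 <- spatial_partition_histogram(gt, im$truth$leaf_mask, k = 4)
  n <- nrow(gt)
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(h3$count - n / 4) <= 3 * sigma))
})

test_that("the 452-feature vector follows the fixed block layout", {
  lay <- leaf_feature_layout()
  expect_equal(sum(lay$n), 452)
  expect_equal(lay$n, lay$end - lay$start + 1L)
  expect_equal(sum(lay$n), 48L * 4L + 47L * 4L + 12L * 6L)
  # the HSV non-lesion block precedes the HSV chlorotic block
  hsv <- lay[lay$feature_class == "HSV histogram", ]
  expect_equal(hsv$region, c("entire", "necrotic", "non_lesion", "chlorotic"))
  expect_equal(hsv$start, c(193L, 240L, 287L, 334L))

  im <- generate_leaf(leaf_spec(9, seed = 3))
  fv <- extract_leaf_features(im)
  expect_equal(ncol(fv) - 1L, 452L)
  expect_named(fv, c("image_id", sprintf("F%03d", 1:452)))

  # normalized color blocks: each channel histogram sums to 1
  expect_equal(sum(fv[, sprintf("F%03d", 1:16)]), 1, tolerance = 1e-9)
  expect_equal(sum(fv[, sprintf("F%03d", 193:207)]), 1, tolerance = 1e-9)
  # count blocks are range-normalized by the fixed reference count, so the
  # block total still reflects the lesion count; raw counts retained
  counts <- attr(fv, "counts")
  n_rec <- nrow(extract_lesions(classify_tissue(im, segment_leaf(im))))
  expect_equal(sum(counts$size_necrotic), n_rec)
  expect_equal(sum(fv[, sprintf("F%03d", 381:392)]), n_rec / 50, tolerance = 1e-9)
})

test_that("a lesion-free leaf zeroes all lesion blocks", {
  im <- generate_leaf(leaf_spec(0, seed = 19))
  fv <- extract_leaf_features(im)
  lay <- leaf_feature_layout()
  lesion_blocks <- lay[lay$region %in% c("necrotic", "chlorotic"), ]
  for (i in seq_len(nrow(lesion_blocks))) {
    cols <- sprintf("F%03d", lesion_blocks$start[i]:lesion_blocks$end[i])
    expect_equal(sum(abs(fv[, cols])), 0)
  }
  expect_equal(sum(fv[, sprintf("F%03d", 1:16)]), 1, tolerance = 1e-9)
})

test_that("feature names resolve to their layout block", {
  d <- describe_feature("F006")
  expect_equal(d$feature_class, "RGB histogram")
  expect_equal(d$region, "entire")
  expect_equal(d$channel, "R")
  expect_equal(d$bin, 5)  # F006 is the 6th R bin (0-based bin 5)

  d2 <- describe_feature("F399")
  expect_equal(d2$feature_class, "Size histogram")
  expect_equal(d2$region, "chlorotic")

  d3 <- describe_feature("F240")
  expect_equal(d3$channel, "H")
  expect_equal(d3$region, "necrotic")
  expect_error(describe_feature("F500"), "out of")
})

test_that("hue-histogram centroid orders green < yellow < brown tissue", {
  centroid_bin <- function(tissue) {
    im <- generate_leaf(leaf_spec(0, leaf_tissue_class = tissue, seed = 6))
    mask <- segment_leaf(im)
    h <- channel_histogram(im$image, "H", bin_spec(10, 0, 360), mask = mask)
    sum(h$bin * h$value)
  }
  g <- centroid_bin("green"); y <- centroid_bin("yellow"); b <- centroid_bin("brown")
  # on the hue circle green sits high (120 deg), yellow mid, brown low;
  # the separation property is strict ordering of the histogram centroids
  expect_true(b < y & y < g)
})

test_that("roundness histograms separate disk-like from irregular leaves", {
  hist_for <- function(shape) {
    im <- generate_leaf(leaf_spec(8, lesion_shape_class = shape, seed = 13))
    les <- extract_lesions(classify_tissue(im, segment_leaf(im)))
    roundness_histogram(les, "necrotic", bin_spec(12, 0, 1))
  }
  he <- hist_for("elliptical"); hi <- hist_for("irregular")
  low_bins <- 0:5
  expect_gt(sum(hi$count[hi$bin %in% low_bins]), sum(he$count[he$bin %in% low_bins]))
  mean_bin <- function(h) sum(h$bin * h$count) / sum(h$count)
  expect_gt(mean_bin(he), mean_bin(hi))
})
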