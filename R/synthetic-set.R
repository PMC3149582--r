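# Balanced training sets and plain-text export of synthetic phenotypes.

#' Generate a balanced, seeded training set
#'
#' Each class template is a [leaf_spec()] or [fruit_spec()] whose `seed` is
#' replaced by per-image seeds derived deterministically from `seed`, so the
#' whole collection is a pure function of the master seed.
#'
#' @param n_per_class images per template.
#' @param classes a (preferably named) list of `leaf_spec` / `fruit_spec`
#'   templates.
#' @param seed master integer seed.
#' @return list of `leaf_image` / `fruit_image` objects; image ids carry the
#'   template name and replicate index.
#' @export
generate_training_set <- function(n_per_class, classes, seed = 1L) {
  if (length(classes) == 0L) abort("classes must be a non-empty list of spec templates")
  if (n_per_class < 1L) abort("n_per_class must be >= 1")
  nm <- names(classes) %||% paste0("class", seq_along(classes))
  nm[nm == ""] <- paste0("class", which(nm == ""))
  total <- n_per_class * length(classes)
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  out <- vector("list", total)
  k <- 0L
  for (ci in seq_along(classes)) {
    for (ri in seq_len(n_per_class)) {
      k <- k + 1L
      sp <- classes[[ci]]
      sp$seed <- seeds[k]
      im <- if (inherits(sp, "leaf_spec")) generate_leaf(sp) else generate_fruit(sp)
      im$id <- sprintf("%s_%02d", nm[ci], ri)
      out[[k]] <- im
    }
  }
  out
}

#' Collect semantic labels of a set of images
#'
#' @param images list of `pheno_image` objects.
#' @return tibble with `image_id`, `semantic_class`, `term`, `degree`.
#' @export
phenotype_labels <- function(images) {
  bind_rows(lapply(images, function(im) mutate(im$labels, image_id = im$id, .before = 1)))
}

#' Write images as PNG with JSON ground-truth sidecars
#'
#' Each image is written as `<id>.png`; ground truth (run-length encoded
#' lesion masks or the fruit outline, plus labels) as `<id>.json`; all labels
#' together as `labels.csv` (image_id, semantic_class, term, degree).
#'
#' @param images list of `pheno_image` objects.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phenotype_set <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in images) {
    png::writePNG(im$image, file.path(dir, paste0(im$id, ".png")))
    side <- list(id = im$id, labels = im$labels)
    if (inherits(im, "leaf_image")) {
      nrr <- dim(im$image)[1]
      side$lesions <- lapply(seq_along(im$truth$lesion_masks), function(i) {
        m <- matrix(FALSE, nrr, dim(im$image)[2])
        m[im$truth$lesion_masks[[i]]] <- TRUE
        list(class = im$truth$lesions$tissue_class[i], mask_rle = rle_encode(m))
      })
    } else {
      side$fruit_outline <- im$truth$outline
    }
    jsonlite::write_json(side, file.path(dir, paste0(im$id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(phenotype_labels(images), file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phenotype image written by [write_phenotype_set()]
#'
#' @param path path to a PNG file.
#' @return H x W x 3 array in `[0,1]`.
#' @export
read_phenotype_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = TRUE]
}

#' The standard synthetic leaf study design
#'
#' Eight class templates spanning the four leaf semantic classes with
#' pairwise-disjoint generative ranges: lesion color (brown vs yellow),
#' shape (elliptical vs irregular), size (small / medium / large area
#' bands), and coverage (few / moderate / extensive counts). Used as the
#' training-set design for end-to-end evaluation; pass to
#' [generate_training_set()].
#'
#' The templates use a large blade (720 x 180 px) with the default absolute
#' lesion-size bands and low lesion counts, keeping the probability of
#' lesion-lesion contact small: merged components are what smear one class's
#' measurements into another's band. Coverage classes are separated by wide
#' count gaps (2 / 4-6 / 16) for the same reason. Extract features with
#' [leaf_study_config()] so the size-histogram bins keep the same absolute
#' width as on the default blade.
#'
#' @return named list of [leaf_spec()] templates.
#' @export
leaf_study_templates <- function() {
  sz <- c(720L, 180L)
  list(
    brown_medium      = leaf_spec(4, "brown_necrotic", "medium", "elliptical", "spaced", image_size = sz),
    yellow_medium     = leaf_spec(4, "yellow_chlorotic", "medium", "elliptical", "spaced", image_size = sz),
    brown_irregular   = leaf_spec(4, "brown_necrotic", "medium", "irregular", "spaced", image_size = sz),
    brown_small       = leaf_spec(6, "brown_necrotic", "small", "elliptical", "spaced", image_size = sz),
    brown_large       = leaf_spec(4, "brown_necrotic", "large", "elliptical", "spaced", image_size = sz),
    brown_few         = leaf_spec(2, "brown_necrotic", "medium", "elliptical", "spaced", image_size = sz),
    yellow_large      = leaf_spec(5, "yellow_chlorotic", "large", "irregular", "spaced", image_size = sz),
    brown_extensive   = leaf_spec(16, "brown_necrotic", "small", "elliptical", "spaced", image_size = sz)
  )
}

#' Extraction configuration matching [leaf_study_templates()]
#'
#' The study blade has three times the area of the default blade; scaling
#' `size_max_frac` down by the same factor keeps the size-histogram bins at
#' the same absolute width (px^2), so the generator's size bands still map
#' into single bins.
#'
#' @return a [leaf_pipeline_config()].
#' @export
leaf_study_config <- function() {
  leaf_pipeline_config(size_max_frac = 1 / 30)
}

#' The standard synthetic fruit study design
#'
#' One template per shape class (medium size) plus small/large round
#' templates, covering the eight fruit shapes and three sizes.
#'
#' @return named list of [fruit_spec()] templates.
#' @export
fruit_study_templates <- function() {
  shapes <- c("flat", "heart", "long", "obovoid", "oxheart",
              "rectangular", "round", "ellipsoid")
  out <- lapply(shapes, function(s) fruit_spec(s, "medium"))
  names(out) <- shapes
  c(out, list(round_small = fruit_spec("round", "small"),
              round_large = fruit_spec("round", "large")))
}
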