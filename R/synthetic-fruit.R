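# Synthetic tomato-style fruit silhouettes: eight shape classes drawn from a
# parametric half-width profile family, three size classes.

# Half-width profile f(s), s in [0,1] from top to bottom of the fruit, with
# max(f) = 1. Ellipse profiles for round/flat/long/ellipsoid, a superellipse
# for rectangular, and beta-like profiles (pointed ends, adjustable broadest
# height) for heart/oxheart/obovoid.
fruit_profiles <- function() {
  ell <- function(s) sqrt(pmax(0, 1 - (2 * s - 1)^2))
  beta_prof <- function(p, q) {
    smax <- p / (p + q)
    cmax <- smax^p * (1 - smax)^q
    function(s) (s^p * (1 - s)^q) / cmax
  }
  list(
    # a_scale / b_scale multiply the nominal radius to give half-width /
    # half-height; long is tall by construction (height/width > 1.3).
    round       = list(f = ell, a = 1.00, b = 1.00),
    flat        = list(f = ell, a = 1.00, b = 0.62),
    long        = list(f = ell, a = 0.58, b = 1.00),
    ellipsoid   = list(f = ell, a = 0.80, b = 1.00),
    rectangular = list(f = function(s) (1 - abs(2 * s - 1)^4)^(1 / 4), a = 0.85, b = 1.00),
    heart       = list(f = beta_prof(0.6, 1.4), a = 0.95, b = 1.00),
    oxheart     = list(f = beta_prof(0.5, 2.0), a = 0.85, b = 1.10),
    obovoid     = list(f = beta_prof(1.6, 0.6), a = 0.85, b = 1.00)
  )
}

#' Specification of one synthetic fruit silhouette
#'
#' @param shape_class one of `flat`, `heart`, `long`, `obovoid`, `oxheart`,
#'   `rectangular`, `round`, `ellipsoid`.
#' @param size_class `small`, `medium` or `large` (nominal radii 45, 75,
#'   105 px).
#' @param fill_color RGB triple in `[0,1]`.
#' @param background_color solid background RGB triple.
#' @param seed integer RNG seed (drives mild size jitter and color noise).
#' @return an object of class `fruit_spec`.
#' @export
fruit_spec <- function(shape_class = c("round", "flat", "heart", "long", "obovoid",
                                       "oxheart", "rectangular", "ellipsoid"),
                       size_class = c("medium", "small", "large"),
                       fill_color = c(0.80, 0.16, 0.10),
                       background_color = c(0.98, 0.98, 0.98),
                       seed = 1L) {
  shape_class <- match.arg(shape_class)
  structure(list(
    kind = "fruit",
    shape_class = shape_class,
    size_class = match.arg(size_class),
    fill_color = fill_color,
    background_color = background_color,
    seed = as.integer(seed)
  ), class = "fruit_spec")
}

fruit_radius <- function(size_class) {
  switch(size_class, small = 45, medium = 75, large = 105)
}

#' Generate a synthetic fruit silhouette with ground truth
#'
#' Produces a single solid fruit on a solid background. The outline is a
#' parametric half-width profile per shape class (a circle for `round`, a
#' tall ellipse for `long`, pointed-bottom profiles for heart types, ...).
#' Identical specs yield bit-identical rasters.
#'
#' @param spec a [fruit_spec()].
#' @return an object of class `fruit_image`: list with `image` (H x W x 3),
#'   `id`, `labels`, and `truth` (logical `mask`, `outline` tibble of the
#'   boundary polygon in 0-based pixel coordinates).
#' @export
generate_fruit <- function(spec) {
  stopifnot(inherits(spec, "fruit_spec"))
  prof <- fruit_profiles()[[spec$shape_class]]
  if (is.null(prof)) abort(paste0("unknown shape_class: ", spec$shape_class))
  with_local_seed(spec$seed, {
    r <- fruit_radius(spec$size_class) * runif(1, 0.95, 1.05)
    a <- prof$a * r; b <- prof$b * r
    S <- 2L * ceiling(1.15 * max(a, b)) + 31L
    cx <- (S - 1) / 2; cy <- (S - 1) / 2
    ys <- 0:(S - 1)
    s <- (ys - (cy - b)) / (2 * b)
    half <- ifelse(s >= 0 & s <= 1, a * prof$f(pmin(pmax(s, 0), 1)), -1)
    xs <- 0:(S - 1)
    mask <- outer(ys, xs, function(y, x) abs(x - cx) <= half[y + 1])
    img <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_color[ch]
    idx <- which(mask)
    hw <- S * S
    for (ch in 1:3) img[idx + (ch - 1L) * hw] <- spec$fill_color[ch]
    noise_idx <- rep(idx, 3) + rep(0:2, each = length(idx)) * hw
    img[noise_idx] <- clip01(img[noise_idx] + rnorm(length(noise_idx), 0, 0.006))
    # outline polygon: right flank top->bottom, then left flank bottom->top
    inside <- which(half >= 0)
    outline <- tibble(
      x = c(cx + half[inside], rev(cx - half[inside])),
      y = c(ys[inside], rev(ys[inside]))
    )
    structure(list(
      image = img,
      id = sprintf("fruit_%s_%s_%d", spec$shape_class, spec$size_class, spec$seed),
      protocol = list(background_color = spec$background_color, kind = "solid_background"),
      labels = tibble(
        semantic_class = c("fruit_shape", "fruit_size"),
        term = c(paste0(spec$shape_class, "_shape"), paste0(spec$size_class, "_size")),
        degree = "extensive"
      ),
      spec = spec,
      truth = list(mask = mask, outline = outline)
    ), class = c("fruit_image", "pheno_image"))
  })
}

#' @export
print.fruit_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fruit_image %s: %dx%d px, shape %s, size %s>\n",
              x$id, d[2], d[1], x$spec$shape_class, x$spec$size_class))
  invisible(x)
}
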