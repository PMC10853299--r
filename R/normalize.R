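#' Standard-scale template constructor
#'
#' A trained piecewise-linear histogram-matching template: ordered percentile
#' landmark ranks and the standard-scale intensities they map to. The first
#' and last standard values are anchored at the ends of `scale_range`.
#'
#' @param landmark_percentiles ordered percentile ranks in (0, 100).
#' @param standard_values strictly increasing standard-scale intensities,
#'   same length, with `standard_values[1] == scale_range[1]` and the last
#'   equal to `scale_range[2]`.
#' @param scale_range two-element numeric, the standard scale endpoints.
#' @param contrast_tag `"pre"` or `"post"` contrast, kept so pre- and
#'   post-contrast templates are never mixed up on disk.
#' @return object of class `standard_scale`.
#' @export
standard_scale <- function(landmark_percentiles, standard_values,
                           scale_range = c(0, 100), contrast_tag = "pre") {
  p <- as.numeric(landmark_percentiles)
  v <- as.numeric(standard_values)
  if (length(p) < 2L || is.unsorted(p, strictly = TRUE) ||
      any(p <= 0) || any(p >= 100))
    stop("landmark percentiles must be strictly increasing inside (0, 100)")
  if (length(v) != length(p))
    stop("'standard_values' must match 'landmark_percentiles' in length")
  if (is.unsorted(v, strictly = TRUE))
    stop("'standard_values' must be strictly increasing")
  if (abs(v[1] - scale_range[1]) > 1e-8 ||
      abs(v[length(v)] - scale_range[2]) > 1e-8)
    stop("first/last standard values must equal the scale range endpoints")
  structure(list(landmark_percentiles = p, standard_values = v,
                 scale_range = as.numeric(scale_range),
                 contrast_tag = contrast_tag),
            class = "standard_scale")
}

#' @export
print.standard_scale <- function(x, ...) {
  cat(sprintf("<standard_scale> %s-contrast, scale [%g, %g]\n",
              x$contrast_tag, x$scale_range[1], x$scale_range[2]))
  m <- rbind(percentile = x$landmark_percentiles,
             standard = round(x$standard_values, 4))
  colnames(m) <- rep("", ncol(m))
  print(m)
  invisible(x)
}

# landmark intensities of one image inside its mask
image_landmarks <- function(vol, mask, percentiles) {
  vals <- if (is.null(mask)) {
    v <- as.vector(vol$data)
    v[v != 0]
  } else {
    vol$data[mask$data != 0]
  }
  if (length(unique(vals)) < length(percentiles))
    stop("mask holds fewer distinct intensities than there are landmarks")
  landmark_quantile(vals, percentiles)
}

#' Train a piecewise-linear histogram-matching template
#'
#' For each cohort image, landmark intensities are computed at the given
#' percentile ranks inside its mask and mapped affinely so that the first
#' and last landmarks hit the ends of `scale_range`; the mapped interior
#' landmarks are then averaged across images. The default configuration is
#' the canonical one for this method: deciles anchored by the 1st and 99th
#' percentiles on a 0-100 scale.
#'
#' @param images list of `mri_volume` (a single volume may be passed bare).
#' @param masks list of binary mask volumes, one per image, or `NULL` to use
#'   each image's nonzero voxels (the brain mask convention for
#'   brain-extracted images and phantoms).
#' @param percentiles ordered landmark ranks in (0, 100).
#' @param scale_range standard scale endpoints.
#' @param contrast_tag stored tag, `"pre"` or `"post"`.
#' @return a [standard_scale()].
#' @export
train_template <- function(images, masks = NULL,
                           percentiles = c(1, seq(10, 90, by = 10), 99),
                           scale_range = c(0, 100), contrast_tag = "pre") {
  if (inherits(images, "mri_volume")) images <- list(images)
  if (inherits(masks, "mri_volume")) masks <- list(masks)
  if (length(images) < 1L) stop("need at least one image")
  if (!is.null(masks) && length(masks) != length(images))
    stop("'masks' must have one mask per image")
  if (is.unsorted(percentiles, strictly = TRUE) ||
      any(percentiles <= 0) || any(percentiles >= 100))
    stop("'percentiles' must be strictly increasing inside (0, 100)")
  s_min <- scale_range[1]; s_max <- scale_range[2]
  mapped <- vapply(seq_along(images), function(i) {
    lm <- image_landmarks(images[[i]],
                          if (is.null(masks)) NULL else masks[[i]],
                          percentiles)
    if (is.unsorted(lm, strictly = TRUE))
      stop("image ", i, " has non-strictly-increasing landmarks")
    s_min + (lm - lm[1]) * (s_max - s_min) / (lm[length(lm)] - lm[1])
  }, numeric(length(percentiles)))
  mapped <- matrix(mapped, nrow = length(percentiles))
  std <- rowMeans(mapped)
  std[1] <- s_min
  std[length(std)] <- s_max
  if (is.unsorted(std, strictly = TRUE))
    stop("averaged landmarks are not strictly increasing; degenerate cohort")
  standard_scale(percentiles, std, scale_range, contrast_tag)
}

# continuous piecewise-linear map through knots (xk, yk), linearly
# extrapolated beyond the first/last knot
map_piecewise_linear <- function(x, xk, yk) {
  K <- length(xk)
  y <- stats::approx(xk, yk, xout = x, rule = 2, ties = "ordered")$y
  lo <- x < xk[1]
  hi <- x > xk[K]
  if (any(lo)) {
    s1 <- (yk[2] - yk[1]) / (xk[2] - xk[1])
    y[lo] <- yk[1] + (x[lo] - xk[1]) * s1
  }
  if (any(hi)) {
    sK <- (yk[K] - yk[K - 1]) / (xk[K] - xk[K - 1])
    y[hi] <- yk[K] + (x[hi] - xk[K]) * sK
  }
  y
}

#' Normalize an image onto a standard scale
#'
#' Computes the image's own landmark intensities inside the mask and maps
#' every voxel by continuous piecewise-linear interpolation from those
#' landmarks to the template's standard values. Values beyond the first or
#' last landmark are linearly extrapolated (never clipped — clipping would
#' flatten the deep-hypointensity tail this analysis depends on). The map
#' is monotone non-decreasing by construction.
#'
#' @param image an `mri_volume`.
#' @param mask binary mask volume or `NULL` for the nonzero-voxel brain
#'   mask convention.
#' @param template a [standard_scale()].
#' @return the normalized `mri_volume`.
#' @export
apply_template <- function(image, mask = NULL, template) {
  stopifnot(inherits(image, "mri_volume"), inherits(template, "standard_scale"))
  lm <- image_landmarks(image, mask, template$landmark_percentiles)
  if (is.unsorted(lm, strictly = TRUE))
    stop("image landmarks are not strictly increasing (near-constant image)")
  out <- image
  out$data <- array(map_piecewise_linear(as.vector(image$data), lm,
                                         template$standard_values),
                    dim(image$data))
  out
}

#' Save / load a standard-scale template
#'
#' Plain-text, versioned key-value format: a header (`version`,
#' `contrast_tag`, `scale_range`) followed by two aligned numeric rows for
#' the percentile ranks and standard values. Pre- and post-contrast
#' templates are stored as separate files.
#'
#' @param template a [standard_scale()].
#' @param path file path.
#' @return `save_template` returns the path invisibly; `load_template`
#'   returns the parsed [standard_scale()].
#' @export
save_template <- function(template, path) {
  stopifnot(inherits(template, "standard_scale"))
  lines <- c("rimsift_template\tv1",
             paste0("contrast_tag\t", template$contrast_tag),
             paste("scale_range", paste(format(template$scale_range, digits = 17),
                                        collapse = "\t"), sep = "\t"),
             paste("percentiles", paste(format(template$landmark_percentiles,
                                               digits = 17), collapse = "\t"),
                   sep = "\t"),
             paste("standard_values", paste(format(template$standard_values,
                                                   digits = 17), collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 5L || fields[[1]][1] != "rimsift_template" ||
      fields[[1]][2] != "v1")
    stop("malformed template file: ", path)
  kv <- stats::setNames(lapply(fields[-1], `[`, -1),
                        vapply(fields[-1], `[`, "", 1))
  need <- c("contrast_tag", "scale_range", "percentiles", "standard_values")
  if (!all(need %in% names(kv)))
    stop("malformed template file (missing keys): ", path)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(kv[[k]]))
    if (any(is.na(v))) stop("malformed numeric row '", k, "' in ", path)
    v
  }
  standard_scale(num("percentiles"), num("standard_values"),
                 num("scale_range"), kv[["contrast_tag"]][1])
}
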