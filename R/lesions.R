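#' Subtract the PRL map from the total lesion map
#'
#' Voxel-wise `total AND NOT prl`, yielding the non-phase-rim white-matter
#' lesion (nPR-WML) map. The output and the PRL map are disjoint and their
#' union recovers the total map wherever the PRL map is contained in it.
#'
#' @param total,prl binary mask volumes on the same grid.
#' @return binary mask `mri_volume`.
#' @export
subtract_prl <- function(total, prl) {
  check_compatible(total = total, prl = prl)
  if (!is_binary(total) || !is_binary(prl))
    stop("masks must be binary (0/1)")
  out <- total
  out$data <- array(as.numeric(total$data != 0 & prl$data == 0), dim(total$data))
  out
}

# neighbour offsets for 6-, 18- and 26-connectivity
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1L,
                 "18" = rowSums(abs(g)) <= 2L,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Standard 3-D connected-component labelling at 6-, 18- or 26-connectivity
#' (default 26, the usual 3-D clustering convention). Labels are assigned
#' in order of each component's first voxel in linear (column-major) grid
#' order, so labelling is deterministic across runs and platforms.
#'
#' @param mask binary mask volume.
#' @param connectivity one of 6, 18, 26.
#' @return object of class `label_map`: list with the integer `labels`
#'   array (0 = background), component count `n`, and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "mri_volume"))
  if (!is_binary(mask)) stop("mask must be binary (0/1)")
  off <- neighbor_offsets(connectivity)
  d <- dim(mask$data)
  dp <- d + 2L
  pm <- array(FALSE, dp)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L) - 1L] <- mask$data != 0
  # linear-index offsets are safe in the padded array: the one-voxel border
  # is background, so a frontier can never wrap onto foreground
  loff <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  labels <- array(0L, dp)
  unvisited <- pm
  seeds <- which(pm)
  k <- 0L
  for (s in seeds) {
    if (!unvisited[s]) next
    k <- k + 1L
    unvisited[s] <- FALSE
    labels[s] <- k
    frontier <- s
    while (length(frontier)) {
      nb <- rep(frontier, each = length(loff)) + loff
      nb <- unique(nb[unvisited[nb]])
      if (!length(nb)) break
      unvisited[nb] <- FALSE
      labels[nb] <- k
      frontier <- nb
    }
  }
  structure(list(labels = labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L),
                                 drop = FALSE],
                 n = k, connectivity = connectivity,
                 voxel_size_mm = mask$voxel_size_mm),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d components at %d-connectivity on a %s grid\n",
              x$n, x$connectivity, paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Per-lesion feature extraction
#'
#' One record per labelled lesion: voxel count, physical volume, mean
#' normalized post-contrast intensity, and the 5th-percentile normalized
#' pre-contrast intensity (computed with the pinned [landmark_quantile()]
#' estimator) — the feature set the downstream classifier runs on.
#'
#' @param labels a [label_components()] result.
#' @param class_label class assigned to every record (`"PRL"` or
#'   `"nPR-WML"`).
#' @param t1pre,t1post normalized pre-/post-contrast `mri_volume`s on the
#'   same grid as the label map.
#' @return a `data.frame` with columns `lesion_id`, `class`, `n_voxels`,
#'   `volume_mm3`, `mean_t1post`, `p5_t1pre`.
#' @export
extract_features <- function(labels, class_label, t1pre, t1post) {
  stopifnot(inherits(labels, "label_map"))
  check_compatible(t1pre = t1pre, t1post = t1post)
  if (!all(dim(labels$labels) == dim(t1pre$data)))
    stop("label map and intensity volumes are on different grids")
  vv <- prod(labels$voxel_size_mm)
  if (labels$n == 0L)
    return(data.frame(lesion_id = integer(0), class = character(0),
                      n_voxels = integer(0), volume_mm3 = numeric(0),
                      mean_t1post = numeric(0), p5_t1pre = numeric(0)))
  fg <- which(labels$labels > 0L)
  lab <- labels$labels[fg]
  if (!setequal(unique(lab), seq_len(labels$n)))
    stop("malformed label map: labels are not contiguous 1..K or a label is empty")
  pre <- split(t1pre$data[fg], lab)
  post <- split(t1post$data[fg], lab)
  ids <- as.integer(names(pre))
  o <- order(ids)
  data.frame(
    lesion_id = ids[o],
    class = class_label,
    n_voxels = vapply(pre, length, 0L)[o],
    volume_mm3 = vapply(pre, length, 0L)[o] * vv,
    mean_t1post = vapply(post, mean, 0)[o],
    p5_t1pre = vapply(pre, landmark_quantile, 0, p = 5)[o],
    row.names = NULL)
}

#' Lesion exclusion filter specification
#'
#' @param min_volume_mm3 lesions strictly under this volume are discarded
#'   (default 1 mm^3, removing segmentation specks).
#' @param max_mean_t1post lesions whose mean normalized post-contrast
#'   intensity is strictly greater than this are discarded (default 80,
#'   screening out contrast-enhancing lesions whose acute inflammation
#'   confounds the pre-contrast hypointensity signal).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(min_volume_mm3 = 1, max_mean_t1post = 80) {
  if (min_volume_mm3 <= 0 || max_mean_t1post <= 0)
    stop("filter thresholds must be positive")
  structure(list(min_volume_mm3 = min_volume_mm3,
                 max_mean_t1post = max_mean_t1post),
            class = "filter_spec")
}

#' Apply the lesion exclusion filters
#'
#' Removal rules use strict inequalities ("under 1 mm^3", "greater than
#' 80"): a 1.0 mm^3 lesion and a mean post-contrast intensity of exactly 80
#' are both kept. Rules are attributed sequentially — volume first, then
#' enhancement among the survivors — so each removed lesion counts under
#' exactly one rule.
#'
#' @param records a feature table from [extract_features()].
#' @param spec a [filter_spec()].
#' @return list with `kept` (the filtered table) and `removed_counts`
#'   (named integer vector: `too_small`, `enhancing`).
#' @export
filter_lesions <- function(records, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  small <- records$volume_mm3 < spec$min_volume_mm3
  enh <- !small & records$mean_t1post > spec$max_mean_t1post
  list(kept = records[!small & !enh, , drop = FALSE],
       removed_counts = c(too_small = sum(small), enhancing = sum(enh)))
}

#' Write / read a lesion feature table
#'
#' Tab-delimited text with a header row.
#'
#' @param records lesion feature table.
#' @param path file path.
#' @return `write_lesion_table` returns the path invisibly;
#'   `read_lesion_table` returns the data frame.
#' @export
write_lesion_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lesion_table
#' @export
read_lesion_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
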