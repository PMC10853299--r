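#' Phantom specification
#'
#' Parameters of the synthetic co-registered MRI set the pipeline is tested
#' on. Defaults reproduce the study conditions the analysis assumes: severe
#' class imbalance (39 phase-rim lesions vs 1075 non-phase-rim white-matter
#' lesions), isotropic 0.5 mm voxels, a unimodal nPR-WML intensity
#' distribution with mode 64.8 on the normalized 0-100 scale, and a bimodal
#' PRL distribution with modes 0.9 and 60.2 carrying 14% of its mass in the
#' hypointense component.
#'
#' Mixture standard deviations are calibrated so the analytic mass below the
#' deep-hypointensity cutoff of 25 equals the target deep-voxel fractions:
#' sd 15.45 puts 0.50% of N(64.8, 15.45) below 25, and the PRL mixture
#' 0.14 N(0.9, 3) + 0.86 N(60.2, 8) has 14.00% of its mass below 25.
#'
#' The background is a four-component tissue mixture (CSF-like, grey-matter-
#' like, white-matter-like at `background_mean`/`background_sd`, and a small
#' bright compartment) whose 1st/99th brain percentiles land near 0/100, so
#' phantom intensities are born on an "already normalizable" standard scale
#' and self-trained normalization is close to the identity.
#'
#' @param grid_shape integer vector of 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @param n_nprwml,n_prl,n_enhancing,n_tiny lesion counts per class. Tiny
#'   lesions are 1-7 voxel clusters (under 1 mm^3 at 0.5 mm spacing);
#'   enhancing lesions get bright post-contrast intensities.
#' @param lesion_radius_range_mm min/max sphere radius in mm for the three
#'   non-tiny classes.
#' @param nprwml_mix named vector `c(mean, sd)` for nPR-WML voxel
#'   intensities.
#' @param prl_mix named vector `c(hypo_mean, hypo_sd, hyper_mean, hyper_sd,
#'   hypo_weight)` for the two-component PRL mixture.
#' @param background_mean,background_sd white-matter background component.
#' @param background_extra list of named vectors `c(weight, mean, sd)` for
#'   the remaining tissue compartments; the white-matter weight is
#'   `1 - sum(weights)`.
#' @param enhancing_post_mean,enhancing_post_sd post-contrast intensity of
#'   enhancing lesions (mean must exceed the 80-intensity screening rule to
#'   exercise the exclusion filter).
#' @param bias_field_amplitude amplitude of a smooth multiplicative bias
#'   field applied to both output volumes; 0 (default) disables it.
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()], [sample_lesion_intensities()]
#' @export
phantom_spec <- function(grid_shape = c(192L, 192L, 192L),
                         voxel_size_mm = 0.5,
                         n_nprwml = 1075L,
                         n_prl = 39L,
                         n_enhancing = 8L,
                         n_tiny = 8L,
                         lesion_radius_range_mm = c(1, 3),
                         nprwml_mix = c(mean = 64.8, sd = 15.45),
                         prl_mix = c(hypo_mean = 0.9, hypo_sd = 3,
                                     hyper_mean = 60.2, hyper_sd = 8,
                                     hypo_weight = 0.14),
                         background_mean = 70,
                         background_sd = 6,
                         background_extra = list(
                           csf    = c(weight = 0.12, mean = 7,  sd = 5),
                           gm     = c(weight = 0.38, mean = 45, sd = 8),
                           bright = c(weight = 0.04, mean = 96, sd = 6)),
                         enhancing_post_mean = 90,
                         enhancing_post_sd = 5,
                         bias_field_amplitude = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  counts <- c(n_nprwml = n_nprwml, n_prl = n_prl,
              n_enhancing = n_enhancing, n_tiny = n_tiny)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("'grid_shape' must be three positive integers")
  if (any(counts < 0))
    stop("lesion counts must be non-negative")
  if (voxel_size_mm <= 0) stop("'voxel_size_mm' must be positive")
  r <- as.numeric(lesion_radius_range_mm)
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
    stop("'lesion_radius_range_mm' must be positive and ordered (min, max)")
  w <- prl_mix[["hypo_weight"]]
  if (is.na(w) || w < 0 || w > 1)
    stop("'hypo_weight' must lie in [0, 1]")
  if (nprwml_mix[["sd"]] <= 0 || prl_mix[["hypo_sd"]] <= 0 || prl_mix[["hyper_sd"]] <= 0)
    stop("mixture standard deviations must be positive")
  ew <- vapply(background_extra, function(comp) comp[["weight"]], 0)
  if (sum(ew) >= 1) stop("background_extra weights must sum to less than 1")
  if (bias_field_amplitude < 0 || bias_field_amplitude >= 1)
    stop("'bias_field_amplitude' must lie in [0, 1)")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_nprwml = as.integer(n_nprwml), n_prl = as.integer(n_prl),
                 n_enhancing = as.integer(n_enhancing), n_tiny = as.integer(n_tiny),
                 lesion_radius_range_mm = r,
                 nprwml_mix = nprwml_mix, prl_mix = prl_mix,
                 background_mean = background_mean, background_sd = background_sd,
                 background_extra = background_extra,
                 enhancing_post_mean = enhancing_post_mean,
                 enhancing_post_sd = enhancing_post_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s @ %.2f mm | PRL %d, nPR-WML %d, enhancing %d, tiny %d | seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              x$n_prl, x$n_nprwml, x$n_enhancing, x$n_tiny, x$seed))
  invisible(x)
}

# relative (dx,dy,dz) offsets of voxels whose centres lie within radius_vox
# (Euclidean, voxel units) of the origin
sphere_offsets <- function(radius_vox) {
  r <- ceiling(radius_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

# Rasterize the sphere of radius radius_mm centred on integer voxel `centre`.
# A voxel belongs to the lesion iff its centre is within radius_mm (world mm).
rasterize_sphere <- function(centre, radius_mm, voxel_size_mm) {
  off <- sphere_offsets(radius_mm / voxel_size_mm)
  sweep(off, 2L, centre, "+")
}

coords_to_index <- function(coords, dims) {
  coords[, 1] + (coords[, 2] - 1L) * dims[1] + (coords[, 3] - 1L) * dims[1] * dims[2]
}

#' Generate a synthetic co-registered MRI phantom
#'
#' Plants non-overlapping lesions (rasterized spheres, plus small irregular
#' clusters for the tiny class) on a tissue-mixture background and draws
#' voxel intensities from the class-specific distributions in the spec.
#' Within each PRL the hypointense component is assigned to the outermost
#' voxels first, giving a rim-like geometry while keeping the overall
#' hypointense fraction binomial with the configured weight. The
#' post-contrast volume equals the pre-contrast one except inside enhancing
#' lesions, which receive bright post-contrast intensities.
#'
#' Lesion placement uses rejection sampling with a minimum one-voxel gap
#' between lesions (checked with a two-voxel Euclidean margin), so connected
#' components of the ground-truth masks coincide with planted lesions at any
#' connectivity.
#'
#' @param spec a [phantom_spec()].
#' @param max_attempts placement attempts per lesion before giving up.
#' @return an object of class `prl_phantom`: a list with `mri_volume`s
#'   `t1_pre`, `t1_post`, binary `total_lesion_mask` and `prl_mask`, a
#'   `truth` data frame (one row per planted lesion: id, class, centre,
#'   radius, voxel count, hypointense-component count), and the `spec`.
#' @export
generate_phantom <- function(spec, max_attempts = 1000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dims <- spec$grid_shape
    nvox <- prod(dims)
    vs <- spec$voxel_size_mm
    occupied <- array(FALSE, dims)
    classes <- c(rep("PRL", spec$n_prl),
                 rep("nPR-WML", spec$n_nprwml),
                 rep("enhancing", spec$n_enhancing),
                 rep("tiny", spec$n_tiny))
    n_lesions <- length(classes)

    lesion_voxels <- vector("list", n_lesions)
    truth <- data.frame(lesion_id = integer(0), class = character(0),
                        cx = integer(0), cy = integer(0), cz = integer(0),
                        radius_mm = numeric(0), n_voxels = integer(0),
                        n_hypo = integer(0))

    for (i in seq_len(n_lesions)) {
      cls <- classes[i]
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        if (cls == "tiny") {
          size <- sample.int(7L, 1L)
          margin <- 6L
          if (any(dims <= 2L * margin))
            stop("grid too small to place tiny lesions")
          centre <- vapply(dims, function(d) sample(seq(margin, d - margin), 1L), 0L)
          coords <- grow_cluster(centre, size, dims)
          radius_mm <- NA_real_
          # demand a Chebyshev-2 clear zone around every cluster voxel
          guard <- cluster_guard(coords, dims)
        } else {
          radius_mm <- stats::runif(1L, spec$lesion_radius_range_mm[1],
                                    spec$lesion_radius_range_mm[2])
          r_vox <- radius_mm / vs
          margin <- ceiling(r_vox) + 3L
          if (any(dims <= 2L * margin))
            stop("grid too small for the requested lesion radii")
          centre <- vapply(dims, function(d) sample(seq(margin, d - margin), 1L), 0L)
          coords <- rasterize_sphere(centre, radius_mm, vs)
          guard <- rasterize_sphere(centre, (r_vox + 2) * vs, vs)
        }
        if (!any(occupied[coords_to_index(guard, dims)])) {
          idx <- coords_to_index(coords, dims)
          occupied[idx] <- TRUE
          lesion_voxels[[i]] <- list(idx = idx, coords = coords, centre = centre)
          truth <- rbind(truth, data.frame(
            lesion_id = i, class = cls,
            cx = centre[1], cy = centre[2], cz = centre[3],
            radius_mm = radius_mm, n_voxels = length(idx), n_hypo = 0L))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "failed to place lesion %d of %d (class %s) after %d attempts; reduce counts or enlarge the grid",
          i, n_lesions, cls, max_attempts))
    }

    # background tissue mixture
    ew <- vapply(spec$background_extra, function(c) c[["weight"]], 0)
    means <- c(vapply(spec$background_extra, function(c) c[["mean"]], 0),
               spec$background_mean)
    sds <- c(vapply(spec$background_extra, function(c) c[["sd"]], 0),
             spec$background_sd)
    wts <- c(ew, 1 - sum(ew))
    comp <- findInterval(stats::runif(nvox), cumsum(wts)[-length(wts)]) + 1L
    t1_pre <- array(stats::rnorm(nvox, means[comp], sds[comp]), dims)

    enhancing_idx <- integer(0)
    enhancing_n <- integer(0)
    for (i in seq_len(n_lesions)) {
      les <- lesion_voxels[[i]]
      n <- length(les$idx)
      cls <- classes[i]
      if (cls == "PRL") {
        pm <- spec$prl_mix
        n_hypo <- stats::rbinom(1L, n, pm[["hypo_weight"]])
        truth$n_hypo[i] <- n_hypo
        # outermost voxels take the hypointense component (rim-like shell);
        # ties on distance broken by linear index for determinism
        d2 <- rowSums(sweep(les$coords, 2L, les$centre, "-")^2)
        ord <- order(-d2, les$idx)
        vals <- numeric(n)
        if (n_hypo > 0L)
          vals[ord[seq_len(n_hypo)]] <-
            stats::rnorm(n_hypo, pm[["hypo_mean"]], pm[["hypo_sd"]])
        if (n_hypo < n)
          vals[ord[seq(n_hypo + 1L, n)]] <-
            stats::rnorm(n - n_hypo, pm[["hyper_mean"]], pm[["hyper_sd"]])
        t1_pre[les$idx] <- vals
      } else {
        t1_pre[les$idx] <- stats::rnorm(n, spec$nprwml_mix[["mean"]],
                                        spec$nprwml_mix[["sd"]])
        if (cls == "enhancing") {
          enhancing_idx <- c(enhancing_idx, les$idx)
          enhancing_n <- c(enhancing_n, n)
        }
      }
    }

    t1_post <- t1_pre
    if (length(enhancing_idx))
      t1_post[enhancing_idx] <- stats::rnorm(length(enhancing_idx),
                                             spec$enhancing_post_mean,
                                             spec$enhancing_post_sd)

    if (spec$bias_field_amplitude > 0) {
      field <- bias_field(dims, spec$bias_field_amplitude)
      t1_pre <- t1_pre * field
      t1_post <- t1_post * field
    }

    total <- array(0, dims)
    prl <- array(0, dims)
    for (i in seq_len(n_lesions)) total[lesion_voxels[[i]]$idx] <- 1
    for (i in which(classes == "PRL")) prl[lesion_voxels[[i]]$idx] <- 1

    structure(list(
      t1_pre = volume(t1_pre, vs),
      t1_post = volume(t1_post, vs),
      total_lesion_mask = volume(total, vs),
      prl_mask = volume(prl, vs),
      truth = truth,
      spec = spec), class = "prl_phantom")
  })
}

# grow a connected 6-neighbour cluster of `size` voxels from `centre`
grow_cluster <- function(centre, size, dims) {
  coords <- matrix(centre, nrow = 1L)
  nb6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(coords) < size) {
    base <- coords[sample.int(nrow(coords), 1L), ]
    cand <- base + nb6[sample.int(6L, 1L), ]
    if (any(cand < 2L) || any(cand > dims - 1L)) next
    dup <- any(coords[, 1] == cand[1] & coords[, 2] == cand[2] & coords[, 3] == cand[3])
    if (!dup) coords <- rbind(coords, cand)
  }
  unname(coords)
}

# all voxels within Chebyshev distance 2 of a small cluster (guard zone)
cluster_guard <- function(coords, dims) {
  g <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  out <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i)
    sweep(g, 2L, coords[i, ], "+")))
  out <- unique(out)
  out[out[, 1] >= 1L & out[, 2] >= 1L & out[, 3] >= 1L &
      out[, 1] <= dims[1] & out[, 2] <= dims[2] & out[, 3] <= dims[3], ,
      drop = FALSE]
}

# smooth multiplicative field 1 + A sin(2*pi*x/nx) sin(2*pi*y/ny) sin(2*pi*z/nz)
bias_field <- function(dims, amplitude) {
  sx <- sin(2 * pi * (seq_len(dims[1]) - 1) / dims[1])
  sy <- sin(2 * pi * (seq_len(dims[2]) - 1) / dims[2])
  sz <- sin(2 * pi * (seq_len(dims[3]) - 1) / dims[3])
  1 + amplitude * (outer(outer(sx, sy), sz))
}

#' @export
print.prl_phantom <- function(x, ...) {
  cat(sprintf("<prl_phantom> grid %s | %d lesions (%s)\n",
              paste(dim(x$t1_pre$data), collapse = "x"), nrow(x$truth),
              paste(sprintf("%s: %d", names(table(x$truth$class)),
                            as.integer(table(x$truth$class))), collapse = ", ")))
  invisible(x)
}

#' Draw i.i.d. voxel intensities for a lesion class
#'
#' Unit-level access to the phantom's class-conditional intensity
#' distributions: the single Gaussian for nPR-WML voxels and the
#' two-component (hypointense / hyperintense) mixture for PRL voxels.
#'
#' @param class_label `"PRL"` or `"nPR-WML"`.
#' @param n number of draws (may be 0).
#' @param spec a [phantom_spec()]; defaults supply the calibrated mixtures.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
sample_lesion_intensities <- function(class_label, n, spec = phantom_spec(),
                                      seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 0) stop("'n' must be non-negative")
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    if (class_label == "nPR-WML") {
      stats::rnorm(n, spec$nprwml_mix[["mean"]], spec$nprwml_mix[["sd"]])
    } else if (class_label == "PRL") {
      pm <- spec$prl_mix
      hypo <- stats::runif(n) < pm[["hypo_weight"]]
      means <- ifelse(hypo, pm[["hypo_mean"]], pm[["hyper_mean"]])
      sds <- ifelse(hypo, pm[["hypo_sd"]], pm[["hyper_sd"]])
      stats::rnorm(n, means, sds)
    } else {
      stop("unknown class label: ", class_label,
           " (expected \"PRL\" or \"nPR-WML\")")
    }
  })
}

#' Apply a global affine distortion plus a smooth bias field
#'
#' Produces a corrupted copy of a volume — `out = (slope * x + intercept) *
#' field` with a smooth sinusoidal multiplicative field — used to give the
#' intensity normalization something nontrivial to undo in recovery
#' experiments.
#'
#' @param vol an `mri_volume`.
#' @param slope,intercept global affine distortion (slope must be positive).
#' @param bias_amplitude amplitude of the multiplicative field; 0 disables.
#' @return the distorted `mri_volume`.
#' @export
distort_volume <- function(vol, slope = 1, intercept = 0, bias_amplitude = 0) {
  stopifnot(inherits(vol, "mri_volume"), slope > 0)
  out <- vol
  d <- slope * vol$data + intercept
  if (bias_amplitude > 0)
    d <- d * bias_field(dim(vol$data), bias_amplitude)
  out$data <- d
  out
}

#' Write a phantom set to disk
#'
#' Writes the four volumes as NIfTI (masks as uint8) and the ground-truth
#' lesion table as tab-delimited text.
#'
#' @param phantom a `prl_phantom`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "prl_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(t1_pre = file.path(dir, "t1_pre.nii.gz"),
             t1_post = file.path(dir, "t1_post.nii.gz"),
             total_lesion_mask = file.path(dir, "total_lesion_mask.nii.gz"),
             prl_mask = file.path(dir, "prl_mask.nii.gz"),
             truth = file.path(dir, "truth.tsv"))
  write_volume(phantom$t1_pre, paths[["t1_pre"]])
  write_volume(phantom$t1_post, paths[["t1_post"]])
  write_volume(phantom$total_lesion_mask, paths[["total_lesion_mask"]], datatype = "uint8")
  write_volume(phantom$prl_mask, paths[["prl_mask"]], datatype = "uint8")
  utils::write.table(phantom$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
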