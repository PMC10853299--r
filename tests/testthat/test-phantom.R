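test_that("zero lesion counts give empty masks and truth table", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24), n_nprwml = 0, n_prl = 0,
                     n_enhancing = 0, n_tiny = 0)
  ph <- generate_phantom(sp)
  expect_equal(sum(ph$total_lesion_mask$data), 0)
  expect_equal(sum(ph$prl_mask$data), 0)
  expect_equal(nrow(ph$truth), 0)
})

test_that("sphere rasterization matches a brute-force grid scan", {
  # 2 mm radius on a 0.5 mm grid: count all voxel centres within radius
  dims <- c(21L, 21L, 21L)
  centre <- c(11L, 11L, 11L)
  vs <- 0.5
  r_mm <- 2.0
  brute <- 0L
  for (x in 1:21) for (y in 1:21) for (z in 1:21) {
    d_mm <- sqrt(sum(((c(x, y, z) - centre) * vs)^2))
    if (d_mm <= r_mm) brute <- brute + 1L
  }
  vox <- rimsift:::rasterize_sphere(centre, r_mm, vs)
  expect_equal(nrow(vox), brute)
  expect_true(all(vox >= 1 & vox <= 21))
  # same count for a non-integer radius
  r2 <- 1.7
  brute2 <- sum(sapply(1:21, function(x) sum(sapply(1:21, function(y)
    sum(sqrt(colSums((rbind(x, y, 1:21) - centre)^2)) * vs <= r2)))))
  expect_equal(nrow(rimsift:::rasterize_sphere(centre, r2, vs)), brute2)
})

test_that("phantom structure: masks nested, binary, on one grid, deterministic", {
  sp <- small_spec(seed = 9)
  ph <- generate_phantom(sp)
  expect_true(all(ph$prl_mask$data %in% c(0, 1)))
  expect_true(all(ph$total_lesion_mask$data %in% c(0, 1)))
  expect_true(all(ph$prl_mask$data <= ph$total_lesion_mask$data))
  expect_true(check_compatible(ph$t1_pre, ph$t1_post,
                               ph$total_lesion_mask, ph$prl_mask))
  expect_equal(sum(ph$total_lesion_mask$data), sum(ph$truth$n_voxels))
  expect_equal(sum(ph$prl_mask$data),
               sum(ph$truth$n_voxels[ph$truth$class == "PRL"]))
  # tiny lesions are under 1 mm^3 at 0.5 mm spacing
  expect_true(all(ph$truth$n_voxels[ph$truth$class == "tiny"] < 8))

  ph2 <- generate_phantom(sp)
  expect_identical(ph$t1_pre$data, ph2$t1_pre$data)
  expect_identical(ph$t1_post$data, ph2$t1_post$data)
  expect_identical(ph$truth, ph2$truth)
  ph3 <- generate_phantom(small_spec(seed = 10))
  expect_false(identical(ph$t1_pre$data, ph3$t1_pre$data))
})

test_that("post-contrast volume differs from pre only inside enhancing lesions", {
  ph <- generate_phantom(small_spec(seed = 3))
  diff_idx <- which(ph$t1_post$data != ph$t1_pre$data)
  enh <- ph$truth[ph$truth$class == "enhancing", ]
  expect_equal(length(diff_idx), sum(enh$n_voxels))
  expect_true(all(ph$total_lesion_mask$data[diff_idx] == 1))
  expect_true(all(ph$prl_mask$data[diff_idx] == 0))
  # enhancing lesions are bright post-contrast (mean near 90, well over 80)
  expect_true(mean(ph$t1_post$data[diff_idx]) > 80)
})

test_that("placement failure raises an informative error", {
  sp <- phantom_spec(grid_shape = c(26, 26, 26), n_nprwml = 400, n_prl = 0,
                     n_enhancing = 0, n_tiny = 0,
                     lesion_radius_range_mm = c(2, 3))
  expect_error(generate_phantom(sp, max_attempts = 20), "failed to place")
})

test_that("spec validation rejects bad parameters", {
  expect_error(phantom_spec(n_prl = -1), "non-negative")
  expect_error(phantom_spec(lesion_radius_range_mm = c(3, 1)), "ordered")
  expect_error(phantom_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(prl_mix = c(hypo_mean = 0.9, hypo_sd = 3,
                                        hyper_mean = 60.2, hyper_sd = 8,
                                        hypo_weight = 1.4)), "hypo_weight")
})

test_that("sampled intensities reproduce the configured mixtures", {
  expect_length(sample_lesion_intensities("PRL", 0), 0)
  expect_error(sample_lesion_intensities("GM", 10), "unknown class")

  spec <- phantom_spec()
  n <- 2e5
  x <- sample_lesion_intensities("nPR-WML", n, spec, seed = 21)
  se <- spec$nprwml_mix[["sd"]] / sqrt(n)
  expect_lt(abs(mean(x) - 64.8), 3 * se)

  pm <- spec$prl_mix
  mix_mean <- pm[["hypo_weight"]] * pm[["hypo_mean"]] +
    (1 - pm[["hypo_weight"]]) * pm[["hyper_mean"]]
  mix_var <- pm[["hypo_weight"]] * (pm[["hypo_sd"]]^2 + pm[["hypo_mean"]]^2) +
    (1 - pm[["hypo_weight"]]) * (pm[["hyper_sd"]]^2 + pm[["hyper_mean"]]^2) -
    mix_mean^2
  y <- sample_lesion_intensities("PRL", n, spec, seed = 22)
  expect_lt(abs(mean(y) - mix_mean), 3 * sqrt(mix_var / n))

  # reproducibility under seed
  expect_identical(sample_lesion_intensities("PRL", 100, spec, seed = 5),
                   sample_lesion_intensities("PRL", 100, spec, seed = 5))
})

test_that("hypointense-component fraction in planted PRLs is binomial at spec weight", {
  # phantom rich in PRL voxels; truth table records per-lesion assignments
  sp <- phantom_spec(grid_shape = c(96, 96, 96), n_nprwml = 0, n_prl = 80,
                     n_enhancing = 0, n_tiny = 0,
                     lesion_radius_range_mm = c(1.5, 3), seed = 31)
  ph <- generate_phantom(sp)
  n_tot <- sum(ph$truth$n_voxels)
  expect_gt(n_tot, 2e4)
  frac <- sum(ph$truth$n_hypo) / n_tot
  se <- sqrt(0.14 * 0.86 / n_tot)
  expect_lt(abs(frac - 0.14), 3 * se)
  # and the hypointense voxels really are dark: the empirical deep fraction
  # of PRL voxels matches the component assignment
  vox <- ph$t1_pre$data[ph$prl_mask$data == 1]
  expect_lt(abs(deep_fraction(vox, 25) - frac), 0.01)
})

test_that("lesions are isolated: component count equals planted count at 26-connectivity", {
  ph <- generate_phantom(small_spec(seed = 17))
  lab <- label_components(ph$total_lesion_mask, 26)
  expect_equal(lab$n, nrow(ph$truth))
})

test_that("distort_volume applies affine and bias field as stated", {
  v <- volume(array(seq_len(27), c(3, 3, 3)))
  d <- distort_volume(v, slope = 2, intercept = 5)
  expect_equal(d$data, 2 * v$data + 5)
  db <- distort_volume(v, slope = 1, intercept = 0, bias_amplitude = 0.1)
  expect_true(all(abs(db$data / v$data - 1) <= 0.1 + 1e-12))
  expect_error(distort_volume(v, slope = -1), "slope")
})

test_that("phantom writes NIfTI volumes and a truth table that read back", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                      n_nprwml = 2, n_prl = 1,
                                      n_enhancing = 0, n_tiny = 0,
                                      lesion_radius_range_mm = c(1, 1.5),
                                      seed = 2))
  dir <- tempfile()
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_volume(paths[["prl_mask"]])
  expect_equal(as.vector(rt$data), as.vector(ph$prl_mask$data))
  truth <- read.delim(paths[["truth"]])
  expect_equal(truth$n_voxels, ph$truth$n_voxels)
})
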