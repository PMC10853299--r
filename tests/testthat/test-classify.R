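make_table <- function(n_prl, n_npr, seed = 1) {
  set.seed(seed)
  data.frame(
    lesion_id = seq_len(n_prl + n_npr),
    class = c(rep("PRL", n_prl), rep("nPR-WML", n_npr)),
    n_voxels = 50L, volume_mm3 = 6.25,
    mean_t1post = 60,
    p5_t1pre = c(rnorm(n_prl, 5, 4), rnorm(n_npr, 40, 5)))
}

test_that("stratified 50% split sends the odd lesion to training for every seed", {
  tab <- make_table(39, 1075)
  for (seed in c(1, 2, 17, 123, 99991)) {
    sp <- stratified_split(tab, 0.5, seed)
    expect_equal(sum(sp$train$class == "PRL"), 20)
    expect_equal(sum(sp$train$class == "nPR-WML"), 538)
    expect_equal(sum(sp$test$class == "PRL"), 19)
    expect_equal(sum(sp$test$class == "nPR-WML"), 537)
    # partition: disjoint and exhaustive
    expect_setequal(c(sp$train$lesion_id, sp$test$lesion_id), tab$lesion_id)
    expect_length(intersect(sp$train$lesion_id, sp$test$lesion_id), 0)
  }
})

test_that("split rejects degenerate fractions and single-class tables", {
  tab <- make_table(5, 10)
  expect_error(stratified_split(tab, 1.0), "strictly inside")
  expect_error(stratified_split(tab, 0), "strictly inside")
  expect_error(stratified_split(tab[tab$class == "PRL", ], 0.5), "both")
  expect_error(stratified_split(tab[0, ], 0.5), "empty")
})

test_that("split membership is reproducible under the seed", {
  tab <- make_table(9, 30)
  s1 <- stratified_split(tab, 0.5, 7)
  s2 <- stratified_split(tab, 0.5, 7)
  expect_identical(s1$train$lesion_id, s2$train$lesion_id)
  s3 <- stratified_split(tab, 0.5, 8)
  expect_false(identical(s1$train$lesion_id, s3$train$lesion_id))
})

test_that("perfectly separated classes give a perfect constrained cutoff", {
  train <- data.frame(class = c("PRL", "PRL", "nPR-WML", "nPR-WML"),
                      p5_t1pre = c(5, 6, 50, 60))
  fit <- select_cutoff(train, 0.95)
  expect_equal(fit$train_sensitivity, 1)
  expect_equal(fit$train_specificity, 1)
  expect_gt(fit$cutoff, 6)
  expect_lt(fit$cutoff, 50)
  expect_equal(unname(coef(fit)), fit$cutoff)
})

test_that("cutoff selection matches the exhaustive oracle on random instances", {
  set.seed(12)
  for (i in 1:60) {
    n_pos <- sample(2:12, 1)
    n_neg <- sample(2:18, 1)
    tab <- data.frame(
      class = c(rep("PRL", n_pos), rep("nPR-WML", n_neg)),
      p5_t1pre = round(c(rnorm(n_pos, 20, 15), rnorm(n_neg, 40, 15)), 1))
    constraint <- sample(c(0.5, 0.8, 0.9, 1.0), 1)
    fit <- select_cutoff(tab, constraint)
    oracle <- oracle_select_cutoff(tab$p5_t1pre, tab$class == "PRL", constraint)
    expect_equal(fit$train_sensitivity, oracle$sens, tolerance = 1e-12)
    expect_equal(fit$train_specificity, oracle$spec, tolerance = 1e-12)
    # identical decision rule (cutoffs may differ only in sentinel handling)
    expect_identical(tab$p5_t1pre < fit$cutoff, tab$p5_t1pre < oracle$cutoff)
    expect_gte(fit$train_specificity, constraint)
    expect_true(is.finite(fit$cutoff))
  }
})

test_that("cutoff selection honors the constraint and errors when infeasible", {
  train <- data.frame(class = c("PRL", "nPR-WML"), p5_t1pre = c(10, 20))
  expect_error(select_cutoff(train, 1.5), "spec_constraint")
  fit <- select_cutoff(train, 1.0)
  expect_equal(fit$train_specificity, 1)
  expect_error(select_cutoff(data.frame(class = c("PRL", "PRL"),
                                        p5_t1pre = c(1, 2)), 0.95),
               "both classes")
})

test_that("predictions are strictly-below-threshold", {
  fit <- structure(list(cutoff = 42.133, positive = "PRL"),
                   class = "p5_cutoff")
  expect_identical(predict(fit, c(42.132, 42.133, 42.134), type = "logical"),
                   c(TRUE, FALSE, FALSE))
  expect_identical(predict(fit, data.frame(p5_t1pre = 10)), "PRL")
})

test_that("evaluate reproduces the printed test-set metrics from its counts", {
  # composition: 19 positives (10 predicted), 537 negatives (22 predicted)
  test <- data.frame(
    class = c(rep("PRL", 19), rep("nPR-WML", 537)),
    p5_t1pre = c(rep(10, 10), rep(50, 9), rep(10, 22), rep(50, 515)))
  fit <- structure(list(cutoff = 42.133, positive = "PRL"),
                   class = "p5_cutoff")
  m <- evaluate(test, fit)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(10, 9, 22, 515))
  expect_equal(round_half_up(m$sensitivity, 3), 0.526)
  expect_equal(round_half_up(m$specificity, 3), 0.959)
  expect_equal(round_half_up(m$ppv, 3), 0.313)
  expect_equal(round_half_up(m$f1, 3), 0.392)
  # identity npv = 515/524 = 0.98282; agrees with a 3-decimal print of 0.982
  # to within one unit in the last printed digit
  expect_equal(m$npv, 515 / 524, tolerance = 1e-12)
  expect_lt(abs(m$npv - 0.982), 1e-3)
  expect_length(m$undefined, 0)
  expect_lt(m$fisher_p, 1e-6)
})

test_that("metric identities hold exactly and perfect/degenerate cases behave", {
  test <- data.frame(class = c(rep("PRL", 4), rep("nPR-WML", 6)),
                     p5_t1pre = c(rep(1, 4), rep(9, 6)))
  perfect <- structure(list(cutoff = 5, positive = "PRL"), class = "p5_cutoff")
  m <- evaluate(test, perfect)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv, m$f1),
               rep(1, 5))

  none <- structure(list(cutoff = 0, positive = "PRL"), class = "p5_cutoff")
  m0 <- evaluate(test, none)
  expect_equal(m0$sensitivity, 0)
  expect_true(is.nan(m0$ppv))
  expect_true("ppv" %in% m0$undefined)

  # identities on random integer counts
  set.seed(13)
  for (i in 1:20) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    fp <- sample(0:20, 1); tn <- sample(1:20, 1)
    if (tp + fn == 0) fn <- 1
    tt <- data.frame(
      class = c(rep("PRL", tp + fn), rep("nPR-WML", fp + tn)),
      p5_t1pre = c(rep(0, tp), rep(9, fn), rep(0, fp), rep(9, tn)))
    m <- evaluate(tt, structure(list(cutoff = 5, positive = "PRL"),
                                class = "p5_cutoff"))
    expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
  }
})

test_that("fisher_exact matches enumeration, handles edge tables, is symmetric", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 1, 2), 2)), 1)
  expect_error(fisher_exact(matrix(c(-1, 0, 1, 2), 2)), "non-negative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "grand total")

  set.seed(14)
  for (i in 1:50) {
    m <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    p <- fisher_exact(m)
    expect_equal(p, oracle_fisher(m), tolerance = 1e-7)
    expect_equal(fisher_exact(t(m)), p, tolerance = 1e-12)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("end-to-end phantom classification attains the constraint with signal", {
  # p5 features driven by the calibrated mixtures: PRL p5 sits in the
  # hypointense component, nPR-WML p5 in the Gaussian lower tail
  for (seed in 1:10) {
    tab <- make_table(12, 60, seed = seed)
    sp <- stratified_split(tab, 0.5, seed)
    fit <- select_cutoff(sp$train, 0.95)
    expect_gte(fit$train_specificity, 0.95)
    m <- evaluate(sp$test, fit)
    expect_gt(m$sensitivity, 0)
  }
})
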