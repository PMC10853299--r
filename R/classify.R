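#' Stratified train/test split of a lesion table
#'
#' Splits the lesion table per class at the given fraction. The training
#' half receives the extra lesion when a class count is odd (ceiling
#' allocation), so 39 PRLs and 1075 nPR-WMLs at 50% always give
#' 20/538 training and 19/537 test lesions, whatever the seed. Membership
#' within a class is random and reproducible under the seed.
#'
#' @param table lesion feature table with a `class` column.
#' @param fraction training fraction, strictly inside (0, 1); default 0.5.
#' @param seed RNG seed.
#' @return object of class `prl_split`: list with `train`, `test`,
#'   `fraction`, `seed`.
#' @export
stratified_split <- function(table, fraction = 0.5, seed = 1L) {
  if (nrow(table) == 0L) stop("'table' is empty")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly inside (0, 1)")
  cls <- unique(table$class)
  if (any(table(table$class) == 0L) || length(cls) < 2L)
    stop("both lesion classes must be present to split")
  with_seed(seed, {
    in_train <- logical(nrow(table))
    for (cl in sort(cls)) {
      idx <- which(table$class == cl)
      n_train <- as.integer(ceiling(length(idx) * fraction))
      in_train[sample(idx, n_train)] <- TRUE
    }
    structure(list(train = table[in_train, , drop = FALSE],
                   test = table[!in_train, , drop = FALSE],
                   fraction = fraction, seed = as.integer(seed)),
              class = "prl_split")
  })
}

#' @export
print.prl_split <- function(x, ...) {
  tr <- table(x$train$class); te <- table(x$test$class)
  cat(sprintf("<prl_split> fraction %.2f, seed %d\n  train: %s\n  test:  %s\n",
              x$fraction, x$seed,
              paste(sprintf("%s %d", names(tr), as.integer(tr)), collapse = ", "),
              paste(sprintf("%s %d", names(te), as.integer(te)), collapse = ", ")))
  invisible(x)
}

# sensitivity/specificity of the rule "positive iff p5 < cutoff" at every
# candidate cutoff
roc_points <- function(p5, is_pos, cutoffs) {
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  t(vapply(cutoffs, function(cc) {
    pred <- p5 < cc
    c(sensitivity = sum(pred & is_pos) / npos,
      specificity = sum(!pred & !is_pos) / nneg)
  }, c(sensitivity = 0, specificity = 0)))
}

#' Fit the specificity-constrained p5 cutoff classifier
#'
#' The single-variable lesion classifier: predict PRL iff the lesion's
#' p5 pre-contrast intensity falls strictly below a cutoff. Candidate
#' cutoffs are the midpoints between consecutive sorted unique p5 values
#' (plus sentinels beyond the extremes); among candidates whose training
#' specificity meets the constraint, the one with maximal sensitivity is
#' chosen, ties resolved towards higher specificity and then the lower
#' cutoff. Specificity is constrained rather than balanced because PRLs
#' are rare: a small specificity loss floods the positives with false
#' calls.
#'
#' @param train training lesion table (`class`, `p5_t1pre` columns), both
#'   classes present.
#' @param spec_constraint minimum training specificity in (0, 1]; default
#'   0.95.
#' @param positive label of the positive class; default `"PRL"`.
#' @return object of class `p5_cutoff` with elements `cutoff`, `direction`
#'   (`"below"`), `spec_constraint`, `train_sensitivity`,
#'   `train_specificity`, `positive`, and the training ROC surface `roc`.
#' @export
select_cutoff <- function(train, spec_constraint = 0.95, positive = "PRL") {
  if (spec_constraint <= 0 || spec_constraint > 1)
    stop("'spec_constraint' must lie in (0, 1]")
  is_pos <- train$class == positive
  if (!any(is_pos) || all(is_pos))
    stop("training data must contain both classes")
  p5 <- train$p5_t1pre
  u <- sort(unique(p5))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  rp <- roc_points(p5, is_pos, cand)
  feasible <- rp[, "specificity"] >= spec_constraint
  if (!any(feasible))
    stop("no cutoff attains training specificity >= ", spec_constraint,
         "; lower the constraint")
  idx <- which(feasible)
  best <- idx[order(-rp[idx, "sensitivity"], -rp[idx, "specificity"],
                    cand[idx])][1]
  cutoff <- cand[best]
  # sentinels induce the same decision rule as a finite cutoff just outside
  # the observed range; keep the stored cutoff finite
  if (cutoff == -Inf) cutoff <- u[1] - 1
  if (cutoff == Inf) cutoff <- u[length(u)] + 1
  structure(list(cutoff = cutoff, direction = "below",
                 spec_constraint = spec_constraint,
                 train_sensitivity = unname(rp[best, "sensitivity"]),
                 train_specificity = unname(rp[best, "specificity"]),
                 positive = positive,
                 roc = data.frame(cutoff = cand,
                                  sensitivity = rp[, "sensitivity"],
                                  specificity = rp[, "specificity"]),
                 n_train = nrow(train)),
            class = "p5_cutoff")
}

#' @export
print.p5_cutoff <- function(x, ...) {
  cat(sprintf("<p5_cutoff> predict %s iff p5 < %.4g (training sens %.3f, spec %.3f >= %.2f)\n",
              x$positive, x$cutoff, x$train_sensitivity,
              x$train_specificity, x$spec_constraint))
  invisible(x)
}

#' @export
summary.p5_cutoff <- function(object, ...) {
  print(object)
  cat(sprintf("  fitted on %d lesions; %d candidate cutoffs, %d meeting the constraint\n",
              object$n_train, nrow(object$roc),
              sum(object$roc$specificity >= object$spec_constraint)))
  invisible(object)
}

#' @export
coef.p5_cutoff <- function(object, ...) {
  c(cutoff = object$cutoff)
}

#' @export
plot.p5_cutoff <- function(x, ...) {
  graphics::plot(1 - x$roc$specificity, x$roc$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "training ROC", ...)
  graphics::abline(v = 1 - x$spec_constraint, lty = 2, col = "grey40")
  sel <- which.min(abs(x$roc$cutoff - x$cutoff))
  graphics::points(1 - x$roc$specificity[sel], x$roc$sensitivity[sel],
                   pch = 19, col = "firebrick")
  invisible(x)
}

#' Predict lesion classes from a fitted cutoff
#'
#' A lesion with p5 exactly equal to the cutoff predicts negative: the rule
#' is strictly below-threshold.
#'
#' @param object a fitted `p5_cutoff`.
#' @param newdata a lesion table with a `p5_t1pre` column, or a bare
#'   numeric vector of p5 values.
#' @param type `"class"` for labels, `"logical"` for a positive indicator.
#' @param ... unused.
#' @return character labels or logical vector.
#' @export
predict.p5_cutoff <- function(object, newdata, type = c("class", "logical"),
                              ...) {
  type <- match.arg(type)
  p5 <- if (is.numeric(newdata)) newdata else newdata$p5_t1pre
  pos <- p5 < object$cutoff
  if (type == "logical") pos
  else ifelse(pos, object$positive, paste0("non-", object$positive))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value sums the probabilities of all tables with the same
#' margins whose hypergeometric probability does not exceed the observed
#' table's.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts with a
#'   positive grand total.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("grand total must be positive")
  stats::fisher.test(m)$p.value
}

#' Evaluate a fitted cutoff on a test set
#'
#' Confusion counts and the derived metrics, plus Fisher's exact test on
#' the confusion matrix. Metrics with zero denominators are returned as
#' `NaN` and named in `undefined` rather than silently coerced to 0.
#'
#' @param test test lesion table.
#' @param model a fitted `p5_cutoff`.
#' @return object of class `confusion_metrics`: counts `tp`, `fn`, `fp`,
#'   `tn`; proportions `sensitivity`, `specificity`, `ppv`, `npv`, `f1`;
#'   `fisher_p`; and `undefined`, a character vector naming any metrics
#'   with empty denominators.
#' @export
evaluate <- function(test, model) {
  stopifnot(inherits(model, "p5_cutoff"))
  if (nrow(test) == 0L) stop("'test' is empty")
  truth <- test$class == model$positive
  pred <- predict(model, test, type = "logical")
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  safe <- function(num, den) if (den == 0) NaN else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp)
  npv <- safe(tn, tn + fn)
  f1 <- if (is.nan(ppv) || is.nan(sens) || ppv + sens == 0) NaN
        else 2 * ppv * sens / (ppv + sens)
  vals <- c(sensitivity = sens, specificity = spec, ppv = ppv,
            npv = npv, f1 = f1)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1,
                 fisher_p = fisher_exact(matrix(c(tp, fn, fp, tn), 2L)),
                 undefined = names(vals)[is.nan(vals)]),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("<confusion_metrics> tp %d, fn %d, fp %d, tn %d\n",
              x$tp, x$fn, x$fp, x$tn))
  fmt <- function(v) if (is.nan(v)) "undefined" else
    format(round_half_up(v, digits), nsmall = digits)
  cat(sprintf("  sensitivity %s, specificity %s, ppv %s, npv %s, f1 %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv), fmt(x$f1)))
  cat(sprintf("  Fisher exact p = %.3g\n", x$fisher_p))
  invisible(x)
}
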