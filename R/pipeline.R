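#' Pipeline run configuration
#'
#' Bundles every stage's settings into one reproducible configuration.
#' Exactly one input source must be given: a [phantom_spec()] (synthetic
#' run) or a named list of NIfTI `paths` with elements `t1_pre`, `t1_post`,
#' `total_lesion_mask`, `prl_mask` (real co-registered inputs; probability
#' lesion maps are binarized at `binarize_threshold`). The global `seed`
#' propagates to every stochastic stage: the phantom generator uses `seed`
#' and the train/test split uses `seed + 1`.
#'
#' @param phantom a [phantom_spec()], or `NULL` when reading from files.
#' @param paths named list of four NIfTI paths, or `NULL`.
#' @param percentiles,scale_range normalization template settings.
#' @param filter a [filter_spec()].
#' @param bin_width,smooth_window,deep_cutoff histogram-analysis settings.
#' @param fraction,spec_constraint classifier settings.
#' @param connectivity connected-component connectivity (6, 18 or 26).
#' @param binarize_threshold lower threshold applied to non-binary lesion
#'   maps read from disk.
#' @param seed global integer seed.
#' @param out_dir directory for artifacts, or `NULL` to skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), paths = NULL,
                       percentiles = c(1, seq(10, 90, by = 10), 99),
                       scale_range = c(0, 100),
                       filter = filter_spec(),
                       bin_width = 0.1, smooth_window = 5, deep_cutoff = 25,
                       fraction = 0.5, spec_constraint = 0.95,
                       connectivity = 26, binarize_threshold = 0.5,
                       seed = 1L, out_dir = NULL) {
  if (is.null(phantom) == is.null(paths))
    stop("exactly one input source must be set: 'phantom' or 'paths'")
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  if (!is.null(paths)) {
    need <- c("t1_pre", "t1_post", "total_lesion_mask", "prl_mask")
    if (!all(need %in% names(paths)))
      stop("'paths' must name: ", paste(need, collapse = ", "))
  }
  structure(list(phantom = phantom, paths = paths,
                 percentiles = percentiles, scale_range = scale_range,
                 filter = filter, bin_width = bin_width,
                 smooth_window = smooth_window, deep_cutoff = deep_cutoff,
                 fraction = fraction, spec_constraint = spec_constraint,
                 connectivity = connectivity,
                 binarize_threshold = binarize_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 15,
                           force = TRUE, null = "null"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in workflow order: input acquisition (phantom
#' generation or NIfTI loading), intensity normalization of the pre- and
#' post-contrast volumes with self-trained standard-scale templates, PRL
#' subtraction and connected-component isolation, per-lesion feature
#' extraction, exclusion filtering, voxel-wise group histogram analysis,
#' lesion-wise rank-sum contrast of the p5 intensities, and the
#' specificity-constrained cutoff classifier with test-set evaluation.
#'
#' With `out_dir` set, normalized volumes, the lesion table, the group
#' histograms, a JSON report and a run log are written there. The report
#' carries no timestamps, so identical configurations reproduce
#' byte-identical reports.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress to stderr.
#' @return object of class `prl_report` (see the elements in the vignette).
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage input")
  inp <- stage("input", {
    if (!is.null(config$phantom)) {
      spec <- config$phantom
      spec$seed <- config$seed
      ph <- generate_phantom(spec)
      list(t1_pre = ph$t1_pre, t1_post = ph$t1_post,
           total = ph$total_lesion_mask, prl = ph$prl_mask,
           truth = ph$truth)
    } else {
      total <- read_volume(config$paths$total_lesion_mask)
      prl <- read_volume(config$paths$prl_mask)
      if (!is_binary(total)) total <- binarize(total, config$binarize_threshold)
      if (!is_binary(prl)) prl <- binarize(prl, config$binarize_threshold)
      list(t1_pre = read_volume(config$paths$t1_pre),
           t1_post = read_volume(config$paths$t1_post),
           total = total, prl = prl, truth = NULL)
    }
  })
  stage("input", check_compatible(t1_pre = inp$t1_pre, t1_post = inp$t1_post,
                                  total_lesion_mask = inp$total,
                                  prl_mask = inp$prl))

  say("stage normalize")
  norm <- stage("normalize", {
    tpl_pre <- train_template(inp$t1_pre, percentiles = config$percentiles,
                              scale_range = config$scale_range,
                              contrast_tag = "pre")
    tpl_post <- train_template(inp$t1_post, percentiles = config$percentiles,
                               scale_range = config$scale_range,
                               contrast_tag = "post")
    list(tpl_pre = tpl_pre, tpl_post = tpl_post,
         t1_pre = apply_template(inp$t1_pre, template = tpl_pre),
         t1_post = apply_template(inp$t1_post, template = tpl_post))
  })

  say("stage lesions")
  les <- stage("lesions", {
    npr_mask <- subtract_prl(inp$total, inp$prl)
    lab_prl <- label_components(inp$prl, config$connectivity)
    lab_npr <- label_components(npr_mask, config$connectivity)
    feats_prl <- extract_features(lab_prl, "PRL", norm$t1_pre, norm$t1_post)
    feats_npr <- extract_features(lab_npr, "nPR-WML", norm$t1_pre, norm$t1_post)
    feats_npr$lesion_id <- feats_npr$lesion_id + max(0L, lab_prl$n)
    tab <- rbind(feats_prl, feats_npr)
    filt <- filter_lesions(tab, config$filter)
    list(npr_mask = npr_mask, n_prl = lab_prl$n, n_npr = lab_npr$n,
         table = tab, kept = filt$kept, removed_counts = filt$removed_counts)
  })

  say("stage groupstats")
  grp <- stage("groupstats", {
    prl_vox <- norm$t1_pre$data[inp$prl$data != 0]
    npr_vox <- norm$t1_pre$data[les$npr_mask$data != 0]
    summ_prl <- summarize_group(prl_vox, config$bin_width,
                                config$smooth_window, config$deep_cutoff,
                                group = "PRL")
    summ_npr <- summarize_group(npr_vox, config$bin_width,
                                config$smooth_window, config$deep_cutoff,
                                group = "nPR-WML")
    wt <- wilcoxon_rank_sum(les$kept$p5_t1pre[les$kept$class == "PRL"],
                            les$kept$p5_t1pre[les$kept$class == "nPR-WML"])
    list(prl = summ_prl, npr = summ_npr, wilcoxon = wt)
  })

  say("stage classify")
  clf <- stage("classify", {
    split <- stratified_split(les$kept, config$fraction, config$seed + 1L)
    model <- select_cutoff(split$train, config$spec_constraint)
    metrics <- evaluate(split$test, model)
    list(split = split, model = model, metrics = metrics)
  })

  report <- structure(list(
    config = config,
    config_hash = config_hash(config),
    counts = list(
      planted = if (is.null(inp$truth)) NULL else table(inp$truth$class),
      components_prl = les$n_prl, components_npr = les$n_npr,
      lesions_before_filter = nrow(les$table),
      lesions_after_filter = nrow(les$kept),
      removed = les$removed_counts),
    templates = list(pre = norm$tpl_pre, post = norm$tpl_post),
    lesion_table = les$kept,
    group_summary = list(PRL = grp$prl, `nPR-WML` = grp$npr),
    wilcoxon_p5 = grp$wilcoxon,
    split = clf$split,
    model = clf$model,
    metrics = clf$metrics,
    truth = inp$truth), class = "prl_report")

  if (!is.null(config$out_dir)) {
    say("stage write")
    stage("write", write_report_artifacts(report, norm, config$out_dir))
  }
  report
}

write_report_artifacts <- function(report, norm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(norm$t1_pre, file.path(dir, "t1_pre_normalized.nii.gz"))
  write_volume(norm$t1_post, file.path(dir, "t1_post_normalized.nii.gz"))
  save_template(report$templates$pre, file.path(dir, "template_pre.txt"))
  save_template(report$templates$post, file.path(dir, "template_post.txt"))
  write_lesion_table(report$lesion_table, file.path(dir, "lesion_table.tsv"))
  write_histogram(report$group_summary$PRL$histogram,
                  file.path(dir, "histogram_prl.tsv"))
  write_histogram(report$group_summary$`nPR-WML`$histogram,
                  file.path(dir, "histogram_nprwml.tsv"))
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("rimsift %s", as.character(utils::packageVersion("rimsift"))),
               sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("config_hash %s", report$config_hash),
               sprintf("removed too_small %d",
                       report$counts$removed[["too_small"]]),
               sprintf("removed enhancing %d",
                       report$counts$removed[["enhancing"]])),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

# plain-list rendering of a report for JSON serialization
report_as_list <- function(report) {
  m <- report$metrics
  list(
    config_hash = report$config_hash,
    seed = report$config$seed,
    counts = list(components_prl = report$counts$components_prl,
                  components_npr = report$counts$components_npr,
                  before_filter = report$counts$lesions_before_filter,
                  after_filter = report$counts$lesions_after_filter,
                  removed_too_small = report$counts$removed[["too_small"]],
                  removed_enhancing = report$counts$removed[["enhancing"]]),
    group_summary = lapply(report$group_summary, function(s)
      list(n_modes = s$n_modes, mode_locations = s$mode_locations,
           intermode_minimum = s$intermode_minimum,
           deep_cutoff = s$deep_cutoff, deep_fraction = s$deep_fraction,
           n_voxels = s$histogram$n)),
    wilcoxon_p5 = list(statistic = report$wilcoxon_p5$statistic,
                       p = report$wilcoxon_p5$p.value),
    split = list(train = as.list(table(report$split$train$class)),
                 test = as.list(table(report$split$test$class))),
    cutoff = report$model$cutoff,
    train_sensitivity = report$model$train_sensitivity,
    train_specificity = report$model$train_specificity,
    test_metrics = list(tp = m$tp, fn = m$fn, fp = m$fp, tn = m$tn,
                        sensitivity = m$sensitivity,
                        specificity = m$specificity,
                        ppv = m$ppv, npv = m$npv, f1 = m$f1,
                        fisher_p = m$fisher_p))
}

#' @export
print.prl_report <- function(x, ...) {
  cat(sprintf("<prl_report> config %s, seed %d\n", x$config_hash, x$config$seed))
  cat(sprintf("  lesions: %d PRL + %d nPR-WML components; %d kept after filters (%d too small, %d enhancing)\n",
              x$counts$components_prl, x$counts$components_npr,
              x$counts$lesions_after_filter,
              x$counts$removed[["too_small"]],
              x$counts$removed[["enhancing"]]))
  cat(sprintf("  voxel-wise: PRL %s (modes %s), nPR-WML %s (mode %s); deep fractions %.3f / %.4f below %g\n",
              if (x$group_summary$PRL$n_modes == 2) "bimodal" else "unimodal",
              paste(format(x$group_summary$PRL$mode_locations, digits = 3),
                    collapse = ", "),
              if (x$group_summary$`nPR-WML`$n_modes == 2) "bimodal" else "unimodal",
              paste(format(x$group_summary$`nPR-WML`$mode_locations, digits = 3),
                    collapse = ", "),
              x$group_summary$PRL$deep_fraction,
              x$group_summary$`nPR-WML`$deep_fraction,
              x$group_summary$PRL$deep_cutoff))
  cat(sprintf("  p5 rank-sum p = %.3g\n", x$wilcoxon_p5$p.value))
  print(x$model)
  print(x$metrics)
  invisible(x)
}

#' @export
summary.prl_report <- function(object, ...) {
  print(object)
  cat("\nLesion table head:\n")
  print(utils::head(object$lesion_table))
  invisible(object)
}
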