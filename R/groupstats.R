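#' Percentage histogram of a voxel group
#'
#' Uniform-width half-open bins starting at `floor(min)` and covering every
#' value up to the maximum, with bar heights
#' expressed as the percentage of the group's voxels rather than raw
#' frequency, so groups of very different size (PRL vs nPR-WML voxels)
#' overlay on comparable axes.
#'
#' @param values nonempty numeric vector of voxel intensities.
#' @param bin_width positive bin width (default 0.1, fine enough to resolve
#'   mode locations to one decimal).
#' @param group optional group label carried along for printing/plotting.
#' @return object of class `group_histogram`: `bin_edges`, `bin_centers`,
#'   `heights` (percent), `counts`, `n`, `group`.
#' @export
group_histogram <- function(values, bin_width = 0.1, group = NULL) {
  if (length(values) == 0L) stop("'values' must be nonempty")
  if (!is.finite(bin_width) || bin_width <= 0) stop("'bin_width' must be positive")
  lo <- floor(min(values))
  # enough half-open [edge, edge + width) bins to hold the maximum value
  nbins <- as.integer(floor((max(values) - lo) / bin_width + 1e-9)) + 1L
  edges <- lo + (0:nbins) * bin_width
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nbins] <- nbins
  counts <- tabulate(idx, nbins)
  structure(list(bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_width / 2,
                 heights = counts * 100 / length(values),
                 counts = counts, n = length(values), group = group),
            class = "group_histogram")
}

#' @export
print.group_histogram <- function(x, ...) {
  cat(sprintf("<group_histogram>%s %d voxels in %d bins of width %g over [%g, %g]\n",
              if (is.null(x$group)) "" else paste0(" ", x$group, ":"),
              x$n, length(x$heights),
              diff(x$bin_edges[1:2]), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.group_histogram <- function(x, col = "steelblue", ...) {
  graphics::plot(x$bin_centers, x$heights, type = "h", col = col,
                 xlab = "normalized intensity", ylab = "% of group voxels",
                 main = x$group, ...)
  invisible(x)
}

#' Export a histogram as tab-delimited text
#'
#' @param hist a [group_histogram()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(data.frame(bin_center = hist$bin_centers,
                                percent = hist$heights),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# moving-average smoothing with shrinking windows at the edges
smooth_heights <- function(h, window) {
  if (window == 1L) return(h)
  half <- (window - 1L) %/% 2L
  n <- length(h)
  cs <- cumsum(c(0, h))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect histogram modes and the inter-mode minimum
#'
#' Smooths the percentage histogram with a centred moving average, finds
#' local maxima (plateaus collapse to their lowest-intensity bin), and
#' retains the tallest one or two as modes. A second mode is reported only
#' if it is separated from the first by an inclusive span of at least
#' `min_separation` bins, reaches at least `min_mode_frac` of the primary
#' mode's smoothed height (so isolated sampling spikes in sparse tails do
#' not count), and the smoothed valley between the two drops below
#' `prominence` times the smaller mode's height — otherwise the
#' histogram is called unimodal. Ties on height resolve to the lower
#' intensity. For a bimodal result the inter-mode minimum is the bin centre
#' of the lowest smoothed height strictly between the two mode bins.
#'
#' @param hist a [group_histogram()] with at least 3 bins.
#' @param smooth_window odd moving-average window length (>= 1); default 5.
#' @param min_separation minimum inclusive bin span between the two mode
#'   bins; default 5 (mode bins at least 4 indices apart).
#' @param prominence valley-depth factor in (0, 1] deciding bimodality;
#'   default 0.5.
#' @param min_mode_frac minimum height of a second mode as a fraction of
#'   the primary mode's; default 0.05.
#' @return list with `mode_locations` (ascending intensities),
#'   `mode_heights` (smoothed percent at the modes, same order),
#'   `n_modes` (1 or 2) and `intermode_minimum` (`NA` if unimodal).
#' @export
detect_modes <- function(hist, smooth_window = 5, min_separation = 5,
                         prominence = 0.5, min_mode_frac = 0.05) {
  stopifnot(inherits(hist, "group_histogram"))
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("'smooth_window' must be odd and >= 1")
  h <- hist$heights
  nb <- length(h)
  if (nb < 3L) stop("need at least 3 bins to detect modes")
  sm <- smooth_heights(h, as.integer(smooth_window))
  left <- c(-Inf, sm[-nb])
  right <- c(sm[-1], -Inf)
  cand <- which(sm >= left & sm >= right & (sm > left | sm > right))
  # collapse plateau runs to their first (lowest-intensity) bin
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, !(diff(cand) == 1L & diff(sm[cand]) == 0))]
  if (length(cand) == 0L) cand <- which.max(sm)
  ord <- cand[order(-sm[cand], cand)]
  i1 <- ord[1]
  second <- NA_integer_
  for (j in ord[-1]) {
    if (sm[j] < min_mode_frac * sm[i1]) break
    if (abs(j - i1) + 1L < min_separation) next
    lo <- min(i1, j); hi <- max(i1, j)
    if (hi - lo < 2L) next
    valley <- min(sm[(lo + 1L):(hi - 1L)])
    if (valley <= prominence * sm[j]) {
      second <- j
      break
    }
  }
  centers <- hist$bin_centers
  if (is.na(second)) {
    list(mode_locations = centers[i1], mode_heights = sm[i1],
         n_modes = 1L, intermode_minimum = NA_real_)
  } else {
    lo <- min(i1, second); hi <- max(i1, second)
    between <- (lo + 1L):(hi - 1L)
    vmin <- between[which.min(sm[between])]
    modes <- sort(c(i1, second))
    list(mode_locations = centers[modes], mode_heights = sm[modes],
         n_modes = 2L, intermode_minimum = centers[vmin])
  }
}

#' Fraction of voxels in the deeply hypointense segment
#'
#' Strictly-below fraction: `mean(values < cutoff)`.
#'
#' @param values nonempty numeric vector.
#' @param cutoff intensity cutoff (25 separates the two PRL modes on the
#'   standard 0-100 scale).
#' @return fraction in `[0, 1]`.
#' @export
deep_fraction <- function(values, cutoff) {
  if (length(values) == 0L) stop("'values' must be nonempty")
  mean(values < cutoff)
}

#' Voxel-wise group summary
#'
#' Convenience wrapper assembling the percentage histogram, detected modes,
#' inter-mode minimum and deep-voxel fraction for one voxel group.
#'
#' @param values voxel intensities of the group.
#' @param bin_width,smooth_window passed to [group_histogram()] and
#'   [detect_modes()].
#' @param deep_cutoff threshold for [deep_fraction()]; default 25.
#' @param group optional group label.
#' @return object of class `bimodal_summary`.
#' @export
summarize_group <- function(values, bin_width = 0.1, smooth_window = 5,
                            deep_cutoff = 25, group = NULL) {
  hist <- group_histogram(values, bin_width, group = group)
  modes <- detect_modes(hist, smooth_window)
  structure(c(modes,
              list(deep_cutoff = deep_cutoff,
                   deep_fraction = deep_fraction(values, deep_cutoff),
                   histogram = hist, group = group)),
            class = "bimodal_summary")
}

#' @export
print.bimodal_summary <- function(x, ...) {
  cat(sprintf("<bimodal_summary>%s %s with mode(s) at %s",
              if (is.null(x$group)) "" else paste0(" ", x$group, ":"),
              if (x$n_modes == 2L) "bimodal" else "unimodal",
              paste(format(x$mode_locations, digits = 3), collapse = ", ")))
  if (x$n_modes == 2L)
    cat(sprintf("; inter-mode minimum at %s",
                format(x$intermode_minimum, digits = 3)))
  cat(sprintf("\n  %.2f%% of voxels below intensity %g\n",
              100 * x$deep_fraction, x$deep_cutoff))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The null distribution is
#' exact (full enumeration of rank assignments, via the Mann-Whitney
#' distribution) when the combined sample size is at most 20 and there are
#' no ties; otherwise a normal approximation with tie correction and no
#' continuity correction is used, so identical samples yield p = 1.
#'
#' @param x,y nonempty numeric samples.
#' @return list with `statistic` (rank sum of `x`), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (m + n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && m + n <= 20L) {
    U <- W - m * (m + 1) / 2
    p <- 2 * min(stats::pwilcox(U, m, n),
                 1 - stats::pwilcox(U - 1, m, n))
    list(statistic = W, p.value = min(1, p), method = "exact")
  } else {
    nt <- table(r)
    sigma2 <- m * n / 12 *
      ((m + n + 1) - sum(nt^3 - nt) / ((m + n) * (m + n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (W - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    list(statistic = W, p.value = min(1, p), method = "normal")
  }
}
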