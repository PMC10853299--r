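# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (sorting, flood fill, exhaustive enumeration) kept free of
# the package's own code paths.

# small phantom spec used by most unit tests
small_spec <- function(seed = 42L, ...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), n_nprwml = 20L, n_prl = 6L,
               n_enhancing = 2L, n_tiny = 3L,
               lesion_radius_range_mm = c(1, 2.5), seed = seed, ...)
}

# sort-based percentile oracle: index (n-1)*p/100, linear interpolation
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# stack-based flood fill, one component at a time, explicit coordinate
# arithmetic (no padding, no vectorized frontier)
oracle_label <- function(mask_array, connectivity = 26) {
  d <- dim(mask_array)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- switch(as.character(connectivity),
              "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
              "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
              "26" = g)
  lab <- array(0L, d)
  k <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (mask_array[x, y, z] == 0 || lab[x, y, z] > 0L) next
    k <- k + 1L
    stack <- list(c(x, y, z))
    lab[x, y, z] <- k
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(g))) {
        w <- v + g[r, ]
        if (any(w < 1L) || any(w > d)) next
        if (mask_array[w[1], w[2], w[3]] != 0 && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- k
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# partitions agree up to label renaming
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- which(a > 0)
  if (length(fg) == 0) return(TRUE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# exhaustive cutoff-selection oracle: try every candidate midpoint, apply
# the constraint and tie-break rules literally
oracle_select_cutoff <- function(p5, is_pos, spec_constraint) {
  u <- sort(unique(p5))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (cc in cand) {
    pred <- p5 < cc
    sens <- sum(pred & is_pos) / sum(is_pos)
    spec <- sum(!pred & !is_pos) / sum(!is_pos)
    if (spec < spec_constraint) next
    if (is.null(best) || sens > best$sens + 1e-12 ||
        (abs(sens - best$sens) <= 1e-12 && spec > best$spec + 1e-12) ||
        (abs(sens - best$sens) <= 1e-12 && abs(spec - best$spec) <= 1e-12 &&
         cc < best$cutoff)) {
      best <- list(cutoff = cc, sens = sens, spec = spec)
    }
  }
  best
}

# hypergeometric enumeration oracle for the two-sided Fisher exact test
oracle_fisher <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  if (n == 0) stop("empty table")
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(k)
    stats::dhyper(k, c1, n - c1, r1), 0)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# full enumeration oracle for the two-sided rank-sum test (no ties)
oracle_wilcoxon <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  combos <- utils::combn(m + n, m)
  sums <- colSums(matrix(seq_len(m + n)[combos], nrow = m))
  mu <- m * (m + n + 1) / 2
  p_lo <- mean(sums <= W)
  p_hi <- mean(sums >= W)
  min(1, 2 * min(p_lo, p_hi))
}

# direct per-voxel piecewise-linear interpolation oracle
oracle_map <- function(x, xk, yk) {
  K <- length(xk)
  vapply(x, function(v) {
    if (v <= xk[1]) {
      yk[1] + (v - xk[1]) * (yk[2] - yk[1]) / (xk[2] - xk[1])
    } else if (v >= xk[K]) {
      yk[K] + (v - xk[K]) * (yk[K] - yk[K - 1]) / (xk[K] - xk[K - 1])
    } else {
      j <- max(which(xk <= v))
      yk[j] + (v - xk[j]) * (yk[j + 1] - yk[j]) / (xk[j + 1] - xk[j])
    }
  }, 0)
}

# random binary mask as an mri_volume
random_mask <- function(dims, p = 0.3, voxel_size = 0.5) {
  volume(array(as.numeric(stats::runif(prod(dims)) < p), dims), voxel_size)
}
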