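#' Percentile landmark estimator
#'
#' The single percentile estimator used throughout the package: linear
#' interpolation between closest order statistics at index `(n-1)*p/100`
#' (the classical type-7 sample quantile). Pinning one estimator keeps the
#' normalization landmarks, the per-lesion p5 feature and every test oracle
#' bit-comparable.
#'
#' @param x numeric vector of finite values.
#' @param p percentile ranks in `[0, 100]` (note: percent, not probability).
#' @return numeric vector of the same length as `p`.
#' @export
#' @examples
#' landmark_quantile(0:99, 5) # 4.95
landmark_quantile <- function(x, p) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("'x' must be a nonempty numeric vector")
  if (any(!is.finite(x)))
    stop("'x' contains non-finite values")
  if (any(p < 0 | p > 100))
    stop("percentile ranks must lie in [0, 100]")
  as.numeric(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how the
#' classification metrics are conventionally printed (0.3125 -> 0.313 at
#' three decimals, unlike banker's rounding).
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library functions never clobber user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a hash of a string, returned as 8 hex digits. Used to stamp a
# run configuration into reports; arithmetic split to stay exact in doubles.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31) , as.integer(b)) + (h %/% 2^31) * 2^31
    # multiply by 16777619 mod 2^32 without losing precision
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- (lo * 16777619 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}
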