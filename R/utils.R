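# Internal numeric helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used wherever a sub-pixel centroid must be mapped
#' to a pixel index (base `round()` rounds half to even).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(m, r) {
  h <- nrow(m)
  w <- ncol(m)
  m[c(rep(1L, r), seq_len(h), rep(h, r)), c(rep(1L, r), seq_len(w), rep(w, r)),
    drop = FALSE]
}

# Separable 2-D convolution with an odd-length 1-D kernel applied along both
# axes. Edges are replicate-padded so the output has the same size as the
# input. Used by the band-pass filter in locate().
conv_sep <- function(m, k) {
  stopifnot(length(k) %% 2 == 1)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  h <- nrow(m)
  w <- ncol(m)
  p <- pad_replicate(m, r)
  # stats::filter operates column-wise on matrices
  p <- stats::filter(p, k, sides = 2)
  p <- t(stats::filter(t(p), k, sides = 2))
  out <- p[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE]
  matrix(as.numeric(out), h, w)
}

gaussian_kernel <- function(sd, radius = ceiling(2 * sd)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

boxcar_kernel <- function(width) {
  rep(1 / width, width)
}

# Grayscale maximum filter over a (2r+1) x (2r+1) square window, computed by
# running shifted pmax passes along rows then columns (edges replicate).
max_filter <- function(m, r) {
  h <- nrow(m)
  w <- ncol(m)
  out <- m
  for (s in seq_len(r)) {
    up <- m[c(rep(1L, s), seq_len(h - s)), , drop = FALSE]
    dn <- m[c(seq_len(h - s) + s, rep(h, s)), , drop = FALSE]
    out <- pmax(out, up, dn)
  }
  m2 <- out
  for (s in seq_len(r)) {
    lf <- m2[, c(rep(1L, s), seq_len(w - s)), drop = FALSE]
    rt <- m2[, c(seq_len(w - s) + s, rep(w, s)), drop = FALSE]
    out <- pmax(out, lf, rt)
  }
  out
}

# stop() with a condition class so callers can distinguish capability errors
# (missing optional backend) from programming errors.
stop_capability <- function(msg) {
  stop(errorCondition(msg, class = c("fluortrack_capability_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
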