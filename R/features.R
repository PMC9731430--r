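#' Peak (transient) detection parameters
#'
#' A calcium transient is a local maximum with topographic prominence of at
#' least `min_prominence` whose half-prominence width (frames) divided by
#' its prominence does not exceed `max_width_prominence_ratio`; the ratio
#' filter rejects extremely broad humps that are not transients. Parameters
#' are fixed in configuration, never tuned per trace, so one calibration
#' carries over to subsequent data sets.
#'
#' @param min_prominence minimum topographic prominence, a.u.
#' @param max_width_prominence_ratio maximum half-prominence width divided by
#'   prominence (frames per a.u.)
#' @return object of class `peak_params`
#' @export
peak_params <- function(min_prominence = 3, max_width_prominence_ratio = 10) {
  stopifnot(min_prominence > 0, max_width_prominence_ratio > 0)
  structure(list(min_prominence = min_prominence,
                 max_width_prominence_ratio = max_width_prominence_ratio),
            class = "peak_params")
}

#' Changepoint (step) detection parameters
#'
#' Steps in a trace are found by penalized piecewise-linear segmentation;
#' the `penalty` (residual sum-of-squares units) is calibrated once on
#' synthetic step traces so a single ideal step yields at most two
#' changepoints (the two corners of the smoothed ramp). Changepoints whose
#' bracketing fitted segments have nearly equal slopes are removed — they
#' reflect baseline drift, not steps.
#'
#' @param penalty per-changepoint penalty added to the residual sum of
#'   squares
#' @param max_changepoints_per_step expected changepoints per intensity step
#'   (documentation of the calibration target; not enforced per step)
#' @param min_slope_difference minimum |post - pre| fitted slope difference,
#'   a.u./frame, below which a changepoint looks like drift
#' @param min_level_difference minimum fitted-level jump (a.u.) at the
#'   junction; a changepoint is dropped as baseline drift only when both the
#'   slope difference and the level jump are small (an instantaneous level
#'   shift has equal slopes on both sides but is a real step)
#' @param min_segment_length minimum segment length, frames
#' @return object of class `step_params`
#' @export
step_params <- function(penalty = 50, max_changepoints_per_step = 2,
                        min_slope_difference = 0.1,
                        min_level_difference = 2,
                        min_segment_length = 10) {
  stopifnot(penalty > 0, max_changepoints_per_step > 0,
            min_slope_difference > 0, min_level_difference > 0,
            min_segment_length >= 2)
  structure(list(penalty = penalty,
                 max_changepoints_per_step = as.integer(max_changepoints_per_step),
                 min_slope_difference = min_slope_difference,
                 min_level_difference = min_level_difference,
                 min_segment_length = as.integer(min_segment_length)),
            class = "step_params")
}

# Local maxima of a numeric vector with plateau handling: a candidate is the
# middle sample of a maximal run of equal values that is higher than both
# neighboring runs. Returns 1-based indices.
local_maxima <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                     r$values[2:(k - 1)] > r$values[3:k], FALSE)
  idx <- which(is_max)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

#' Find transient peaks in a trace
#'
#' Locates local maxima, computes each one's topographic prominence (height
#' above the higher of the two flanking minima, where each flank extends to
#' the nearest sample higher than the peak or to the trace border) and its
#' width at half prominence (linear interpolation of the crossing points),
#' and keeps peaks passing the [peak_params()] filters.
#'
#' @param y finite numeric trace
#' @param params a [peak_params()] object
#' @return data.frame with columns `location` (0-based frame), `height`,
#'   `prominence`, `width` (frames), ordered by location
#' @export
find_transients <- function(y, params = peak_params()) {
  empty <- data.frame(location = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  n <- length(y)
  if (n < 3) return(empty)
  stopifnot(all(is.finite(y)))
  cand <- local_maxima(y)
  if (length(cand) == 0) return(empty)

  rows <- lapply(cand, function(i) {
    h <- y[i]
    # left flank: up to the nearest strictly higher sample (exclusive)
    left <- if (i == 1) integer(0) else seq_len(i - 1)
    higher <- left[y[left] > h]
    lb <- if (length(higher)) max(higher) + 1L else 1L
    min_l <- min(y[lb:i])
    right <- if (i == n) integer(0) else (i + 1):n
    higher <- right[y[right] > h]
    rb <- if (length(higher)) min(higher) - 1L else n
    min_r <- min(y[i:rb])
    prom <- h - max(min_l, min_r)
    if (prom < params$min_prominence) return(NULL)
    ref <- h - prom / 2
    # crossing points of the half-prominence level within the flanks
    jl <- max(which(y[lb:i] < ref)) + lb - 1L
    xl <- jl + (ref - y[jl]) / (y[jl + 1] - y[jl])
    jr <- min(which(y[i:rb] < ref)) + i - 1L
    xr <- jr - 1 + (ref - y[jr - 1]) / (y[jr] - y[jr - 1])
    width <- xr - xl
    if (width / prom > params$max_width_prominence_ratio) return(NULL)
    data.frame(location = i - 1L, height = h, prominence = prom,
               width = width)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$location), , drop = FALSE]
}

# SSE of an ordinary least-squares line fit on y[i..j] for a vector of
# start indices i (1-based, inclusive) and a fixed end j, in O(1) each via
# prefix sums. Pre-computed sums are passed in.
segment_sse <- function(ps, i, j) {
  m <- j - i + 1
  sx <- ps$cx[j + 1] - ps$cx[i]
  sy <- ps$cy[j + 1] - ps$cy[i]
  sxx <- ps$cxx[j + 1] - ps$cxx[i]
  sxy <- ps$cxy[j + 1] - ps$cxy[i]
  syy <- ps$cyy[j + 1] - ps$cyy[i]
  vxx <- sxx - sx^2 / m
  vxy <- sxy - sx * sy / m
  vyy <- syy - sy^2 / m
  sse <- vyy - ifelse(vxx > 0, vxy^2 / vxx, 0)
  pmax(sse, 0)
}

segment_slope <- function(ps, i, j) {
  m <- j - i + 1
  sx <- ps$cx[j + 1] - ps$cx[i]
  sy <- ps$cy[j + 1] - ps$cy[i]
  sxx <- ps$cxx[j + 1] - ps$cxx[i]
  sxy <- ps$cxy[j + 1] - ps$cxy[i]
  vxx <- sxx - sx^2 / m
  vxy <- sxy - sx * sy / m
  if (vxx > 0) vxy / vxx else 0
}

# OLS prediction of segment y[i..j] (1-based) at 0-based frame x0
segment_predict <- function(ps, i, j, x0) {
  m <- j - i + 1
  xbar <- (ps$cx[j + 1] - ps$cx[i]) / m
  ybar <- (ps$cy[j + 1] - ps$cy[i]) / m
  b <- segment_slope(ps, i, j)
  ybar + b * (x0 - xbar)
}

prefix_sums <- function(y) {
  x <- seq_along(y) - 1
  list(cx = c(0, cumsum(x)), cy = c(0, cumsum(y)),
       cxx = c(0, cumsum(x^2)), cxy = c(0, cumsum(x * y)),
       cyy = c(0, cumsum(y^2)))
}

#' Find intensity steps (changepoints) in a trace
#'
#' Penalized least-squares segmentation into independent linear pieces
#' (optimal partitioning by dynamic programming): the trace is split at the
#' set of changepoints minimizing total squared residuals plus
#' `penalty * (number of changepoints)`, subject to `min_segment_length`.
#' Changepoints whose bracketing segments have fitted slopes closer than
#' `min_slope_difference` are then dropped (iteratively, weakest first,
#' re-fitting the merged segments), which separates true steps from
#' baseline drift. A single ideal intensity step yields one changepoint;
#' a smoothed (ramp-shaped) step yields two, one per ramp corner.
#'
#' @param y numeric trace of length >= `2 * min_segment_length`
#' @param params a [step_params()] object
#' @return data.frame with columns `index` (0-based frame at which a new
#'   segment starts), `pre_slope`, `post_slope` (a.u./frame), ordered by
#'   index
#' @export
find_steps <- function(y, params = step_params()) {
  empty <- data.frame(index = integer(0), pre_slope = numeric(0),
                      post_slope = numeric(0))
  n <- length(y)
  ms <- params$min_segment_length
  if (n < 2 * ms) return(empty)
  ps <- prefix_sums(y)
  beta <- params$penalty

  f <- rep(Inf, n + 1)
  f[1] <- -beta
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < ms) next
    taus <- 0:(j - ms)                     # last frame of previous segment
    taus <- taus[taus == 0 | taus >= ms]   # segments all >= min length
    if (length(taus) == 0) next
    costs <- f[taus + 1] + beta + segment_sse(ps, taus + 1, j)
    k <- which.min(costs)
    f[j + 1] <- costs[k]
    prev[j + 1] <- taus[k]
  }
  # backtrack segment boundaries
  bounds <- integer(0)
  j <- n
  while (j > 0) {
    tau <- prev[j + 1]
    bounds <- c(tau, bounds)
    j <- tau
  }
  cps <- bounds[bounds > 0]  # interior boundaries; new segment starts at cp
  if (length(cps) == 0) return(empty)

  # iterative drift filter: a changepoint whose bracketing fits continue each
  # other (similar slopes AND no level jump at the junction) is baseline
  # drift, not a step; drop the weakest, merge, re-fit, repeat
  repeat {
    starts <- c(1L, cps + 1L)
    ends <- c(cps, n)
    slopes <- mapply(function(i, j) segment_slope(ps, i, j), starts, ends)
    dslope <- abs(diff(slopes))
    djump <- vapply(seq_along(cps), function(k) {
      x0 <- cps[k] - 0.5  # 0-based junction between frames cps-1 and cps
      abs(segment_predict(ps, starts[k + 1], ends[k + 1], x0) -
          segment_predict(ps, starts[k], ends[k], x0))
    }, numeric(1))
    weak <- which(dslope < params$min_slope_difference &
                  djump < params$min_level_difference)
    if (length(weak) == 0 || length(cps) == 0) break
    score <- dslope[weak] / params$min_slope_difference +
      djump[weak] / params$min_level_difference
    cps <- cps[-weak[which.min(score)]]
    if (length(cps) == 0) return(empty)
  }
  starts <- c(1L, cps + 1L)
  ends <- c(cps, n)
  slopes <- mapply(function(i, j) segment_slope(ps, i, j), starts, ends)
  data.frame(index = as.integer(cps),  # 0-based: cps is 1-based last frame
             pre_slope = slopes[seq_along(cps)],
             post_slope = slopes[seq_along(cps) + 1])
}

#' Summary statistics of a trace
#'
#' Basic time-series statistics used by the behavior fingerprint: extrema,
#' location of the maximum, mean, variance, range, the mean restricted to
#' frames strictly after each requested frame, and the range restricted to
#' frames from the maximum onward.
#'
#' @param y non-empty numeric trace (frames 0, 1, ...)
#' @param after_frames 0-based frames `f` for which `mean(y[frame > f])` is
#'   reported
#' @return list with `min`, `max`, `argmax` (0-based), `mean`, `variance`
#'   (sample variance; 0 for length-1 traces), `range`, `mean_after` (named
#'   by frame; `NA` when no frames remain), `range_after_argmax`
#' @export
summarize_trace <- function(y, after_frames = 50) {
  n <- length(y)
  if (n == 0) stop("empty trace")
  am <- which.max(y)
  ma <- lapply(after_frames, function(f) {
    idx <- seq_len(n)[(seq_len(n) - 1) > f]
    if (length(idx) == 0) NA_real_ else mean(y[idx])
  })
  names(ma) <- as.character(after_frames)
  list(min = min(y), max = max(y), argmax = am - 1L, mean = mean(y),
       variance = if (n > 1) stats::var(y) else 0,
       range = max(y) - min(y),
       mean_after = ma,
       range_after_argmax = max(y[am:n]) - min(y[am:n]))
}

#' Behavior fingerprint of one cell
#'
#' Bundles everything the behavior classifier needs: per-channel summary
#' statistics, transient peaks on the green and blue channels, changepoints
#' on the blue and green channels, and the mean red-minus-blue difference.
#' Traces are smoothed with a centered moving average before feature
#' extraction (set `smooth_window = NULL` for pre-smoothed input).
#'
#' @param blue,green,red equal-length numeric traces on the canonical
#'   background-subtracted scale
#' @param peak a [peak_params()] object
#' @param step a [step_params()] object
#' @param smooth_window moving-average window applied to each channel before
#'   feature extraction, or `NULL`
#' @param after_frames 0-based frames for the restricted means (the default
#'   decision tree needs frame 50 on red)
#' @return object of class `cell_fingerprint`
#' @export
fingerprint <- function(blue, green, red,
                        peak = peak_params(), step = step_params(),
                        smooth_window = 20, after_frames = 50) {
  stopifnot(length(blue) == length(green), length(blue) == length(red))
  ch <- list(blue = blue, green = green, red = red)
  if (!is.null(smooth_window)) {
    ch <- lapply(ch, smooth_trace, window = smooth_window)
  }
  structure(list(
    stats = lapply(ch, summarize_trace, after_frames = after_frames),
    peaks = list(blue = find_transients(ch$blue, peak),
                 green = find_transients(ch$green, peak)),
    changepoints = list(blue = find_steps(ch$blue, step),
                        green = find_steps(ch$green, step)),
    red_blue_mean_diff = mean(ch$red) - mean(ch$blue),
    n_frames = length(blue),
    params = list(peak = peak, step = step, smooth_window = smooth_window,
                  after_frames = after_frames)
  ), class = "cell_fingerprint")
}

#' Fingerprints for every cell of a traces table
#'
#' @param traces an `intensity_traces` data.frame (cell_id, frame, blue,
#'   green, red); if the traces were already smoothed at extraction time the
#'   recorded window is honored and no second smoothing is applied
#' @param ... passed to [fingerprint()]
#' @return named list of `cell_fingerprint` objects (names = cell ids)
#' @export
fingerprint_cells <- function(traces, ...) {
  args <- list(...)
  if (is.null(args$smooth_window) && !is.null(attr(traces, "smooth_window"))) {
    args$smooth_window <- NULL  # already smoothed upstream
    args["smooth_window"] <- list(NULL)
  }
  df <- as.data.frame(traces)
  df <- df[order(df$cell_id, df$frame), ]
  out <- lapply(split(df, df$cell_id), function(d) {
    do.call(fingerprint, c(list(blue = d$blue, green = d$green, red = d$red),
                           args))
  })
  out
}

#' Flatten fingerprints to one row per cell
#'
#' Summary statistics become columns; peak and changepoint tables are
#' JSON-encoded, one column per channel, so the result round-trips through
#' CSV.
#'
#' @param fps named list from [fingerprint_cells()]
#' @return data.frame, one row per cell
#' @export
fingerprints_to_df <- function(fps) {
  rows <- lapply(names(fps), function(id) {
    fp <- fps[[id]]
    row <- list(cell_id = id)
    for (ch in c("blue", "green", "red")) {
      s <- fp$stats[[ch]]
      row[[paste0(ch, "_min")]] <- s$min
      row[[paste0(ch, "_max")]] <- s$max
      row[[paste0(ch, "_argmax")]] <- s$argmax
      row[[paste0(ch, "_mean")]] <- s$mean
      row[[paste0(ch, "_variance")]] <- s$variance
      row[[paste0(ch, "_range")]] <- s$range
      row[[paste0(ch, "_range_after_argmax")]] <- s$range_after_argmax
      for (f in names(s$mean_after)) {
        row[[paste0(ch, "_mean_after_", f)]] <- s$mean_after[[f]]
      }
    }
    row$red_blue_mean_diff <- fp$red_blue_mean_diff
    row$blue_peaks <- as.character(jsonlite::toJSON(fp$peaks$blue, digits = NA))
    row$green_peaks <- as.character(jsonlite::toJSON(fp$peaks$green, digits = NA))
    row$blue_changepoints <-
      as.character(jsonlite::toJSON(fp$changepoints$blue, digits = NA))
    row$green_changepoints <-
      as.character(jsonlite::toJSON(fp$changepoints$green, digits = NA))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
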