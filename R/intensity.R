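#' Background subtraction parameters
#'
#' Tiled-grid background estimation: each image is divided into a
#' `grid x grid` array of regions and, within each region, the mean of the
#' `n_lowest` smallest pixel values is subtracted from every pixel of that
#' region. With the defaults on a 512 x 512 image each region holds 4096
#' pixels, so the 20 lowest values are essentially guaranteed to lie outside
#' cells; this tracks background that is non-uniform in space and drifts in
#' time (e.g. stain leaking into the matrix after injury).
#'
#' @param grid regions per axis
#' @param n_lowest number of smallest pixel values averaged per region
#' @param clip_negative clip the subtracted image at zero; off by default,
#'   negative residuals are informative for quality control
#' @return object of class `background_params`
#' @export
background_params <- function(grid = 8, n_lowest = 20, clip_negative = FALSE) {
  stopifnot(grid >= 1, n_lowest >= 1)
  structure(list(grid = as.integer(grid), n_lowest = as.integer(n_lowest),
                 clip_negative = isTRUE(clip_negative)),
            class = "background_params")
}

# region boundaries: floor split, remainder pixels assigned to the last region
region_breaks <- function(n, g) {
  base <- n %/% g
  sizes <- rep(base, g)
  sizes[g] <- sizes[g] + n %% g
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Subtract tiled-grid background from an image
#'
#' @param image intensity matrix, at least `grid x grid` pixels
#' @param params a [background_params()] object
#' @return matrix of the same size with per-region background removed
#' @export
subtract_background <- function(image, params = background_params()) {
  stopifnot(is.matrix(image))
  g <- params$grid
  if (nrow(image) < g || ncol(image) < g) {
    stop("image smaller than the background grid")
  }
  rb <- region_breaks(nrow(image), g)
  cb <- region_breaks(ncol(image), g)
  if (params$n_lowest > min(rb[, 2] - rb[, 1] + 1) *
                        min(cb[, 2] - cb[, 1] + 1)) {
    stop("n_lowest exceeds the pixel count of a region")
  }
  out <- image
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      rows <- rb[i, 1]:rb[i, 2]
      cols <- cb[j, 1]:cb[j, 2]
      v <- image[rows, cols]
      k <- params$n_lowest
      bg <- mean(sort(as.numeric(v), partial = k)[seq_len(k)])
      out[rows, cols] <- v - bg
    }
  }
  if (params$clip_negative) out[out < 0] <- 0
  out
}

#' Centered moving-average smoothing
#'
#' Removes high-frequency fluctuation from a trace without displacing the
#' features of interest. The window is centered (for even windows, one more
#' sample behind than ahead) and shrinks to the in-bounds portion at the
#' trace ends, so no intensities are fabricated and the output has the same
#' length as the input.
#'
#' @param x numeric trace
#' @param window window size, frames
#' @return smoothed numeric vector
#' @export
smooth_trace <- function(x, window = 20) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0) stop("empty trace")
  if (window == 1 || n == 1) return(x)
  back <- floor(window / 2)
  ahead <- ceiling(window / 2) - 1
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - back, 1L)
  hi <- pmin(i + ahead, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

new_traces <- function(df, background_subtracted, smooth_window) {
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            background_subtracted = isTRUE(background_subtracted),
            smooth_window = smooth_window,
            class = c("intensity_traces", "data.frame"))
}

#' Extract per-cell intensity traces from an image stack
#'
#' For every tracked cell, frame and channel, the mean intensity of the
#' `(2 * half_width + 1)^2` pixel window centered on the rounded centroid is
#' recorded (windows are truncated at image borders). Background subtraction
#' is applied to each channel of each frame *before* extraction (pass
#' `background = NULL` to skip it, e.g. for raw-intensity QC), and a centered
#' moving average optionally smooths each trace afterwards.
#'
#' @param stack an `image_stack`
#' @param tracks a `cell_tracks` data.frame; positions must round to within
#'   the image
#' @param half_width window half-width in px; 1 gives the 3x3 neighborhood
#' @param background a [background_params()] object or `NULL`
#' @param smooth_window moving-average window in frames, or `NULL` for no
#'   smoothing
#' @return `intensity_traces` data.frame: `cell_id`, `frame`, `blue`,
#'   `green`, `red`, with attributes `background_subtracted` and
#'   `smooth_window`
#' @export
extract_traces <- function(stack, tracks, half_width = 1,
                           background = background_params(),
                           smooth_window = NULL) {
  stopifnot(inherits(stack, "image_stack"), half_width >= 0)
  nT <- n_frames(stack)
  if (any(tracks$frame < 0 | tracks$frame > nT - 1)) {
    stop("track references a frame absent from the stack")
  }
  h <- nrow(stack$frames[[1]][[1]])
  w <- ncol(stack$frames[[1]][[1]])
  channels <- c("blue", "green", "red")

  df <- as.data.frame(tracks)
  n <- nrow(df)
  vals <- matrix(NA_real_, n, 3, dimnames = list(NULL, channels))
  px <- round_half_away(df$x) + 1L  # 1-based pixel columns
  py <- round_half_away(df$y) + 1L
  if (any(px < 1 | px > w | py < 1 | py > h)) {
    stop("track positions outside the image after rounding")
  }
  for (f in sort(unique(df$frame))) {
    rows <- which(df$frame == f)
    fr <- stack$frames[[f + 1L]]
    for (ci in seq_along(channels)) {
      m <- fr[[channels[ci]]]
      if (!is.null(background)) m <- subtract_background(m, background)
      for (r in rows) {
        ys <- max(1L, py[r] - half_width):min(h, py[r] + half_width)
        xs <- max(1L, px[r] - half_width):min(w, px[r] + half_width)
        vals[r, ci] <- mean(m[ys, xs])
      }
    }
  }
  out <- data.frame(cell_id = df$cell_id, frame = df$frame,
                    blue = vals[, 1], green = vals[, 2], red = vals[, 3])
  if (!is.null(smooth_window)) {
    out <- out[order(out$cell_id, out$frame), ]
    for (ch in channels) {
      out[[ch]] <- stats::ave(out[[ch]], out$cell_id,
                              FUN = function(v) smooth_trace(v, smooth_window))
    }
  }
  new_traces(out, !is.null(background), smooth_window)
}

#' Write / read intensity traces as CSV with a JSON sidecar
#'
#' The sidecar `<path>.json` records whether background subtraction was
#' applied and the smoothing window, so downstream feature extraction knows
#' what scale the traces are on.
#'
#' @param traces an `intensity_traces` data.frame
#' @param path CSV path
#' @return `path` (write) or `intensity_traces` (read)
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  jsonlite::write_json(
    list(background_subtracted = isTRUE(attr(traces, "background_subtracted")),
         smooth_window = attr(traces, "smooth_window")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  bg <- FALSE
  sw <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    bg <- isTRUE(meta$background_subtracted)
    sw <- meta$smooth_window
  }
  new_traces(df, bg, sw)
}
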