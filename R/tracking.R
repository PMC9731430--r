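#' Tracking parameters
#'
#' Controls centroid localization on the summed-channel image, frame-to-frame
#' linking, gap interpolation and static-phase extension.
#'
#' @param locate_diameter odd spot search diameter, px
#' @param min_mass minimum integrated band-passed intensity of a detection
#' @param min_signal minimum band-passed peak height of a detection, a.u.
#' @param max_link_displacement maximum per-frame displacement when linking
#' @param max_gap_frames maximum number of consecutive missed frames a track
#'   survives ("memory")
#' @param max_gap_displacement maximum displacement (px) between the
#'   detections bracketing a gap for the gap to be linked and interpolated;
#'   default about one cell diameter
#' @param static_extension extend tracks at their last detected position
#'   through the static late phase
#' @param static_start_frame 0-based frame at which the tissue is considered
#'   static; `NULL` auto-detects it from the tracks (first frame after which
#'   the median per-frame displacement stays below 0.2 px over a 10-frame
#'   window)
#' @return object of class `track_params`
#' @export
track_params <- function(locate_diameter = 9,
                         min_mass = 25,
                         min_signal = 1,
                         max_link_displacement = 5,
                         max_gap_frames = 5,
                         max_gap_displacement = 10,
                         static_extension = TRUE,
                         static_start_frame = NULL) {
  stopifnot(locate_diameter >= 3, locate_diameter %% 2 == 1,
            min_mass >= 0, min_signal >= 0, max_link_displacement > 0,
            max_gap_frames >= 0, max_gap_displacement > 0)
  structure(list(locate_diameter = as.integer(locate_diameter),
                 min_mass = min_mass, min_signal = min_signal,
                 max_link_displacement = max_link_displacement,
                 max_gap_frames = as.integer(max_gap_frames),
                 max_gap_displacement = max_gap_displacement,
                 static_extension = isTRUE(static_extension),
                 static_start_frame = static_start_frame),
            class = "track_params")
}

#' Summed-channel composite image
#'
#' Pixelwise sum of the three fluorescence channels of one frame; cells show
#' up as bright isolated regions even when individual channels are dim.
#'
#' @param stack an `image_stack`
#' @param frame 0-based frame index
#' @return intensity matrix
#' @export
composite <- function(stack, frame) {
  stopifnot(inherits(stack, "image_stack"))
  f <- as.integer(frame) + 1L
  if (f < 1L || f > length(stack$frames)) {
    stop("frame ", frame, " out of range [0, ", length(stack$frames) - 1, "]")
  }
  fr <- stack$frames[[f]]
  fr$blue + fr$green + fr$red
}

#' Locate bright spots in a single image
#'
#' Centroid localization in the style of Crocker & Grier: the image is
#' band-pass filtered (Gaussian smoothing at sd 1 px minus a boxcar local
#' average over the search diameter), local maxima above `min_signal` become
#' candidates, and each candidate is refined to sub-pixel precision by the
#' intensity-weighted centroid of its neighborhood, iterating when the
#' centroid moves off the starting pixel. Detections with integrated
#' band-passed mass below `min_mass` are discarded.
#'
#' @param image non-negative intensity matrix (typically a [composite()])
#' @param params a [track_params()] object
#' @return data.frame with columns `x`, `y` (0-based, sub-pixel), `mass`,
#'   `size` (rms radius, px)
#' @export
locate <- function(image, params = track_params()) {
  stopifnot(is.matrix(image))
  w <- params$locate_diameter
  r <- w %/% 2L
  h <- nrow(image)
  wd <- ncol(image)

  bp <- conv_sep(image, gaussian_kernel(1)) - conv_sep(image, boxcar_kernel(w))
  bp[bp < 0] <- 0

  mx <- max_filter(bp, r)
  cand <- which(bp >= mx & bp > params$min_signal, arr.ind = TRUE)
  # drop candidates too close to the border to hold a full window
  keep <- cand[, 1] > r & cand[, 1] <= h - r & cand[, 2] > r & cand[, 2] <= wd - r
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      mass = numeric(0), size = numeric(0)))
  }

  off <- (-r):r
  res <- matrix(NA_real_, nrow(cand), 4)
  for (i in seq_len(nrow(cand))) {
    cy <- cand[i, 1]
    cx <- cand[i, 2]
    for (iter in 1:3) {
      win <- bp[cy + off, cx + off]
      mass <- sum(win)
      if (mass <= 0) break
      dx <- sum(colSums(win) * off) / mass
      dy <- sum(rowSums(win) * off) / mass
      sx <- cx + dx
      sy <- cy + dy
      ncx <- min(max(round_half_away(sx), r + 1), wd - r)
      ncy <- min(max(round_half_away(sy), r + 1), h - r)
      if (ncx == cx && ncy == cy) break
      cx <- ncx
      cy <- ncy
    }
    win <- bp[cy + off, cx + off]
    mass <- sum(win)
    if (mass <= 0) next
    dx <- sum(colSums(win) * off) / mass
    dy <- sum(rowSums(win) * off) / mass
    size2 <- (sum(colSums(win) * off^2) + sum(rowSums(win) * off^2)) / mass
    res[i, ] <- c(cx + dx - 1, cy + dy - 1, mass, sqrt(max(size2, 0)))
  }
  res <- res[!is.na(res[, 1]) & res[, 3] >= params$min_mass, , drop = FALSE]
  det <- data.frame(x = res[, 1], y = res[, 2], mass = res[, 3],
                    size = res[, 4])
  dedupe_detections(det, r)
}

# Refinement can funnel neighboring local maxima of one spot to the same
# centroid; keep the most massive detection among any pair closer than half
# the search radius.
dedupe_detections <- function(det, r) {
  if (nrow(det) < 2) return(det)
  o <- order(-det$mass)
  det <- det[o, ]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det) - 1)) {
    if (!keep[i]) next
    j <- (i + 1):nrow(det)
    d2 <- (det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2
    keep[j[d2 < (r / 2)^2]] <- FALSE
  }
  det <- det[keep, ]
  det[order(det$y, det$x), , drop = FALSE]
}

new_tracks <- function(df) {
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cell_tracks", "data.frame")
  df
}

#' Link per-frame detections into trajectories
#'
#' Nearest-neighbor linking: at each frame every active track is matched to
#' the closest unclaimed detection (pairs assigned globally in order of
#' increasing distance) within `max_link_displacement` px per elapsed frame,
#' capped at `max_gap_displacement` when frames were missed. Tracks not seen
#' for more than `max_gap_frames` frames are retired; unclaimed detections
#' start new tracks. Missed frames inside a track are left unfilled here
#' (see [interpolate_gaps()]).
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`
#'   (and optionally `mass`), sorted by frame or not
#' @param params a [track_params()] object
#' @return `cell_tracks` data.frame: `cell_id`, `frame`, `x`, `y`,
#'   `provenance` (all rows `"detected"`)
#' @export
link <- function(detections, params = track_params()) {
  cols <- c("frame", "x", "y")
  stopifnot(all(cols %in% names(detections)))
  if (nrow(detections) == 0) {
    return(new_tracks(data.frame(cell_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0),
                                 provenance = character(0))))
  }
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections[, c("x", "y")], detections$frame)

  # active track state
  tr_x <- numeric(0); tr_y <- numeric(0); tr_last <- integer(0)
  tr_id <- integer(0)
  next_id <- 0L
  rows_id <- list(); rows_frame <- list(); rows_x <- list(); rows_y <- list()
  add_row <- function(id, f, x, y) {
    k <- length(rows_id) + 1L
    rows_id[[k]] <<- id; rows_frame[[k]] <<- f
    rows_x[[k]] <<- x; rows_y[[k]] <<- y
  }

  for (f in frames) {
    det <- by_frame[[as.character(f)]]
    nd <- nrow(det)
    assigned_det <- rep(FALSE, nd)
    matched_tr <- rep(FALSE, length(tr_id))
    if (length(tr_id) > 0 && nd > 0) {
      gap <- f - tr_last
      lim <- pmin(params$max_link_displacement * gap,
                  ifelse(gap > 1, params$max_gap_displacement, Inf))
      lim <- pmin(lim, max(params$max_link_displacement,
                           params$max_gap_displacement))
      d2 <- outer(tr_x, det$x, `-`)^2 + outer(tr_y, det$y, `-`)^2
      ok <- d2 <= lim^2
      if (any(ok)) {
        idx <- which(ok, arr.ind = TRUE)
        ord <- order(d2[ok])
        for (k in ord) {
          ti <- idx[k, 1]
          di <- idx[k, 2]
          if (matched_tr[ti] || assigned_det[di]) next
          matched_tr[ti] <- TRUE
          assigned_det[di] <- TRUE
          tr_x[ti] <- det$x[di]
          tr_y[ti] <- det$y[di]
          tr_last[ti] <- f
          add_row(tr_id[ti], f, det$x[di], det$y[di])
        }
      }
    }
    # new tracks from unclaimed detections
    for (di in which(!assigned_det)) {
      id <- next_id
      next_id <- next_id + 1L
      tr_id <- c(tr_id, id)
      tr_x <- c(tr_x, det$x[di])
      tr_y <- c(tr_y, det$y[di])
      tr_last <- c(tr_last, f)
      add_row(id, f, det$x[di], det$y[di])
    }
    # retire tracks out of memory
    live <- (f - tr_last) <= params$max_gap_frames
    tr_id <- tr_id[live]; tr_x <- tr_x[live]; tr_y <- tr_y[live]
    tr_last <- tr_last[live]
  }

  new_tracks(data.frame(cell_id = unlist(rows_id),
                        frame = as.integer(unlist(rows_frame)),
                        x = unlist(rows_x), y = unlist(rows_y),
                        provenance = "detected"))
}

#' Fill small track gaps by linear interpolation
#'
#' Fluorescence fluctuation can make a cell invisible for a few frames.
#' Every internal run of missing frames whose bracketing detected positions
#' are at most `max_gap_displacement` px apart is filled by linear
#' interpolation between the brackets and flagged `"interpolated"`. Gaps
#' wider than that displacement split the track into two ids: interpolating
#' across a large displacement would fabricate positions.
#'
#' @param tracks a `cell_tracks` data.frame (from [link()])
#' @param params a [track_params()] object
#' @return `cell_tracks` with interpolated rows inserted
#' @export
interpolate_gaps <- function(tracks, params = track_params()) {
  if (nrow(tracks) == 0) return(tracks)
  pieces <- list()
  next_extra_id <- max(tracks$cell_id) + 1L
  for (df in split(as.data.frame(tracks), tracks$cell_id)) {
    df <- df[order(df$frame), ]
    n <- nrow(df)
    dfr <- diff(df$frame)
    if (n == 1 || all(dfr == 1)) {
      pieces[[length(pieces) + 1L]] <- df
      next
    }
    disp <- sqrt(diff(df$x)^2 + diff(df$y)^2)
    gap <- dfr > 1
    fill <- gap & disp <= params$max_gap_displacement
    split_gap <- gap & !fill
    # rows after an unfillable gap belong to a fresh track id
    seg <- cumsum(c(0L, as.integer(split_gap)))
    ids <- ifelse(seg == 0L, df$cell_id[1], next_extra_id + seg - 1L)
    next_extra_id <- next_extra_id + max(seg)
    df$cell_id <- ids
    pieces[[length(pieces) + 1L]] <- df
    for (i in which(fill)) {
      fg <- (df$frame[i] + 1):(df$frame[i + 1] - 1)
      a <- (fg - df$frame[i]) / (df$frame[i + 1] - df$frame[i])
      pieces[[length(pieces) + 1L]] <- data.frame(
        cell_id = ids[i], frame = fg,
        x = df$x[i] + a * (df$x[i + 1] - df$x[i]),
        y = df$y[i] + a * (df$y[i + 1] - df$y[i]),
        provenance = "interpolated")
    }
  }
  new_tracks(do.call(rbind, pieces))
}

#' Auto-detect the static start frame
#'
#' First 0-based frame after which the median per-frame displacement of all
#' detected track positions stays below `threshold` px over a `window`-frame
#' window. Returns `NA` when no such frame exists.
#'
#' @param tracks a `cell_tracks` data.frame
#' @param threshold displacement threshold, px/frame
#' @param window window length, frames
#' @return integer frame or `NA`
#' @export
detect_static_start <- function(tracks, threshold = 0.2, window = 10) {
  det <- tracks[tracks$provenance == "detected", ]
  if (nrow(det) < 2) return(NA_integer_)
  det <- det[order(det$cell_id, det$frame), ]
  same <- c(FALSE, diff(det$cell_id) == 0 & diff(det$frame) == 1)
  disp <- sqrt(c(NA, diff(det$x))^2 + c(NA, diff(det$y))^2)
  df <- data.frame(frame = det$frame[same], disp = disp[same])
  if (nrow(df) == 0) return(NA_integer_)
  med <- tapply(df$disp, df$frame, stats::median)
  fr <- as.integer(names(med))
  for (i in seq_along(fr)) {
    in_win <- fr >= fr[i] & fr < fr[i] + window
    if (any(in_win) && stats::median(med[in_win]) < threshold) {
      return(fr[i])
    }
  }
  NA_integer_
}

#' Extend tracks through the static late phase
#'
#' Once the tissue has relaxed and cells are nearly static, fluorescence is
#' measured at the last known position even when the cell is no longer
#' visible: every track whose last detection falls at or after
#' `static_start_frame` is extended to the final frame at that position,
#' with the new rows flagged `"extended"`.
#'
#' @param tracks a `cell_tracks` data.frame
#' @param stack the `image_stack` being tracked (used for the frame count),
#'   or an integer frame count
#' @param params a [track_params()] object; `static_start_frame = NULL`
#'   auto-detects via [detect_static_start()]
#' @return `cell_tracks` with extended rows appended
#' @export
extend_static <- function(tracks, stack, params = track_params()) {
  if (!params$static_extension || nrow(tracks) == 0) return(tracks)
  total <- if (inherits(stack, "image_stack")) n_frames(stack)
           else as.integer(stack)
  start <- params$static_start_frame
  if (is.null(start)) start <- detect_static_start(tracks)
  if (is.na(start)) return(tracks)
  if (start > total - 1) {
    stop("static_start_frame ", start, " beyond the last frame ", total - 1)
  }
  pieces <- list(as.data.frame(tracks))
  for (df in split(as.data.frame(tracks), tracks$cell_id)) {
    last <- df[which.max(df$frame), ]
    if (last$frame >= start && last$frame < total - 1) {
      fg <- (last$frame + 1):(total - 1)
      pieces[[length(pieces) + 1L]] <- data.frame(
        cell_id = last$cell_id, frame = fg, x = last$x, y = last$y,
        provenance = "extended")
    }
  }
  new_tracks(do.call(rbind, pieces))
}

#' Track all cells through an image stack
#'
#' Full tracking pipeline: summed-channel [composite()] per frame,
#' [locate()] detections, [link()] into trajectories, [interpolate_gaps()],
#' and [extend_static()].
#'
#' @param stack an `image_stack`
#' @param params a [track_params()] object
#' @return `cell_tracks` data.frame
#' @export
track <- function(stack, params = track_params()) {
  stopifnot(inherits(stack, "image_stack"))
  nT <- n_frames(stack)
  dets <- vector("list", nT)
  for (f in seq_len(nT)) {
    d <- locate(composite(stack, f - 1), params)
    if (nrow(d) > 0) d$frame <- f - 1L
    dets[[f]] <- d
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  if (is.null(dets) || nrow(dets) == 0) {
    return(new_tracks(data.frame(cell_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0),
                                 provenance = character(0))))
  }
  tracks <- link(dets, params)
  tracks <- interpolate_gaps(tracks, params)
  extend_static(tracks, nT, params)
}

#' Filter out stub tracks
#'
#' Removes tracks with fewer than `min_detected` detected frames (spurious
#' detections of noise blobs leave one- or two-frame stubs) and, optionally,
#' tracks that end before `last_frame` (cells that vanish early cannot be
#' classified on features of the late phase).
#'
#' @param tracks a `cell_tracks` data.frame
#' @param min_detected minimum number of `detected` rows per track
#' @param last_frame 0-based frame every kept track must reach (after
#'   interpolation/extension), or `NULL`
#' @return filtered `cell_tracks`
#' @export
filter_tracks <- function(tracks, min_detected = 50, last_frame = NULL) {
  if (nrow(tracks) == 0) return(tracks)
  df <- as.data.frame(tracks)
  ndet <- tapply(df$provenance == "detected", df$cell_id, sum)
  keep <- names(ndet)[ndet >= min_detected]
  if (!is.null(last_frame)) {
    fmax <- tapply(df$frame, df$cell_id, max)
    keep <- intersect(keep, names(fmax)[fmax >= last_frame])
  }
  new_tracks(df[as.character(df$cell_id) %in% keep, , drop = FALSE])
}

#' Write / read a tracks table as CSV
#'
#' Columns: `cell_id`, `frame` (0-based), `x`, `y` (0-based px),
#' `provenance` (`detected` / `interpolated` / `extended`).
#'
#' @param tracks a `cell_tracks` data.frame
#' @param path CSV path
#' @return `path` (write) or `cell_tracks` (read)
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  new_tracks(utils::read.csv(path, stringsAsFactors = FALSE))
}
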