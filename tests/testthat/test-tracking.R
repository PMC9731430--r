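make_stack_from_matrices <- function(mats) {
  zero <- mats[[1]] * 0
  image_stack(lapply(mats, function(m) list(blue = m, green = zero, red = zero)))
}

test_that("composite sums the three channels pixelwise", {
  m1 <- matrix(1, 8, 8); m2 <- matrix(2, 8, 8); m3 <- matrix(3, 8, 8)
  st <- image_stack(list(list(blue = m1, green = m2, red = m3)))
  expect_equal(composite(st, 0), matrix(6, 8, 8))

  st <- image_stack(list(list(blue = m1 * 0, green = m2, red = m3)))
  expect_equal(composite(st, 0), m2 + m3)

  set.seed(21)
  fr <- list(blue = matrix(runif(64), 8, 8), green = matrix(runif(64), 8, 8),
             red = matrix(runif(64), 8, 8))
  st <- image_stack(list(fr))
  expect_equal(composite(st, 0), fr$blue + fr$green + fr$red)
  expect_error(composite(st, 1), "out of range")
})

test_that("locate finds rendered spots to sub-pixel accuracy", {
  expect_equal(nrow(locate(matrix(0, 64, 64))), 0)

  spot <- function(m, x0, y0, amp = 30, sigma = 2) {
    xx <- matrix(rep(0:(ncol(m) - 1), each = nrow(m)), nrow(m))
    yy <- matrix(rep(0:(nrow(m) - 1), times = ncol(m)), nrow(m))
    m + amp * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * sigma^2))
  }
  img <- spot(matrix(0, 256, 256), 100.0, 200.0)
  d <- locate(img)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 100), 0.1)
  expect_lt(abs(d$y - 200), 0.1)

  img2 <- spot(spot(matrix(0, 256, 256), 80.3, 120.7), 130.3, 120.7)
  expect_equal(nrow(locate(img2)), 2)

  expect_error(locate(img, track_params(locate_diameter = 8)))
})

test_that("linking follows identities and respects the displacement cap", {
  # one static spot over 10 frames
  det <- data.frame(frame = 0:9, x = 5, y = 5)
  tr <- link(det)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(sum(tr$provenance == "detected"), 10)

  # two spots drifting 1 px/frame in opposite directions keep identities
  det <- rbind(data.frame(frame = 0:9, x = 10 + 0:9, y = 10),
               data.frame(frame = 0:9, x = 30 - 0:9, y = 10))
  tr <- link(det)
  expect_equal(length(unique(tr$cell_id)), 2)
  a <- tr[tr$cell_id == tr$cell_id[tr$frame == 0 & tr$x == 10], ]
  expect_equal(sort(a$x), 10 + 0:9)

  # a jump beyond max_link_displacement starts a new track
  det <- data.frame(frame = 0:5, x = c(5, 5, 5, 40, 40, 40), y = 5)
  tr <- link(det, track_params(max_link_displacement = 5))
  expect_equal(length(unique(tr$cell_id)), 2)

  expect_equal(nrow(link(data.frame(frame = integer(0), x = numeric(0),
                                    y = numeric(0)))), 0)
})

test_that("gap interpolation fills small gaps linearly and splits large ones", {
  det <- data.frame(frame = c(5, 7), x = c(10, 12), y = c(0, 0))
  tr <- interpolate_gaps(link(det))
  mid <- tr[tr$frame == 6, ]
  expect_equal(mid$x, 11)
  expect_equal(mid$y, 0)
  expect_equal(mid$provenance, "interpolated")

  # displacement above max_gap_displacement: not filled, track splits
  det <- data.frame(frame = c(0, 1, 4, 5), x = c(0, 1, 31, 32), y = 0)
  tr <- interpolate_gaps(link(det, track_params(max_link_displacement = 40,
                                                max_gap_frames = 5,
                                                max_gap_displacement = 10)))
  expect_equal(length(unique(tr$cell_id)), 2)
  expect_false(any(tr$provenance == "interpolated"))

  # gapless track unchanged
  det <- data.frame(frame = 0:9, x = 1:10, y = 0)
  tr0 <- link(det)
  expect_identical(as.data.frame(interpolate_gaps(tr0)), as.data.frame(tr0))
})

test_that("interpolated positions lie on the segment between brackets", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      frames <- sort(sample(0:40, 25))
      det <- data.frame(frame = frames, x = cumsum(runif(25, -1, 1)) + 50,
                        y = cumsum(runif(25, -1, 1)) + 50)
      tr <- interpolate_gaps(link(det, track_params(max_gap_frames = 10)))
      ip <- tr[tr$provenance == "interpolated", ]
      dt <- tr[tr$provenance == "detected", ]
      for (k in seq_len(nrow(ip))) {
        pre <- dt[dt$frame < ip$frame[k], ]
        post <- dt[dt$frame > ip$frame[k], ]
        p1 <- pre[which.max(pre$frame), c("x", "y", "frame")]
        p2 <- post[which.min(post$frame), c("x", "y", "frame")]
        a <- (ip$frame[k] - p1$frame) / (p2$frame - p1$frame)
        expect_equal(ip$x[k], p1$x + a * (p2$x - p1$x))
        expect_equal(ip$y[k], p1$y + a * (p2$y - p1$y))
      }
    }
  })
})

test_that("static extension continues late tracks at their last position", {
  det <- data.frame(frame = 0:100, x = 7, y = 9)
  tr <- link(det)
  ext <- extend_static(tr, 300, track_params(static_start_frame = 50))
  added <- ext[ext$provenance == "extended", ]
  expect_equal(added$frame, 101:299)
  expect_true(all(added$x == 7 & added$y == 9))

  # track spanning all frames: unchanged
  det <- data.frame(frame = 0:299, x = 7, y = 9)
  tr <- link(det)
  expect_identical(nrow(extend_static(tr, 300,
                                      track_params(static_start_frame = 50))),
                   nrow(tr))

  # extension disabled: unchanged
  det <- data.frame(frame = 0:100, x = 7, y = 9)
  tr <- link(det)
  expect_identical(nrow(extend_static(tr, 300,
                                      track_params(static_extension = FALSE))),
                   nrow(tr))

  # a track ending before the static phase is not extended
  det <- data.frame(frame = 0:30, x = 7, y = 9)
  tr <- link(det)
  ext <- extend_static(tr, 300, track_params(static_start_frame = 50))
  expect_false(any(ext$provenance == "extended"))

  expect_error(extend_static(tr, 300, track_params(static_start_frame = 400)),
               "beyond")
})

test_that("full tracking recovers a rendered static scene", {
  fx <- tiny_scene(n_cells = 20, n_frames = 150, field = 160, seed = 31,
                   motion_model = list(type = "static"))
  tracks <- track(fx$stack)
  m <- match_tracks_to_truth(tracks, fx$scene)
  full <- 0
  tdf <- as.data.frame(tracks)
  for (k in seq_len(nrow(m))) {
    if (is.na(m$true_cell[k])) next
    fr <- sort(tdf$frame[tdf$cell_id == m$cell_id[k]])
    if (length(fr) == 150 && all(diff(fr) == 1)) full <- full + 1
  }
  expect_gte(full / 20, 0.99)

  # localization RMSE of detected positions against ground truth
  det <- tdf[tdf$provenance == "detected", ]
  tx <- vapply(fx$scene$cells, function(cl) cl$trajectory[, "x"], numeric(150))
  ty <- vapply(fx$scene$cells, function(cl) cl$trajectory[, "y"], numeric(150))
  mm <- m$true_cell[match(det$cell_id, m$cell_id)]
  ok <- !is.na(mm)
  err2 <- (det$x[ok] - tx[cbind(det$frame[ok] + 1, mm[ok] + 1)])^2 +
          (det$y[ok] - ty[cbind(det$frame[ok] + 1, mm[ok] + 1)])^2
  expect_lt(sqrt(mean(err2)), 0.5)
})

test_that("provenance counts always add up to track length", {
  fx <- tiny_scene(n_cells = 15, n_frames = 150, field = 128, seed = 13,
                   noise = 1)
  # force gaps by deleting detections, then re-track from raw detections
  dets <- list()
  for (f in 0:149) {
    d <- locate(composite(fx$stack, f))
    d$frame <- f
    dets[[f + 1]] <- d
  }
  dets <- do.call(rbind, dets)
  dets <- withr::with_seed(3, dets[runif(nrow(dets)) >= 0.05, ])
  tracks <- extend_static(interpolate_gaps(link(dets)), 150,
                          track_params(static_start_frame = 60))
  for (df in split(as.data.frame(tracks), tracks$cell_id)) {
    expect_equal(sum(df$provenance == "detected") +
                 sum(df$provenance == "interpolated") +
                 sum(df$provenance == "extended"), nrow(df))
    expect_true(all(diff(sort(df$frame)) >= 1))
    # interpolated frames sit between detected ones, extensions after the last
    dfr <- df$frame[df$provenance == "detected"]
    if (any(df$provenance == "interpolated")) {
      expect_true(all(df$frame[df$provenance == "interpolated"] > min(dfr) &
                      df$frame[df$provenance == "interpolated"] < max(dfr)))
    }
    if (any(df$provenance == "extended")) {
      expect_true(all(df$frame[df$provenance == "extended"] > max(dfr)))
    }
  }
})

test_that("empty stacks give empty tracks", {
  st <- image_stack(list(list(blue = matrix(0, 32, 32),
                              green = matrix(0, 32, 32),
                              red = matrix(0, 32, 32))))
  expect_equal(nrow(track(st)), 0)
})

test_that("tracks round-trip through CSV with 0-based conventions intact", {
  det <- data.frame(frame = c(0, 1, 3), x = c(1.5, 2.5, 4.25), y = c(7, 7, 7))
  tr <- interpolate_gaps(link(det))
  path <- file.path(tempdir(), "tracks.csv")
  write_tracks(tr, path)
  rt <- read_tracks(path)
  expect_equal(as.data.frame(rt), as.data.frame(tr))
  expect_equal(min(rt$frame), 0)
  unlink(path)
})
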