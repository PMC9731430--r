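test_that("trace templates carry their category-defining features", {
  # normal cell: polarized red, quiet blue and green
  tr <- trace_template("J", 300, noise_sd = 0)
  expect_gt(mean(tr$red[52:300]), 6)
  expect_lt(max(tr$blue) - min(tr$blue), 10)
  expect_equal(nrow(find_transients(tr$green)), 0)

  # physiologic transients: qualifying green peaks, no blue changepoint
  tr <- trace_template("I", 300, noise_sd = 0)
  pk <- find_transients(smooth_trace(tr$green, 20))
  expect_gte(nrow(pk), 1)
  expect_true(all(pk$prominence >= 3))
  expect_true(all(pk$width / pk$prominence <= 10))
  expect_equal(nrow(find_steps(smooth_trace(tr$blue, 20))), 0)

  # multiple permeability levels: more than three blue changepoints
  tr <- trace_template("L", 300, noise_sd = 0)
  expect_gte(nrow(find_steps(smooth_trace(tr$blue, 20))), 4)
})

test_that("trace templates are deterministic for a fixed seed", {
  a <- trace_template("H", 300, noise_sd = 1.5, seed = 42)
  b <- trace_template("H", 300, noise_sd = 1.5, seed = 42)
  expect_identical(a, b)
  c <- trace_template("H", 300, noise_sd = 1.5, seed = 43)
  expect_false(identical(a$green, c$green))
})

test_that("trace_template rejects unknown categories and short traces", {
  expect_error(trace_template("Z", 300), "unknown behavior category")
  expect_error(trace_template("B", 100), "frame_count")
})

test_that("make_scene honors counts, weights and the seeded generator", {
  p0 <- scenario_params(n_cells = 0, frame_count = 150, seed = 1)
  expect_length(make_scene(p0)$cells, 0)

  w <- c(rep(0, 9), 1, 0, 0)  # everything on J
  pj <- scenario_params(n_cells = 50, frame_count = 150, field_size = 256,
                        category_weights = w, seed = 2)
  cats <- vapply(make_scene(pj)$cells, `[[`, "", "category")
  expect_identical(unname(cats), rep("J", 50))

  # category draw matches a brute-force draw with the same seeded generator
  p <- scenario_params(n_cells = 400, frame_count = 150, field_size = 480,
                       seed = 77)
  scene <- make_scene(p)
  drawn <- vapply(scene$cells, `[[`, "", "category")
  expected <- withr::with_seed(77L, {
    sample(behavior_categories(), 400, replace = TRUE,
           prob = p$category_weights)
  })
  expect_identical(unname(drawn), expected)

  # full scene determinism
  scene2 <- make_scene(p)
  expect_identical(scene, scene2)
})

test_that("scenes respect field bounds, separation and trace invariants", {
  p <- scenario_params(n_cells = 60, frame_count = 150, field_size = 256,
                       impact_center = c(128, 128), impact_radius_um = 100,
                       seed = 9)
  scene <- make_scene(p)
  pos <- t(vapply(scene$cells, function(cl) cl$trajectory[1, ], numeric(2)))
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  expect_gte(min(d), p$min_separation)
  for (cl in scene$cells) {
    expect_equal(nrow(cl$trajectory), 150)
    expect_true(all(cl$trajectory >= 0 & cl$trajectory <= 255))
    expect_true(all(cl$traces$blue >= 0))
    expect_true(all(cl$traces$green >= 0))
    expect_true(all(cl$traces$red >= 0))
  }
})

test_that("death-associated behaviors concentrate near the impact site", {
  w <- rep(0, 12); names(w) <- behavior_categories()
  w[c("B", "C", "J")] <- c(0.25, 0.25, 0.5)
  p <- scenario_params(n_cells = 120, frame_count = 150, field_size = 512,
                       category_weights = w,
                       impact_center = c(256, 256), impact_radius_um = 200,
                       seed = 4)
  scene <- make_scene(p)
  radius_px <- 200 / p$pixel_size
  cats <- vapply(scene$cells, `[[`, "", "category")
  dist_c <- vapply(scene$cells, function(cl) {
    sqrt(sum((cl$trajectory[150, ] - c(256, 256))^2))
  }, numeric(1))
  bc_inside <- mean(dist_c[cats %in% c("B", "C")] <= radius_px)
  expect_gte(bc_inside, 0.8)
  j_outside <- mean(dist_c[cats == "J"] > radius_px)
  expect_gte(j_outside, 0.7)
})

test_that("rendering reproduces ground truth geometry and noise level", {
  # empty scene: uniform background everywhere
  p0 <- scenario_params(n_cells = 0, frame_count = 150, field_size = 64,
                        seed = 1)
  st <- render_stack(make_scene(p0), render_params(background_level = 5))
  expect_true(all(vapply(st$frames[[1]], function(m) all(m == 5), TRUE)))

  # single static cell, noise off: intensity-weighted centroid of the
  # background-subtracted spot matches ground truth within 0.1 px
  w <- c(rep(0, 9), 1, 0, 0)
  p1 <- scenario_params(n_cells = 1, frame_count = 150, field_size = 64,
                        category_weights = w,
                        motion_model = list(type = "static"), seed = 8)
  scene <- make_scene(p1)
  st <- render_stack(scene, render_params(background_level = 5))
  truth <- scene$cells[[1]]$trajectory[1, ]
  img <- st$frames[[1]]$red - 5
  xs <- round(truth["x"] + 1) + (-8:8)
  ys <- round(truth["y"] + 1) + (-8:8)
  win <- img[ys, xs]
  cx <- sum(colSums(win) * (xs - 1)) / sum(win)
  cy <- sum(rowSums(win) * (ys - 1)) / sum(win)
  expect_lt(abs(cx - truth["x"]), 0.1)
  expect_lt(abs(cy - truth["y"]), 0.1)

  # camera noise: noisy minus clean render has the stated sd, mean ~ 0
  stn <- render_stack(scene, render_params(background_level = 5,
                                           camera_noise_sd = 2))
  dif <- stn$frames[[1]]$blue - st$frames[[1]]$blue
  expect_lt(abs(mean(dif)), 0.1)
  expect_lt(abs(sd(dif) - 2), 0.1)
})

test_that("quantized rendering reports saturation instead of silence", {
  w <- c(rep(0, 9), 1, 0, 0)
  p <- scenario_params(n_cells = 1, frame_count = 150, field_size = 64,
                       category_weights = w, seed = 8)
  scene <- make_scene(p)
  expect_warning(
    st <- render_stack(scene, render_params(background_level = 250,
                                            bit_depth = 8, quantize = TRUE)),
    "saturated")
  expect_gt(st$saturated, 0)
  expect_true(all(st$frames[[1]]$red <= 255))
})

test_that("image stacks round-trip through TIFF plus sidecar", {
  fx <- tiny_scene(n_cells = 3, n_frames = 150, field = 64)
  path <- file.path(tempdir(), "stack.tiff")
  write_stack(fx$stack, path)
  st2 <- read_stack(path)
  expect_equal(n_frames(st2), 150)
  expect_equal(st2$pixel_size, fx$stack$pixel_size)
  expect_equal(st2$frame_interval, fx$stack$frame_interval)
  # 16-bit quantization error is bounded by the stored scale / 65535
  vmax <- max(vapply(fx$stack$frames, function(fr) max(fr$red), 0))
  expect_lt(max(abs(st2$frames[[5]]$green - fx$stack$frames[[5]]$green)),
            vmax / 65535)
  unlink(c(path, paste0(path, ".json")))
})
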