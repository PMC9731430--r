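# Build a fingerprint from raw trace vectors (no smoothing: the vectors are
# constructed directly on the canonical scale).
fp_from <- function(blue, green, red) {
  fingerprint(blue, green, red, smooth_window = NULL)
}

flat <- function(v, n = 300) rep(v, n)

test_that("single-branch decisions follow the tree thresholds literally", {
  n <- 300
  # blue max 9 at frame 3 -> starts elevated (A)
  blue <- flat(1, n); blue[4] <- 9
  r <- classify_cell(fp_from(blue, flat(2, n), flat(30, n)))
  expect_equal(r$category, "A")
  expect_match(r$path[1], "blue_starts_elevated=yes")

  # boundary is strict: blue max exactly 7 is not "elevated"
  blue <- flat(1, n); blue[4] <- 7
  r <- classify_cell(fp_from(blue, flat(2, n), flat(30, n)))
  expect_false(r$category == "A")

  # 5 blue changepoints (staircase) -> multiple levels (L)
  tr <- trace_template("L", n)
  r <- classify_cell(fingerprint(tr$blue, tr$green, tr$red))
  expect_equal(r$category, "L")

  # no blue changepoints + a qualifying green peak -> physiologic transients
  green <- flat(2, n); green[100:110] <- 2 + c(2, 4, 6, 8, 10, 8, 6, 4, 2, 1, 0.5)
  r <- classify_cell(fp_from(flat(1, n), green, flat(30, n)))
  expect_equal(r$category, "I")

  # quiet cell, blue range 4: red mean after frame 50 separates J from K
  blue <- flat(1, n); blue[200] <- 5
  r <- classify_cell(fp_from(blue, flat(2, n), flat(30, n)))
  expect_equal(r$category, "J")
  r <- classify_cell(fp_from(blue, flat(2, n), flat(2, n)))
  expect_equal(r$category, "K")
})

test_that("all twelve noise-free templates classify into their category", {
  for (cat in behavior_categories()) {
    tr <- trace_template(cat, 300)
    r <- classify_cell(fingerprint(tr$blue, tr$green, tr$red))
    expect_equal(r$category, cat, info = paste("template", cat))
  }
})

test_that("every fingerprint reaches exactly one leaf, replayably", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      cat <- sample(behavior_categories(), 1)
      tr <- trace_template(cat, 300, noise_sd = runif(1, 0, 3),
                           seed = sample.int(1e6, 1))
      fp <- fingerprint(tr$blue, tr$green, tr$red)
      r1 <- classify_cell(fp)
      r2 <- classify_cell(fp)
      expect_true(r1$category %in% behavior_categories())
      # replay: identical fingerprint, identical path and leaf
      expect_identical(r1$path, r2$path)
      expect_identical(r1$category, r2$category)
    }
  })
})

test_that("classification is order independent and handles empty input", {
  trs <- lapply(behavior_categories(), trace_template, frame_count = 300)
  fps <- lapply(trs, function(tr) fingerprint(tr$blue, tr$green, tr$red))
  names(fps) <- paste0("c", seq_along(fps))
  res <- classify_all(fps)
  expect_equal(unname(res$cells$category), behavior_categories())
  expect_equal(sum(res$counts), 12)

  perm <- withr::with_seed(2, sample(length(fps)))
  res2 <- classify_all(fps[perm])
  m <- match(res$cells$cell_id, res2$cells$cell_id)
  expect_equal(res$cells$category, res2$cells$category[m])

  res0 <- classify_all(list())
  expect_equal(nrow(res0$cells), 0)
  expect_equal(sum(res0$counts), 0)
})

test_that("classification requires the red restricted mean it branches on", {
  tr <- trace_template("J", 300)
  fp <- fingerprint(tr$blue, tr$green, tr$red, after_frames = 10)
  expect_error(classify_cell(fp), "missing red mean after frame 50")
})

test_that("scoring implements per-category and total accuracy", {
  truth <- data.frame(cell_id = as.character(1:20),
                      category = rep(c("I", "J"), each = 10))
  pred <- truth
  s <- score_classification(pred, truth)
  expect_true(all(s$per_category$accuracy[s$per_category$n_truth > 0] == 1))
  expect_equal(s$total_accuracy, 1)
  # categories with zero truth count are undefined, not zero
  expect_true(all(is.na(s$per_category$accuracy[s$per_category$n_truth == 0])))

  pred$category[1:3] <- "J"  # 3 of 10 true-I cells mislabeled
  pred$category[11] <- "I"   # 1 of 10 true-J cells mislabeled
  s <- score_classification(pred, truth)
  expect_equal(s$per_category$accuracy[s$per_category$category == "I"], 0.7)
  expect_equal(s$per_category$accuracy[s$per_category$category == "J"], 0.9)
  expect_equal(s$total_accuracy, 16 / 20)

  expect_error(score_classification(pred[-1, ], truth), "differ")
})

test_that("raising blue_rise_range only moves cells from B toward J/K", {
  n <- 300
  fps <- withr::with_seed(77, {
    lapply(seq(4, 20, by = 1), function(amp) {
      # drift-free quiet blue trace with a mid-experiment bump of range amp
      blue <- rep(1, n) + rnorm(n, 0, 0.1)
      blue[150:n] <- blue[150:n] + amp * seq(0, 1, length.out = n - 149)^8
      fp_from(blue, flat(2, n), flat(sample(c(2, 30), 1), n))
    })
  })
  lab_lo <- vapply(fps, function(f) classify_cell(f, tree_params())$category, "")
  lab_hi <- vapply(fps, function(f) {
    classify_cell(f, tree_params(blue_rise_range = 14))$category
  }, "")
  changed <- lab_lo != lab_hi
  expect_true(all(lab_lo[changed] == "B"))
  expect_true(all(lab_hi[changed] %in% c("J", "K")))
})

test_that("noisy synthetic traces classify accurately at the default noise", {
  r <- classification_accuracy_experiment(seed = 5, per_category = 8)
  expect_gte(r$total_accuracy_percent, 81)
})

test_that("accuracy degrades monotonically with noise", {
  acc <- vapply(c(0, 2.5, 5), function(sd) {
    classification_accuracy_experiment(seed = 3, per_category = 5,
                                       noise_sd = sd)$total_accuracy_percent
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 100)
})

test_that("benchmark backends train, score and stay deterministic", {
  skip_if_not_installed("randomForest")
  # two well-separated categories
  mk <- function(cat, ids) {
    do.call(rbind, lapply(ids, function(i) {
      tr <- trace_template(cat, 150, noise_sd = 1, seed = i)
      data.frame(cell_id = paste0(cat, i), frame = 0:149,
                 blue = tr$blue, green = tr$green, red = tr$red)
    }))
  }
  traces <- rbind(mk("J", 1:12), mk("B", 13:24))
  labels <- data.frame(cell_id = c(paste0("J", 1:12), paste0("B", 13:24)),
                       category = rep(c("J", "B"), each = 12))
  out <- benchmark_backends(traces, labels, "random_forest", split_seed = 2)
  expect_gte(out$accuracy, 0.95)
  out2 <- benchmark_backends(traces, labels, "random_forest", split_seed = 2)
  expect_identical(out$accuracy, out2$accuracy)

  expect_error(benchmark_backends(traces, labels, character(0)),
               class = "fluortrack_capability_error")
  expect_error(benchmark_backends(traces, labels, "no_such_backend"),
               class = "fluortrack_capability_error")
})
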