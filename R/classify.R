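#' Decision-tree thresholds
#'
#' Thresholds of the twelve-category behavior decision tree, all on the
#' canonical background-subtracted intensity scale (a.u.) and 0-based frame
#' indices at the long-term imaging cadence. Every comparison in the tree is
#' a strict inequality, read literally ("greater than 7" excludes 7).
#'
#' @param elevated_blue_max blue maximum above which a cell can count as
#'   "starts elevated" (a.u.)
#' @param elevated_blue_argmax_frame frame before which the blue maximum must
#'   occur for "starts elevated"
#' @param multilevel_changepoint_count blue changepoint count above which the
#'   permeability has multiple levels (strict "more than")
#' @param red_blue_mean_diff mean red-minus-blue difference above which
#'   mitochondria count as polarized despite the permeability increase (a.u.)
#' @param late_argmax_frame frame after which the blue maximum must occur for
#'   a "late" increase
#' @param late_changepoint_frame frame after which the first blue changepoint
#'   must occur for a "late" increase
#' @param plateau_range_after_max blue range after the maximum below which
#'   the trace counts as a plateau (a.u.)
#' @param blue_rise_range blue range above which permeability counts as
#'   rising when no changepoint was detected (a.u.)
#' @param red_mean_frame frame after which the red mean is taken (cells have
#'   stabilized by then)
#' @param red_mean_low red mean below which mitochondria count as
#'   depolarized (a.u.)
#' @return object of class `tree_params`
#' @export
tree_params <- function(elevated_blue_max = 7,
                        elevated_blue_argmax_frame = 7,
                        multilevel_changepoint_count = 3,
                        red_blue_mean_diff = 20,
                        late_argmax_frame = 120,
                        late_changepoint_frame = 100,
                        plateau_range_after_max = 8,
                        blue_rise_range = 10,
                        red_mean_frame = 50,
                        red_mean_low = 6) {
  stopifnot(elevated_blue_max > 0, elevated_blue_argmax_frame > 0,
            multilevel_changepoint_count > 0, red_blue_mean_diff > 0,
            late_argmax_frame > 0, late_changepoint_frame > 0,
            plateau_range_after_max > 0, blue_rise_range > 0,
            red_mean_frame > 0, red_mean_low > 0)
  structure(list(elevated_blue_max = elevated_blue_max,
                 elevated_blue_argmax_frame = elevated_blue_argmax_frame,
                 multilevel_changepoint_count = multilevel_changepoint_count,
                 red_blue_mean_diff = red_blue_mean_diff,
                 late_argmax_frame = late_argmax_frame,
                 late_changepoint_frame = late_changepoint_frame,
                 plateau_range_after_max = plateau_range_after_max,
                 blue_rise_range = blue_rise_range,
                 red_mean_frame = red_mean_frame,
                 red_mean_low = red_mean_low),
            class = "tree_params")
}

#' Classify one cell fingerprint into a behavior category
#'
#' Rule-based decision tree over the fingerprint features. Cells whose blue
#' (nuclear membrane permeability) signal starts out elevated are split off
#' first; the tree then branches on whether blue changepoints exist. With
#' changepoints: more than `multilevel_changepoint_count` of them means
#' multiple permeability levels (L); a large mean red-minus-blue difference
#' means polarized mitochondria despite the increase (E); green transients
#' before versus after the first blue changepoint separate H from G; with no
#' green transients, a late increase (blue maximum after
#' `late_argmax_frame` and first changepoint after `late_changepoint_frame`)
#' splits into F (green changepoint: calcium dropped first) or D (no
#' trigger); an early increase splits into C (blue peaks: rise and fall),
#' B (plateau after the maximum) or the A fallback. Without blue
#' changepoints: green transients give I, a large blue range gives B, and a
#' low versus high red mean after `red_mean_frame` separates K from J.
#'
#' @param fp a [fingerprint()] object; its `after_frames` must include
#'   `red_mean_frame`
#' @param params a [tree_params()] object
#' @return list with `category` (one of [behavior_categories()]) and `path`,
#'   the ordered character vector of branch decisions taken (replaying it
#'   reproduces the label)
#' @export
classify_cell <- function(fp, params = tree_params()) {
  stopifnot(inherits(fp, "cell_fingerprint"), inherits(params, "tree_params"))
  red_key <- as.character(params$red_mean_frame)
  if (!red_key %in% names(fp$stats$red$mean_after)) {
    stop("fingerprint missing red mean after frame ", params$red_mean_frame,
         "; recompute with after_frames = ", params$red_mean_frame)
  }
  if (is.na(fp$stats$red$mean_after[[red_key]])) {
    stop("trace has no frames after frame ", params$red_mean_frame,
         "; cannot evaluate the red-mean branch")
  }
  path <- character(0)
  note <- function(lbl, yes) {
    path[length(path) + 1L] <<- paste0(lbl, "=", if (yes) "yes" else "no")
    yes
  }
  b <- fp$stats$blue
  n_bcp <- nrow(fp$changepoints$blue)
  first_bcp <- if (n_bcp > 0) fp$changepoints$blue$index[1] else NA
  n_gpk <- nrow(fp$peaks$green)
  first_gpk <- if (n_gpk > 0) fp$peaks$green$location[1] else NA

  finish <- function(category) list(category = category, path = path)

  if (note("blue_starts_elevated",
           b$max > params$elevated_blue_max &&
           b$argmax < params$elevated_blue_argmax_frame)) {
    return(finish("A"))
  }
  if (note("has_blue_changepoints", n_bcp > 0)) {
    if (note("multilevel", n_bcp > params$multilevel_changepoint_count)) {
      return(finish("L"))
    }
    if (note("red_blue_diff_high",
             fp$red_blue_mean_diff > params$red_blue_mean_diff)) {
      return(finish("E"))
    }
    if (note("has_green_peaks", n_gpk > 0)) {
      if (note("green_peak_before_blue_changepoint", first_gpk < first_bcp)) {
        return(finish("H"))
      }
      return(finish("G"))
    }
    if (note("late_increase",
             b$argmax > params$late_argmax_frame &&
             first_bcp > params$late_changepoint_frame)) {
      if (note("has_green_changepoint", nrow(fp$changepoints$green) > 0)) {
        return(finish("F"))
      }
      return(finish("D"))
    }
    if (note("has_blue_peaks", nrow(fp$peaks$blue) > 0)) {
      return(finish("C"))
    }
    if (note("plateau_after_max",
             b$range_after_argmax < params$plateau_range_after_max)) {
      return(finish("B"))
    }
    return(finish("A"))  # second route to A, kept as its own decision path
  }
  if (note("has_green_peaks", n_gpk > 0)) {
    return(finish("I"))
  }
  if (note("blue_range_high", b$range > params$blue_rise_range)) {
    return(finish("B"))
  }
  if (note("red_mean_low",
           fp$stats$red$mean_after[[red_key]] < params$red_mean_low)) {
    return(finish("K"))
  }
  finish("J")
}

#' Classify every fingerprint of a data set
#'
#' Applies [classify_cell()] independently to each cell; the result does not
#' depend on input order.
#'
#' @param fps named list of fingerprints from [fingerprint_cells()]
#' @param params a [tree_params()] object
#' @return object of class `classification_result`: data.frame `cells`
#'   (`cell_id`, `category`, `decision_path`) plus a `counts` table over the
#'   twelve categories
#' @export
classify_all <- function(fps, params = tree_params()) {
  ids <- names(fps) %||% as.character(seq_along(fps) - 1L)
  rows <- lapply(seq_along(fps), function(i) {
    r <- tryCatch(classify_cell(fps[[i]], params),
                  error = function(e) {
                    stop("cell ", ids[i], ": ", conditionMessage(e),
                         call. = FALSE)
                  })
    data.frame(cell_id = ids[i], category = r$category,
               decision_path = paste(r$path, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), category = character(0),
               decision_path = character(0))
  counts <- table(factor(cells$category, levels = behavior_categories()))
  structure(list(cells = cells, counts = counts, params = params),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result:", nrow(x$cells), "cells\n")
  print(x$counts)
  invisible(x)
}

#' Score a classification against ground-truth labels
#'
#' Per-category accuracy is the number of true positives divided by the
#' number of cells whose true label is that category; categories absent from
#' the truth are reported as `NA` (undefined), not 0. Total accuracy is the
#' overall fraction of correctly labeled cells.
#'
#' @param predicted a [classify_all()] result, or a data.frame with
#'   `cell_id` and `category`
#' @param truth data.frame with `cell_id` and `category` (same cell ids)
#' @return list with `per_category` (data.frame: category, accuracy,
#'   n_truth), `total_accuracy`, `n_correct`, `n_total`
#' @export
score_classification <- function(predicted, truth) {
  pred <- if (inherits(predicted, "classification_result")) predicted$cells
          else as.data.frame(predicted)
  truth <- as.data.frame(truth)
  pred$cell_id <- as.character(pred$cell_id)
  truth$cell_id <- as.character(truth$cell_id)
  if (!setequal(pred$cell_id, truth$cell_id) ||
      nrow(pred) != nrow(truth)) {
    stop("predicted and truth cell_id sets differ")
  }
  m <- merge(pred[, c("cell_id", "category")],
             truth[, c("cell_id", "category")],
             by = "cell_id", suffixes = c("_pred", "_true"))
  cats <- behavior_categories()
  per <- data.frame(category = cats,
                    accuracy = NA_real_,
                    n_truth = 0L)
  for (i in seq_along(cats)) {
    in_cat <- m$category_true == cats[i]
    per$n_truth[i] <- sum(in_cat)
    if (per$n_truth[i] > 0) {
      per$accuracy[i] <- sum(in_cat & m$category_pred == cats[i]) /
        per$n_truth[i]
    }
  }
  n_correct <- sum(m$category_pred == m$category_true)
  list(per_category = per,
       total_accuracy = n_correct / nrow(m),
       n_correct = n_correct,
       n_total = nrow(m))
}

#' Write a classification and its accuracy report as CSV
#'
#' `labels` CSV columns: cell_id, category, decision_path. The report CSV
#' mirrors the per-category accuracy table (Category, Accuracy, Total Cells)
#' with a final total row.
#'
#' @param result a [classify_all()] result
#' @param path labels CSV path
#' @param score optional [score_classification()] result
#' @param report_path accuracy report CSV path (required when `score` given)
#' @return `path`, invisibly
#' @export
write_labels <- function(result, path, score = NULL, report_path = NULL) {
  utils::write.csv(result$cells, path, row.names = FALSE)
  if (!is.null(score)) {
    stopifnot(!is.null(report_path))
    rep_df <- data.frame(Category = score$per_category$category,
                         Accuracy = score$per_category$accuracy,
                         Total.Cells = score$per_category$n_truth)
    rep_df <- rbind(rep_df, data.frame(Category = "Total",
                                       Accuracy = score$total_accuracy,
                                       Total.Cells = score$n_total))
    utils::write.csv(rep_df, report_path, row.names = FALSE)
  }
  invisible(path)
}

# --- optional machine-learning benchmark backends -------------------------

# Each backend is an external multivariate time-series classifier wrapped in
# a uniform train/predict contract; the flattened (blue, green, red) series
# is the feature vector. Internals of the classifiers are not re-implemented
# here.
builtin_backend <- function(name) {
  switch(name,
    random_forest = list(
      name = "random_forest",
      train = function(x, y) {
        if (!requireNamespace("randomForest", quietly = TRUE)) {
          stop_capability("backend 'random_forest' needs the randomForest package")
        }
        randomForest::randomForest(x, factor(y))
      },
      predict = function(model, x) as.character(stats::predict(model, x))
    ),
    svm = list(
      name = "svm",
      train = function(x, y) {
        if (!requireNamespace("e1071", quietly = TRUE)) {
          stop_capability("backend 'svm' needs the e1071 package")
        }
        e1071::svm(x, factor(y))
      },
      predict = function(model, x) as.character(stats::predict(model, x))
    ),
    stop_capability(paste0("no such backend: ", name))
  )
}

traces_to_matrix <- function(traces, downsample = 4) {
  df <- as.data.frame(traces)
  df <- df[order(df$cell_id, df$frame), ]
  sp <- split(df, df$cell_id)
  rows <- lapply(sp, function(d) {
    idx <- seq(1, nrow(d), by = downsample)
    c(d$blue[idx], d$green[idx], d$red[idx])
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(sp)
  x
}

#' Benchmark interchangeable time-series classifier backends
#'
#' Harness around external multivariate time-series classifiers: the labeled
#' traces are split into seeded train/test sets, each backend is trained and
#' its test accuracy reported. Optionally the transient-bearing cells (at
#' least one green peak) are split into a separate classification problem,
#' which tends to score higher because transient timing varies from cell to
#' cell.
#'
#' @param traces an `intensity_traces` data.frame
#' @param labels data.frame with `cell_id` and `category`
#' @param backends character vector of built-in backend names
#'   (`"random_forest"`, `"svm"`) or a list of
#'   `list(name =, train = function(x, y), predict = function(model, x))`
#'   adapters; an unavailable backend raises a capability error, never a
#'   silent skip
#' @param split_seed seed for the train/test split
#' @param split_fraction fraction of cells used for training
#' @param split_transients classify transient-bearing and transient-free
#'   cells as two separate problems
#' @param peak a [peak_params()] object (used to detect transients when
#'   `split_transients = TRUE`)
#' @param downsample keep every `downsample`-th frame in the feature vector
#' @return data.frame with columns `backend`, `subset`, `accuracy`,
#'   `n_train`, `n_test`
#' @export
benchmark_backends <- function(traces, labels, backends = "random_forest",
                               split_seed = 1L, split_fraction = 0.5,
                               split_transients = FALSE,
                               peak = peak_params(), downsample = 4) {
  if (length(backends) == 0) stop_capability("no backends registered")
  specs <- lapply(backends, function(b) {
    if (is.character(b)) builtin_backend(b) else b
  })
  x <- traces_to_matrix(traces, downsample)
  labels <- as.data.frame(labels)
  y <- labels$category[match(rownames(x), as.character(labels$cell_id))]
  stopifnot(!anyNA(y))

  subsets <- list(all = seq_len(nrow(x)))
  if (split_transients) {
    df <- as.data.frame(traces)
    df <- df[order(df$cell_id, df$frame), ]
    has_peak <- vapply(split(df$green, df$cell_id), function(g) {
      nrow(find_transients(smooth_trace(g, 20), peak)) > 0
    }, TRUE)
    has_peak <- has_peak[match(rownames(x), names(has_peak))]
    subsets <- list(transient = which(has_peak),
                    no_transient = which(!has_peak))
  }

  out <- list()
  for (sub_name in names(subsets)) {
    idx <- subsets[[sub_name]]
    if (length(idx) < 4) next
    tr_idx <- withr::with_seed(as.integer(split_seed), {
      sample(idx, size = max(2, round(split_fraction * length(idx))))
    })
    te_idx <- setdiff(idx, tr_idx)
    for (spec in specs) {
      model <- spec$train(x[tr_idx, , drop = FALSE], y[tr_idx])
      pred <- spec$predict(model, x[te_idx, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        backend = spec$name, subset = sub_name,
        accuracy = mean(pred == y[te_idx]),
        n_train = length(tr_idx), n_test = length(te_idx))
    }
  }
  do.call(rbind, out)
}
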