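# Brute-force oracles, written independently of the package internals.

# Topographic prominence by definition: for every strict local maximum, walk
# each flank to the nearest strictly higher sample (or border), take the
# minimum en route, and subtract the higher of the two flank minima. Width is
# measured at half prominence by linear interpolation. O(n) per candidate,
# no shared code with find_transients().
oracle_peaks <- function(y, min_prominence = 3, max_ratio = 10) {
  n <- length(y)
  out <- NULL
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) next
    h <- y[i]
    min_l <- Inf
    j <- i - 1
    while (j >= 1 && y[j] <= h) {
      min_l <- min(min_l, y[j])
      j <- j - 1
    }
    min_r <- Inf
    j <- i + 1
    while (j <= n && y[j] <= h) {
      min_r <- min(min_r, y[j])
      j <- j + 1
    }
    base <- max(min(min_l, h), min(min_r, h))
    prom <- h - base
    if (prom < min_prominence) next
    ref <- h - prom / 2
    j <- i
    while (y[j] >= ref) j <- j - 1
    xl <- j + (ref - y[j]) / (y[j + 1] - y[j])
    j <- i
    while (y[j] >= ref) j <- j + 1
    xr <- j - (ref - y[j]) / (y[j - 1] - y[j])
    w <- xr - xl
    if (w / prom > max_ratio) next
    out <- rbind(out, data.frame(location = i - 1L, prominence = prom,
                                 width = w))
  }
  if (is.null(out)) {
    data.frame(location = integer(0), prominence = numeric(0),
               width = numeric(0))
  } else {
    out
  }
}

# Exhaustive single-changepoint least-squares: best split of the trace into
# two independently fitted lines. Returns the 0-based frame at which the
# second segment starts.
oracle_single_changepoint <- function(y, min_seg = 10) {
  n <- length(y)
  t <- seq_len(n) - 1
  best <- NULL
  best_sse <- Inf
  for (k in min_seg:(n - min_seg)) {
    f1 <- stats::lm(y[1:k] ~ t[1:k])
    f2 <- stats::lm(y[(k + 1):n] ~ t[(k + 1):n])
    sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- k
    }
  }
  best  # 1-based last frame of segment 1 == 0-based first frame of segment 2
}

# Windowed moving-average oracle mirroring a centered window that shrinks at
# the trace ends (one more sample behind than ahead for even windows).
oracle_movmean <- function(x, window) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - floor(window / 2))
    hi <- min(n, i + ceiling(window / 2) - 1)
    mean(x[lo:hi])
  }, numeric(1))
}

# Fixture suite of traces for oracle-equivalence checks: all twelve smoothed
# noisy archetypes plus a few hand shapes.
fixture_traces <- function(n_frames = 300, seed = 99) {
  traces <- list()
  for (cat in behavior_categories()) {
    tr <- trace_template(cat, n_frames, noise_sd = 1, seed = seed)
    traces[[paste0(cat, "_green")]] <- smooth_trace(tr$green, 20)
    traces[[paste0(cat, "_blue")]] <- smooth_trace(tr$blue, 20)
    seed <- seed + 1
  }
  t <- 0:(n_frames - 1)
  traces$two_bumps <- 1 + 8 * exp(-(t - 80)^2 / 50) + 5 * exp(-(t - 200)^2 / 32)
  traces$noisy_flat <- withr::with_seed(7, rnorm(n_frames, 5, 0.8))
  traces
}

# Small rendered fixture used by several modules.
tiny_scene <- function(n_cells = 12, n_frames = 150, field = 96,
                       seed = 11, noise = 0, ...) {
  sp <- scenario_params(n_cells = n_cells, frame_count = n_frames,
                        field_size = field, seed = seed, ...)
  scene <- make_scene(sp)
  stack <- render_stack(scene, render_params(background_level = 5,
                                             camera_noise_sd = noise))
  list(scene = scene, stack = stack)
}
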