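#' The twelve cell behavior categories
#'
#' Single-letter codes for the twelve temporal behavior archetypes seen in
#' three-channel (blue = nuclear membrane permeability, green = cytosolic
#' calcium, red = mitochondrial polarity) fluorescence traces of cells in
#' mechanically stimulated tissue:
#'
#' * `A` permeability starts elevated and decays
#' * `B` permeability increases early and plateaus (or keeps rising)
#' * `C` permeability increases early, then decays
#' * `D` permeability increases late, with no visible trigger
#' * `E` permeability increases although mitochondria stay polarized
#' * `F` sustained calcium drops, then permeability increases
#' * `G` calcium transient after permeability is already elevated
#' * `H` calcium transient followed by a permeability increase
#' * `I` calcium transient(s) only, permeability stays low
#' * `J` normal cell: all quiet, mitochondria polarized
#' * `K` all three signals low, mitochondria depolarized
#' * `L` permeability steps through multiple levels
#'
#' @return character vector of the twelve category codes
#' @export
behavior_categories <- function() LETTERS[1:12]

#' Default category frequencies
#'
#' Relative frequencies of the twelve behaviors as observed in impacted
#' cartilage explants (normal quiet cells dominate; late or multi-level
#' permeability changes are rare). Used as the default `category_weights`
#' of [scenario_params()].
#'
#' @return named numeric vector of 12 proportions summing to 1
#' @export
default_category_weights <- function() {
  counts <- c(A = 313, B = 151, C = 748, D = 11, E = 63, F = 60,
              G = 41, H = 73, I = 524, J = 3244, K = 101, L = 18)
  counts / sum(counts)
}

#' Synthetic scenario parameters
#'
#' Parameters of a ground-truth scene: how many cells, for how long, on what
#' pixel grid, with which behavior mix and motion.
#'
#' @param n_cells number of cells to place
#' @param frame_count number of frames (>= 2; behavior templates need >= 150)
#' @param frame_interval seconds between frames (long-term cadence; the
#'   imaging protocol this emulates used 10-20 s)
#' @param field_size square field side, pixels
#' @param pixel_size micrometres per pixel
#' @param category_weights 12 non-negative proportions, normalized internally
#' @param impact_center `(x, y)` pixel coordinates of the impact site, or
#'   `NULL` for no spatial structure
#' @param impact_radius_um radius around the impact site within which
#'   death-associated behaviors (B, C) are concentrated; default 400 um
#' @param motion_model either `list(type = "static")` or
#'   `list(type = "relaxation_drift", amplitude = 6, decay = 40)`; under
#'   relaxation drift every cell starts displaced along the radial direction
#'   from the impact center and relaxes exponentially (decay in frames)
#'   toward its rest position, emulating tissue relaxation after impact
#' @param noise_sd additive Gaussian noise sd on the per-cell true traces,
#'   arbitrary intensity units (a.u.); 0 keeps the ground-truth traces
#'   noise-free (camera noise is added separately at render time)
#' @param spot_sigma Gaussian spot sd, pixels (cell image of roughly 10 px
#'   diameter at 1.29 um/px)
#' @param min_separation minimum center-to-center distance between cells,
#'   pixels; keeps 3x3 extraction windows disjoint
#' @param seed integer seed controlling all scene randomness
#' @return object of class `scenario_params`
#' @export
scenario_params <- function(n_cells = 1000,
                            frame_count = 300,
                            frame_interval = 20,
                            field_size = 512,
                            pixel_size = 660 / 512,
                            category_weights = default_category_weights(),
                            impact_center = NULL,
                            impact_radius_um = 400,
                            motion_model = list(type = "relaxation_drift",
                                                amplitude = 6, decay = 40),
                            noise_sd = 0,
                            spot_sigma = 2,
                            min_separation = 8,
                            seed = 1L) {
  stopifnot(n_cells >= 0, frame_count >= 2, field_size >= 16,
            pixel_size > 0, length(category_weights) == 12,
            all(category_weights >= 0), sum(category_weights) > 0,
            noise_sd >= 0, spot_sigma > 0, min_separation > 0)
  if (!is.null(impact_center)) stopifnot(length(impact_center) == 2)
  motion_model$type <- match.arg(motion_model$type,
                                 c("static", "relaxation_drift"))
  w <- category_weights / sum(category_weights)
  names(w) <- behavior_categories()
  structure(list(
    n_cells = as.integer(n_cells), frame_count = as.integer(frame_count),
    frame_interval = frame_interval, field_size = as.integer(field_size),
    pixel_size = pixel_size, category_weights = w,
    impact_center = impact_center, impact_radius_um = impact_radius_um,
    motion_model = motion_model, noise_sd = noise_sd,
    spot_sigma = spot_sigma, min_separation = min_separation,
    seed = as.integer(seed)
  ), class = "scenario_params")
}

# Piecewise building blocks for the behavior templates. All take the 0-based
# frame vector `t` and return an intensity vector on the canonical
# background-subtracted a.u. scale.
tmpl_flat <- function(t, level) rep(level, length(t))
tmpl_decay <- function(t, from, to, tau, start = 0) {
  to + (from - to) * exp(-pmax(t - start, 0) / tau)
}
tmpl_step <- function(t, at, lo, hi) ifelse(t < at, lo, hi)
tmpl_bump <- function(t, center, sigma, amp, base = 0) {
  base + amp * exp(-(t - center)^2 / (2 * sigma^2))
}

#' Noise-free three-channel template for one behavior category
#'
#' Builds the blue/green/red trace archetype of a behavior category on the
#' canonical background-subtracted intensity scale, on which the default
#' decision-tree thresholds (7, 20, 8, 10, 6, peak prominence 3) are
#' meaningful. Event amplitudes exceed every threshold the category's
#' decision path touches by the factor `margin` (default 2), so the
#' noise-free template survives smoothing, rendering and re-extraction and is
#' still classified into its generating category.
#'
#' Event timing follows the frame conventions of the default decision tree
#' at the long-term cadence: "early" permeability steps are placed so their
#' first changepoint lands well before frame 100, "late" steps so the blue
#' maximum falls after frame 120 and the changepoint after frame 100.
#'
#' @param category one of [behavior_categories()]
#' @param frame_count number of frames, >= 150 (events are placed relative to
#'   the frame-100/120 early-late boundary)
#' @param noise_sd additive i.i.d. Gaussian noise sd (a.u.) applied to all
#'   three channels; 0 returns the noise-free archetype
#' @param seed integer seed for the noise draw
#' @param margin multiple by which event amplitudes exceed the corresponding
#'   classification thresholds
#' @return list with numeric vectors `blue`, `green`, `red` (length
#'   `frame_count`) and the `category` code
#' @export
trace_template <- function(category, frame_count, noise_sd = 0, seed = 1L,
                           margin = 2) {
  category <- as.character(category)
  if (!category %in% behavior_categories()) {
    stop("unknown behavior category: ", category)
  }
  n <- as.integer(frame_count)
  if (n < 150L) {
    stop("frame_count must be >= 150 to host the category-defining events")
  }
  stopifnot(noise_sd >= 0, margin > 0)
  t <- seq_len(n) - 1  # 0-based frames

  b0 <- 1; g0 <- 2                      # baselines, a.u.
  r_hi <- 30; r_lo <- 2                 # polarized / depolarized red levels
  step_amp <- 10 * margin               # blue permeability step height
  peak_amp <- 6 * margin                # raw green transient amplitude
  peak_sigma <- 5                       # green transient width (frames)
  late_step <- min(100L + round(n / 5), n - 30L)  # "late" blue step frame

  blue <- tmpl_flat(t, b0)
  green <- tmpl_flat(t, g0)
  red <- tmpl_flat(t, r_hi)

  if (category == "A") {
    blue <- tmpl_decay(t, 12.5 * margin, 1, 60)
    red <- tmpl_decay(t, r_hi, r_lo, 60)
  } else if (category == "B") {
    blue <- tmpl_step(t, 60, b0, b0 + step_amp)
    red <- tmpl_decay(t, r_hi, 3, 60, start = 60)
  } else if (category == "C") {
    peak <- 12.5 * margin
    blue <- ifelse(t < 60, b0, peak - (peak - 6) * (t - 60) / (n - 1 - 60))
    red <- tmpl_decay(t, r_hi, 3, 60, start = 60)
  } else if (category == "D") {
    blue <- tmpl_step(t, late_step, b0, b0 + step_amp)
    red <- tmpl_decay(t, r_hi, 5, 60, start = late_step)
  } else if (category == "E") {
    blue <- tmpl_step(t, 60, b0, b0 + step_amp)
    # red level chosen so mean(red - blue) ~= margin * the 20 a.u. threshold
    red <- tmpl_flat(t, mean(blue) + 20 * margin)
  } else if (category == "F") {
    blue <- tmpl_step(t, late_step, b0, b0 + step_amp)
    green <- tmpl_step(t, late_step - 30, 15, g0)
    red <- tmpl_decay(t, r_hi, 4, 60, start = late_step)
  } else if (category == "G") {
    blue <- tmpl_step(t, 50, b0, b0 + step_amp)
    green <- tmpl_bump(t, round(n / 2), peak_sigma, peak_amp, g0)
    red <- tmpl_decay(t, r_hi, 4, 60, start = 50)
  } else if (category == "H") {
    blue <- tmpl_step(t, 90, b0, b0 + step_amp)
    green <- tmpl_bump(t, 40, peak_sigma, peak_amp, g0)
    red <- tmpl_decay(t, r_hi, 4, 60, start = 90)
  } else if (category == "I") {
    green <- g0 + peak_amp * (exp(-(t - 60)^2 / (2 * peak_sigma^2)) +
                              exp(-(t - round(0.4 * n))^2 / (2 * peak_sigma^2)))
  } else if (category == "J") {
    # all defaults: quiet cell, polarized mitochondria
  } else if (category == "K") {
    green <- tmpl_flat(t, 1)
    red <- tmpl_flat(t, r_lo)
  } else if (category == "L") {
    lvl <- step_amp / 2
    blue <- b0 + lvl * ((t >= 50) + (t >= round(0.43 * n)) + (t >= 210))
    red <- tmpl_decay(t, r_hi, 3, 60, start = 50)
  }

  out <- list(blue = blue, green = green, red = red)
  if (noise_sd > 0) {
    out <- withr::with_seed(as.integer(seed), {
      lapply(out, function(v) v + stats::rnorm(n, 0, noise_sd))
    })
  }
  out$category <- category
  out
}

# Seeded rejection sampling of cell rest positions. Death-associated
# categories (B, C) are preferentially placed within the impact radius and
# normal cells (J) outside it, emulating the spatial layout of impacted
# tissue. Positions are 0-based pixel coordinates.
place_cells <- function(categories, params) {
  n <- length(categories)
  fs <- params$field_size
  margin <- max(10, ceiling(4 * params$spot_sigma) + 2)
  if (!is.null(params$motion_model$amplitude)) {
    margin <- margin + ceiling(params$motion_model$amplitude)
  }
  lo <- margin
  hi <- fs - 1 - margin
  if (hi <= lo) stop("field_size too small for placement margins")
  minsep2 <- params$min_separation^2
  radius_px <- params$impact_radius_um / params$pixel_size
  center <- params$impact_center
  p_zone <- 0.9  # probability a zone-biased cell lands in its target zone

  xs <- numeric(n)
  ys <- numeric(n)
  max_attempts <- 200L * max(n, 1L)
  attempts <- 0L
  for (i in seq_len(n)) {
    zone <- "any"
    if (!is.null(center)) {
      if (categories[i] %in% c("B", "C") && stats::runif(1) < p_zone) {
        zone <- "inside"
      } else if (categories[i] == "J" && stats::runif(1) < p_zone) {
        zone <- "outside"
      }
    }
    cell_attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      cell_attempts <- cell_attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n, " cells at min_separation ",
             params$min_separation, " px; reduce n_cells or separation")
      }
      # a zone may be unsatisfiable (e.g. the impact radius covers the whole
      # field); relax it after enough failed draws, keeping the separation
      if (cell_attempts > 50L) zone <- "any"
      x <- stats::runif(1, lo, hi)
      y <- stats::runif(1, lo, hi)
      if (zone != "any") {
        d2c <- sqrt((x - center[1])^2 + (y - center[2])^2)
        if (zone == "inside" && d2c > radius_px) next
        if (zone == "outside" && d2c <= radius_px) next
      }
      if (i > 1) {
        d2 <- (xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2
        if (min(d2) < minsep2) next
      }
      xs[i] <- x
      ys[i] <- y
      break
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a ground-truth synthetic scene
#'
#' Draws cell behavior categories from the scenario's category weights,
#' places cells with a minimum separation (biasing death-associated
#' behaviors toward the impact site when one is given), builds per-cell
#' trajectories under the motion model, and attaches the per-category
#' three-channel trace archetypes. The same seed always produces an
#' identical scene.
#'
#' @param params a [scenario_params()] object
#' @return object of class `synthetic_scene`: list with `cells` (a list of
#'   per-cell records: `cell_id`, `category`, `trajectory` frame-by-frame
#'   `(x, y)` matrix, `traces` list of blue/green/red vectors, `spot_sigma`)
#'   and `params`
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed, {
    n <- params$n_cells
    cats <- if (n > 0) {
      sample(behavior_categories(), n, replace = TRUE,
             prob = params$category_weights)
    } else character(0)
    pos <- place_cells(cats, params)
    t <- seq_len(params$frame_count) - 1

    # relaxation drift: displaced along the radial direction at t = 0,
    # relaxing exponentially toward the rest position
    mm <- params$motion_model
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      if (mm$type == "relaxation_drift") {
        if (!is.null(params$impact_center)) {
          d <- pos[i, ] - params$impact_center
          nrm <- sqrt(sum(d^2))
          u <- if (nrm > 0) d / nrm else c(1, 0)
          radius_px <- params$impact_radius_um / params$pixel_size
          amp <- mm$amplitude * exp(-nrm / (2 * radius_px))
        } else {
          u <- c(cos(pi / 4), sin(pi / 4))
          amp <- mm$amplitude
        }
        relax <- exp(-t / mm$decay)
        traj <- cbind(x = pos[i, 1] + amp * u[1] * relax,
                      y = pos[i, 2] + amp * u[2] * relax)
      } else {
        traj <- cbind(x = rep(pos[i, 1], params$frame_count),
                      y = rep(pos[i, 2], params$frame_count))
      }
      tr <- trace_template(cats[i], params$frame_count,
                           noise_sd = params$noise_sd,
                           seed = params$seed + i)
      cells[[i]] <- list(
        cell_id = i - 1L,  # 0-based ids for CSV interchange
        category = cats[i],
        trajectory = traj,
        traces = list(blue = pmax(tr$blue, 0), green = pmax(tr$green, 0),
                      red = pmax(tr$red, 0)),
        spot_sigma = params$spot_sigma
      )
    }
    structure(list(cells = cells, params = params), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cats <- vapply(x$cells, `[[`, "", "category")
  cat("synthetic_scene:", length(x$cells), "cells,",
      x$params$frame_count, "frames,",
      x$params$field_size, "x", x$params$field_size, "px\n")
  if (length(cats)) print(table(factor(cats, behavior_categories())))
  invisible(x)
}

#' Ground-truth table of a synthetic scene
#'
#' Long-format table of the scene's ground truth: one row per cell and frame
#' with the true position, category and noise-free channel intensities.
#' 0-based frames and pixel coordinates.
#'
#' @param scene a [make_scene()] result
#' @return data.frame with columns cell_id, frame, x, y, category,
#'   blue, green, red
#' @export
scene_truth <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n_frames <- scene$params$frame_count
  do.call(rbind, lapply(scene$cells, function(cl) {
    data.frame(
      cell_id = cl$cell_id,
      frame = seq_len(n_frames) - 1L,
      x = cl$trajectory[, "x"],
      y = cl$trajectory[, "y"],
      category = cl$category,
      blue = cl$traces$blue,
      green = cl$traces$green,
      red = cl$traces$red,
      row.names = NULL
    )
  }))
}
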