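#' Rendering parameters for synthetic image stacks
#'
#' @param background_level uniform background intensity, a.u.
#' @param background_gradient optional `field_size x field_size` matrix of
#'   additive per-pixel background offsets (a.u.), applied to every channel
#'   and frame; emulates locally elevated background
#' @param leak_halo optional stain-leak halo around the impact site:
#'   `list(amplitude =, radius =)` (a.u., px). Requires the scene to have an
#'   impact center. Emulates stain leaking into the matrix near the injury.
#' @param camera_noise_sd additive Gaussian camera noise sd, a.u.
#' @param bit_depth 8 or 16; with `quantize = TRUE` rendered values are
#'   rounded to integer digital numbers and clipped at `2^bit_depth - 1`
#' @param quantize round to integer intensities and clip at the bit depth;
#'   saturated pixels are counted and reported on the stack, never silently
#' @return object of class `render_params`
#' @export
render_params <- function(background_level = 5,
                          background_gradient = NULL,
                          leak_halo = NULL,
                          camera_noise_sd = 0,
                          bit_depth = 16,
                          quantize = FALSE) {
  stopifnot(background_level >= 0, camera_noise_sd >= 0,
            bit_depth %in% c(8, 16))
  if (!is.null(leak_halo)) {
    stopifnot(leak_halo$amplitude >= 0, leak_halo$radius > 0)
  }
  structure(list(background_level = background_level,
                 background_gradient = background_gradient,
                 leak_halo = leak_halo,
                 camera_noise_sd = camera_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 quantize = isTRUE(quantize)),
            class = "render_params")
}

#' Build an image stack from per-frame channel matrices
#'
#' Container for a T-frame, three-channel (blue, green, red) image stack
#' with acquisition metadata. [render_stack()] and [read_stack()] return
#' this class; use this constructor to wrap externally acquired data.
#'
#' @param frames list of frames, each a named list of `blue`, `green`, `red`
#'   intensity matrices of identical size
#' @param pixel_size micrometres per pixel
#' @param frame_interval seconds between frames
#' @param seed generating seed, if any (metadata only)
#' @param saturated count of saturated pixels, if known
#' @return object of class `image_stack`
#' @export
image_stack <- function(frames, pixel_size = 1, frame_interval = 1,
                        seed = NULL, saturated = 0L) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]][["blue"]])
  for (fr in frames) {
    stopifnot(all(c("blue", "green", "red") %in% names(fr)),
              all(dim(fr$blue) == d), all(dim(fr$green) == d),
              all(dim(fr$red) == d))
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, seed = seed,
                 saturated = as.integer(saturated)),
            class = "image_stack")
}

new_image_stack <- function(frames, pixel_size, frame_interval, seed = NULL,
                            saturated = 0L) {
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, seed = seed,
                 saturated = as.integer(saturated)),
            class = "image_stack")
}

#' Number of frames in an image stack
#' @param stack an `image_stack`
#' @return integer frame count
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  length(stack$frames)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]][[1]])
  cat("image_stack:", length(x$frames), "frames x 3 channels,",
      d[1], "x", d[2], "px,",
      "pixel", signif(x$pixel_size, 4), "um,",
      "interval", x$frame_interval, "s\n")
  if (x$saturated > 0) cat("  saturated pixels:", x$saturated, "\n")
  invisible(x)
}

# Add one Gaussian spot to a matrix in place (returns the modified matrix).
# x, y are 0-based pixel coordinates; the spot is truncated at 4 sigma.
add_spot <- function(m, x, y, sigma, amplitude) {
  if (amplitude <= 0) return(m)
  h <- nrow(m)
  w <- ncol(m)
  r <- ceiling(4 * sigma)
  cx <- x + 1  # 1-based
  cy <- y + 1
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(m)
  gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
  gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
  m[y0:y1, x0:x1] <- m[y0:y1, x0:x1] + amplitude * outer(gy, gx)
  m
}

#' Render a synthetic scene into a multichannel image stack
#'
#' Each cell is drawn as an isotropic Gaussian spot in every channel, with
#' peak amplitude equal to the cell's true trace value at that frame, added
#' on top of the background. Camera noise, an optional background gradient
#' and an optional stain-leak halo can be enabled via [render_params()].
#' Rendering is deterministic given the scene (noise is seeded from the
#' scene seed).
#'
#' @param scene a [make_scene()] result
#' @param render a [render_params()] object
#' @return an `image_stack`: per frame a list of blue/green/red intensity
#'   matrices plus pixel size and frame interval metadata. If quantization
#'   saturated any pixels their count is recorded in `$saturated` and a
#'   warning is raised.
#' @export
render_stack <- function(scene, render = render_params()) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(render, "render_params"))
  p <- scene$params
  fs <- p$field_size
  nT <- p$frame_count
  channels <- c("blue", "green", "red")

  base <- matrix(render$background_level, fs, fs)
  if (!is.null(render$background_gradient)) {
    stopifnot(all(dim(render$background_gradient) == c(fs, fs)))
    base <- base + render$background_gradient
  }
  if (!is.null(render$leak_halo)) {
    if (is.null(p$impact_center)) {
      stop("leak_halo requires the scene to have an impact_center")
    }
    xx <- matrix(rep(0:(fs - 1), each = fs), fs, fs)
    yy <- matrix(rep(0:(fs - 1), times = fs), fs, fs)
    r2 <- (xx - p$impact_center[1])^2 + (yy - p$impact_center[2])^2
    base <- base + render$leak_halo$amplitude *
      exp(-r2 / (2 * render$leak_halo$radius^2))
  }

  max_dn <- 2^render$bit_depth - 1
  saturated <- 0L
  frames <- withr::with_seed(p$seed + 7654321L, {
    lapply(seq_len(nT), function(f) {
      fr <- stats::setNames(vector("list", 3), channels)
      for (ch in channels) {
        m <- base
        for (cl in scene$cells) {
          m <- add_spot(m, cl$trajectory[f, "x"], cl$trajectory[f, "y"],
                        cl$spot_sigma, cl$traces[[ch]][f])
        }
        if (render$camera_noise_sd > 0) {
          m <- m + matrix(stats::rnorm(fs * fs, 0, render$camera_noise_sd),
                          fs, fs)
        }
        if (render$quantize) {
          m <- round_half_away(m)
          m[m < 0] <- 0
          over <- m > max_dn
          if (any(over)) {
            saturated <<- saturated + sum(over)
            m[over] <- max_dn
          }
        }
        fr[[ch]] <- m
      }
      fr
    })
  })
  if (saturated > 0) {
    warning(saturated, " pixels saturated at bit depth ", render$bit_depth)
  }
  new_image_stack(frames, p$pixel_size, p$frame_interval, seed = p$seed,
                  saturated = saturated)
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major with channels blue, green, red within each
#' frame. Intensities are stored as 16-bit integers after scaling by the
#' stack maximum; the scale factor and acquisition metadata (pixel size,
#' frame interval, seed) go to `<path>.json` so [read_stack()] can restore
#' the original values.
#'
#' @param stack an `image_stack`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vmax <- max(vapply(stack$frames,
                     function(fr) max(vapply(fr, max, 0)), 0))
  vmin <- min(vapply(stack$frames,
                     function(fr) min(vapply(fr, min, 0)), 0))
  vscale <- max(vmax - vmin, 1e-12)
  pages <- list()
  for (fr in stack$frames) {
    for (ch in c("blue", "green", "red")) {
      pages[[length(pages) + 1L]] <- (fr[[ch]] - vmin) / vscale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               seed = stack$seed,
               n_frames = length(stack$frames),
               channels = c("blue", "green", "red"),
               intensity_scale = vscale,
               intensity_offset = vmin,
               saturated = stack$saturated)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside it
#' @return an `image_stack`
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nT <- meta$n_frames
  stopifnot(length(pages) == 3 * nT)
  off <- meta$intensity_offset %||% 0
  frames <- lapply(seq_len(nT), function(f) {
    idx <- (f - 1) * 3
    list(blue = pages[[idx + 1]] * meta$intensity_scale + off,
         green = pages[[idx + 2]] * meta$intensity_scale + off,
         red = pages[[idx + 3]] * meta$intensity_scale + off)
  })
  new_image_stack(frames, meta$pixel_size, meta$frame_interval,
                  seed = meta$seed, saturated = meta$saturated %||% 0L)
}
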