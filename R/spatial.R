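#' Imaging region layout
#'
#' Rectangular imaging regions laid out on a common coordinate system, used
#' to book-keep multiple fields of view: region 1 covers the impact site,
#' region 2 lies lateral to it, region 3 below it, and regions 4-5 are on
#' the unimpacted control. Offsets between fields are instrument-specific,
#' so the layout is plain configuration.
#'
#' @param regions data.frame with columns `region`, `x0`, `y0`, `x1`, `y1`
#'   (half-open rectangles, `[x0, x1)` by `[y0, y1)`, px)
#' @return data.frame of class `region_layout`
#' @export
region_layout <- function(regions) {
  stopifnot(all(c("region", "x0", "y0", "x1", "y1") %in% names(regions)),
            all(regions$x1 > regions$x0), all(regions$y1 > regions$y0))
  structure(as.data.frame(regions), class = c("region_layout", "data.frame"))
}

#' Assign positions to imaging regions
#'
#' Deterministic containment test against a [region_layout()]. A position on
#' a shared boundary goes to the lower-indexed (earlier listed) region;
#' positions outside all regions get the sentinel `"unassigned"`.
#'
#' @param x,y numeric position vectors, px
#' @param layout a [region_layout()]
#' @return character vector of region ids (or `"unassigned"`)
#' @export
assign_region <- function(x, y, layout) {
  stopifnot(inherits(layout, "region_layout"), length(x) == length(y))
  out <- rep("unassigned", length(x))
  for (i in rev(seq_len(nrow(layout)))) {
    inside <- x >= layout$x0[i] & x < layout$x1[i] &
              y >= layout$y0[i] & y < layout$y1[i]
    out[inside] <- as.character(layout$region[i])
  }
  out
}

#' Per-category spatial count maps
#'
#' Bins every labeled cell by its position at a reference frame into a
#' per-category 2-D count grid (half-open bins, `[lo, hi)`), the substrate
#' for behavior heat maps. Each category's grid sums to the number of cells
#' carrying that label, and maps are independent of cell input order.
#' Colorbar maxima are left to the plotting step so sparse categories stay
#' visible.
#'
#' @param labels data.frame with `cell_id` and `category` (or a
#'   [classify_all()] result)
#' @param tracks a `cell_tracks` data.frame holding a position (detected,
#'   interpolated or extended) for every labeled cell at `reference_frame`
#' @param bin_size bin side, px
#' @param field_size field side, px (bins span `[0, field_size)`)
#' @param reference_frame 0-based frame whose positions are used; default is
#'   the last frame (cells are static by then)
#' @param layout optional [region_layout()]; when given, each cell's region
#'   id is recorded in the returned `positions` table
#' @return object of class `spatial_map`: list with `grids` (named list of
#'   count matrices, rows = y bins, cols = x bins), `bin_size`,
#'   `reference_frame`, and `positions` (cell_id, x, y, category, region)
#' @export
category_map <- function(labels, tracks, bin_size = 64, field_size = 512,
                         reference_frame = NULL, layout = NULL) {
  lab <- if (inherits(labels, "classification_result")) labels$cells
         else as.data.frame(labels)
  stopifnot(all(c("cell_id", "category") %in% names(lab)), bin_size > 0)
  tdf <- as.data.frame(tracks)
  if (is.null(reference_frame)) reference_frame <- max(tdf$frame)
  at_ref <- tdf[tdf$frame == reference_frame, ]
  pos_idx <- match(as.character(lab$cell_id), as.character(at_ref$cell_id))
  if (anyNA(pos_idx)) {
    missing <- lab$cell_id[is.na(pos_idx)]
    stop("labeled cell(s) without a position at frame ", reference_frame,
         ": ", paste(utils::head(missing, 5), collapse = ", "))
  }
  pos <- data.frame(cell_id = lab$cell_id,
                    x = at_ref$x[pos_idx], y = at_ref$y[pos_idx],
                    category = lab$category, stringsAsFactors = FALSE)
  if (!is.null(layout)) pos$region <- assign_region(pos$x, pos$y, layout)

  nb <- ceiling(field_size / bin_size)
  bx <- pmin(floor(pos$x / bin_size), nb - 1) + 1L
  by <- pmin(floor(pos$y / bin_size), nb - 1) + 1L
  grids <- lapply(behavior_categories(), function(cat) {
    g <- matrix(0L, nb, nb)
    sel <- which(pos$category == cat)
    for (i in sel) g[by[i], bx[i]] <- g[by[i], bx[i]] + 1L
    g
  })
  names(grids) <- behavior_categories()
  structure(list(grids = grids, bin_size = bin_size,
                 reference_frame = reference_frame, positions = pos,
                 field_size = field_size, layout = layout),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  totals <- vapply(x$grids, sum, 0L)
  cat("spatial_map:", sum(totals), "cells in",
      nrow(x$grids[[1]]), "x", ncol(x$grids[[1]]), "bins of",
      x$bin_size, "px (positions at frame", x$reference_frame, ")\n")
  print(totals)
  invisible(x)
}

#' Write spatial maps as CSV matrices
#'
#' One CSV per category (`<prefix>_<category>.csv`), each a plain count
#' matrix (rows = y bins), plus `<prefix>_positions.csv` with the binned
#' cell positions. A layout, when present, goes to `<prefix>_layout.json`.
#'
#' @param map a [category_map()] result
#' @param prefix output path prefix
#' @return character vector of written paths, invisibly
#' @export
write_category_map <- function(map, prefix) {
  stopifnot(inherits(map, "spatial_map"))
  paths <- character(0)
  for (cat in names(map$grids)) {
    p <- paste0(prefix, "_", cat, ".csv")
    utils::write.table(map$grids[[cat]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_positions.csv")
  utils::write.csv(map$positions, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(map$layout)) {
    p <- paste0(prefix, "_layout.json")
    jsonlite::write_json(as.data.frame(map$layout), p, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot one category's count heat map
#'
#' Simple base-graphics heat map of a category grid; the color scale runs to
#' that category's own maximum so sparse behaviors remain visible.
#'
#' @param map a [category_map()] result
#' @param category category code
#' @param file optional PNG path; when given the plot is written there
#' @return the count matrix, invisibly
#' @export
plot_category_map <- function(map, category, file = NULL) {
  stopifnot(inherits(map, "spatial_map"),
            category %in% names(map$grids))
  g <- map$grids[[category]]
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(32, "inferno")
  # transpose/flip so the plot matches image coordinates (y down)
  graphics::image(t(g)[, rev(seq_len(nrow(g))), drop = FALSE],
                  col = pal, axes = FALSE,
                  main = paste0("category ", category,
                                " (n = ", sum(g), ")"))
  invisible(g)
}
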