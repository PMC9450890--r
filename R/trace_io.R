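#' Regions of interest
#'
#' ROIs select the pixels averaged into a cell's fluorescence trace. Two
#' geometries are supported: circles (center + radius, convenient for the
#' enlarged-ROI strategy that keeps a small motile cell inside the region)
#' and polygons (vertex list). Coordinates are 0-based pixel indices,
#' x rightward, y downward; a pixel belongs to a polygon ROI when its
#' center is inside under the half-open top/left rasterization rule, which
#' makes rasterization deterministic and tilings non-overlapping.
#'
#' @param roi_id Identifier (string or integer).
#' @param cx,cy Circle center in pixel coordinates.
#' @param radius Circle radius in pixels (> 0).
#' @param xs,ys Polygon vertex coordinates (>= 3 vertices).
#' @param cell_type One of `cell_types()` (or `NA`).
#' @param gut_id,channel Metadata labels.
#' @return An object of class `ca_roi`.
#' @export
roi_circle <- function(roi_id, cx, cy, radius, cell_type = NA_character_,
                       gut_id = "gut1", channel = "GCaMP") {
  assert_scalar_number(radius, "radius", min = .Machine$double.eps)
  structure(list(roi_id = roi_id, shape = "circle",
                 center = c(x = cx, y = cy), radius = radius,
                 cell_type = cell_type, gut_id = gut_id, channel = channel),
            class = "ca_roi")
}

#' @rdname roi_circle
#' @export
roi_polygon <- function(roi_id, xs, ys, cell_type = NA_character_,
                        gut_id = "gut1", channel = "GCaMP") {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  structure(list(roi_id = roi_id, shape = "polygon",
                 xs = as.numeric(xs), ys = as.numeric(ys),
                 cell_type = cell_type, gut_id = gut_id, channel = channel),
            class = "ca_roi")
}

# Pixel mask of an ROI on an ny x nx image: 2-column (y, x), 0-based,
# clipped to bounds. Errors when the clipped mask is empty.
#' @noRd
roi_mask <- function(roi, ny, nx, center = NULL) {
  px <- if (roi$shape == "circle") {
    ctr <- center %||% roi$center
    rasterize_circle(ctr[["x"]], ctr[["y"]], roi$radius, ny, nx)
  } else {
    rasterize_polygon(roi$xs, roi$ys, ny, nx)
  }
  if (nrow(px) == 0) {
    stop("ROI '", roi$roi_id, "' covers no pixels inside the image")
  }
  px
}

#' Write / read ROI sets as JSON
#'
#' @param rois List of `ca_roi` objects.
#' @param path File path.
#' @return `write_rois` returns `path` invisibly; `read_rois` a list of
#'   `ca_roi`.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    if (r$shape == "circle") {
      ctr <- unlist(r$center)          # stored as an (x, y) array
      roi_circle(r$roi_id, ctr[1], ctr[2], r$radius,
                 r$cell_type %||% NA_character_, r$gut_id, r$channel)
    } else {
      roi_polygon(r$roi_id, r$xs, r$ys,
                  r$cell_type %||% NA_character_, r$gut_id, r$channel)
    }
  })
}

#' Extract a mean-fluorescence trace from a movie
#'
#' `F(t)` is the mean intensity over the ROI's pixels at each frame;
#' `t = frame_index * frame_interval`, starting at 0. If `centers` (from
#' [track_roi()]) is supplied for a circle ROI, the ROI follows those
#' per-frame centers.
#'
#' @param movie A `ca_movie` with `T x Y x X` data (use [max_project()]
#'   first for z-stacks).
#' @param roi A `ca_roi`.
#' @param centers Optional tibble with columns `frame`, `cx`, `cy`.
#' @return Trace-table rows: tibble with `gut_id`, `cell_id`, `cell_type`,
#'   `channel`, `t_s`, `F`.
#' @export
extract_trace <- function(movie, roi, centers = NULL) {
  stopifnot(inherits(movie, "ca_movie"), inherits(roi, "ca_roi"))
  d <- dim(movie$data)
  if (length(d) != 3) stop("extract_trace needs a T x Y x X movie; ",
                           "use max_project() for z-stacks")
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  f <- numeric(nt)
  if (is.null(centers)) {
    px <- roi_mask(roi, ny, nx)
    idx <- cbind(px[, "y"] + 1L, px[, "x"] + 1L)
    for (k in seq_len(nt)) {
      img <- matrix(movie$data[k, , ], ny, nx)
      f[k] <- mean(img[idx])
    }
  } else {
    stopifnot(roi$shape == "circle", nrow(centers) == nt)
    for (k in seq_len(nt)) {
      px <- roi_mask(roi, ny, nx,
                     center = c(x = centers$cx[k], y = centers$cy[k]))
      img <- matrix(movie$data[k, , ], ny, nx)
      f[k] <- mean(img[cbind(px[, "y"] + 1L, px[, "x"] + 1L)])
    }
  }
  tibble::tibble(gut_id = roi$gut_id, cell_id = roi$roi_id,
                 cell_type = roi$cell_type, channel = roi$channel,
                 t_s = (seq_len(nt) - 1L) * movie$frame_interval, F = f)
}

#' @rdname extract_trace
#' @param rois List of `ca_roi`.
#' @export
extract_traces <- function(movie, rois) {
  dplyr::bind_rows(lapply(rois, function(r) extract_trace(movie, r)))
}

#' Extract traces for every cell of a tissue map
#'
#' Uses the simulator's cell masks directly, giving the mean intensity of
#' each cell's pixels per frame.
#'
#' @param movie A `ca_movie` rendered on `tissue`.
#' @param tissue The `tissue_map`.
#' @param gut_id,channel Metadata labels.
#' @return A trace table covering all cells.
#' @export
tissue_traces <- function(movie, tissue, gut_id = "gut1",
                          channel = movie$channel) {
  d <- dim(movie$data)
  stopifnot(length(d) == 3,
            d[2] == tissue$field_size[["ny"]],
            d[3] == tissue$field_size[["nx"]])
  nt <- d[1]
  cells <- tissue$cells
  masks <- lapply(cells$cell_id, function(id) which(tissue$label == id))
  f <- matrix(0, nrow(cells), nt)
  for (k in seq_len(nt)) {
    img <- matrix(movie$data[k, , ], d[2], d[3])
    f[, k] <- vapply(masks, function(m) mean(img[m]), numeric(1))
  }
  tibble::tibble(
    gut_id = gut_id,
    cell_id = rep(cells$cell_id, each = nt),
    cell_type = rep(cells$cell_type, each = nt),
    channel = channel,
    t_s = rep((seq_len(nt) - 1L) * movie$frame_interval,
              times = nrow(cells)),
    F = as.numeric(t(f))
  )
}

#' Track an ROI by intensity-weighted centroid re-centering
#'
#' Follows a cell that drifts between frames: at each frame the circle
#' center moves to the intensity-weighted centroid (weights are intensity
#' above the local minimum) of the pixels within `search_radius` of the
#' previous center. When local contrast falls below `min_contrast` the
#' previous center is kept, so featureless frames do not walk the ROI away.
#' Centers leaving the image are clipped with a warning.
#'
#' @param movie A `ca_movie` (`T x Y x X`).
#' @param roi A circle `ca_roi` whose initial position contains the cell.
#' @param search_radius Search radius in pixels.
#' @param min_contrast Minimum (max - min) intensity in the search window
#'   required to re-center.
#' @return Tibble with `frame` (1-based), `t_s`, `cx`, `cy`.
#' @export
track_roi <- function(movie, roi, search_radius = 5, min_contrast = 1e-8) {
  stopifnot(inherits(movie, "ca_movie"), roi$shape == "circle")
  d <- dim(movie$data)
  stopifnot(length(d) == 3)
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  cx <- roi$center[["x"]]; cy <- roi$center[["y"]]
  out_x <- numeric(nt); out_y <- numeric(nt)
  clipped <- FALSE
  for (k in seq_len(nt)) {
    win <- rasterize_circle(cx, cy, search_radius, ny, nx)
    img <- matrix(movie$data[k, , ], ny, nx)
    v <- img[cbind(win[, "y"] + 1L, win[, "x"] + 1L)]
    if (length(v) > 0 && (max(v) - min(v)) >= min_contrast) {
      w <- v - min(v)
      cx <- sum(win[, "x"] * w) / sum(w)
      cy <- sum(win[, "y"] * w) / sum(w)
    }
    if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1) {
      clipped <- TRUE
      cx <- min(max(cx, 0), nx - 1)
      cy <- min(max(cy, 0), ny - 1)
    }
    out_x[k] <- cx; out_y[k] <- cy
  }
  if (clipped) warning("tracked ROI left the image and was clipped")
  tibble::tibble(frame = seq_len(nt),
                 t_s = (seq_len(nt) - 1L) * movie$frame_interval,
                 cx = out_x, cy = out_y)
}

#' Write / read trace tables as CSV
#'
#' Header `gut_id,cell_id,cell_type,channel,t_s,F`; numeric values are
#' written with full precision so a round trip is exact.
#'
#' @param traces A trace table.
#' @param path File path.
#' @return `write_traces` returns `path` invisibly; `read_traces` a tibble.
#' @export
write_traces <- function(traces, path) {
  cols <- c("gut_id", "cell_id", "cell_type", "channel", "t_s", "F")
  stopifnot(all(cols %in% names(traces)))
  df <- as.data.frame(traces[, cols])
  df$t_s <- sprintf("%.17g", df$t_s)
  df$F <- sprintf("%.17g", df$F)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path, colClasses = c(gut_id = "character",
                                      cell_id = "character",
                                      cell_type = "character",
                                      channel = "character",
                                      t_s = "numeric", F = "numeric"))
  tibble::as_tibble(df)
}
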