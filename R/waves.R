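#' Compute a kymograph along a polyline
#'
#' Samples the movie along a polyline at 1-pixel arc-length steps; each row
#' of the matrix is the mean intensity over `width` nearest-pixel samples
#' taken perpendicular to the local direction, per frame. A moving signal
#' appears as a sloped streak whose inverse slope is its speed.
#'
#' @param movie A `ca_movie` (`T x Y x X`).
#' @param polyline Two-column matrix of (x, y) pixel vertices (>= 2 rows,
#'   nonzero length).
#' @param width Sampling width in pixels (odd; 1-pixel steps across).
#' @return A `kymograph`: list with `mat` (distance x time),
#'   `distance_um`, `t_s`, `ds_um`, `dt_s`.
#' @export
compute_kymograph <- function(movie, polyline, width = 3) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$data)
  stopifnot(length(d) == 3)
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2)
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  if (sum(seglen) < 1) stop("degenerate polyline: total length < 1 pixel")
  cum <- c(0, cumsum(seglen))
  s <- seq(0, floor(sum(seglen)), by = 1)

  half <- (width - 1) / 2
  offs <- if (width >= 2) seq(-half, half, length.out = width) else 0
  ny <- d[2]; nx <- d[3]
  rows <- lapply(s, function(sj) {
    k <- findInterval(sj, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(seg))
    f <- (sj - cum[k]) / seglen[k]
    pt <- polyline[k, ] + f * seg[k, ]
    tangent <- seg[k, ] / seglen[k]
    normal <- c(-tangent[2], tangent[1])
    px <- round(pt[1] + offs * normal[1])
    py <- round(pt[2] + offs * normal[2])
    ok <- px >= 0 & px <= nx - 1 & py >= 0 & py <= ny - 1
    cbind(y = py[ok] + 1, x = px[ok] + 1)
  })
  mat <- matrix(NA_real_, length(s), d[1])
  for (k in seq_len(d[1])) {
    img <- matrix(movie$data[k, , ], ny, nx)
    mat[, k] <- vapply(rows, function(ix) {
      if (nrow(ix) == 0) NA_real_ else mean(img[ix])
    }, numeric(1))
  }
  structure(list(mat = mat,
                 distance_um = s * movie$um_per_px,
                 t_s = (seq_len(d[1]) - 1) * movie$frame_interval,
                 ds_um = movie$um_per_px, dt_s = movie$frame_interval),
            class = "kymograph")
}

#' Detect activation events in per-cell traces
#'
#' Discretizes each cell's F/F_min ratio into activation events: maximal
#' runs above a hysteresis threshold pair. An event starts when the ratio
#' crosses the on-threshold and extends backwards and forwards while the
#' ratio stays at or above the off-threshold. With `threshold = "auto"`
#' the on-threshold is the per-cell median ratio plus the larger of
#' `k_mad` times the robust noise s.d. of the ratio (MAD of successive
#' differences over sqrt(2)) and a quarter of the trace's dynamic range
#' above the median; the range floor keeps the threshold meaningful on
#' noiseless traces, where the indicator kernel's tail never reaches zero
#' exactly. The off-threshold sits halfway between the median and the
#' on-threshold.
#'
#' @param traces Trace table (raw fluorescence; normalized per cell
#'   internally).
#' @param threshold `"auto"` or an absolute on-threshold in ratio units.
#' @param off_threshold Absolute off-threshold (default: midway between
#'   the per-cell median ratio and the on-threshold).
#' @param k_mad Noise multiplier for the automatic threshold.
#' @param offset Passed to [normalize_trace()].
#' @return Tibble with `cell_id`, `cell_type`, `onset_s`, `offset_s`,
#'   `peak` (max ratio in the event). `onset < offset` always (offset is
#'   one frame past the last supra-threshold sample).
#' @export
detect_activations <- function(traces, threshold = "auto",
                               off_threshold = NULL, k_mad = 5,
                               offset = 0) {
  traces |>
    dplyr::group_by(.data$gut_id, .data$cell_id, .data$cell_type,
                    .data$channel) |>
    dplyr::group_modify(function(d, key) {
      nt <- normalize_trace(d$F, d$t_s, offset = offset)
      x <- nt$ratio; t <- nt$t_s
      dt <- if (length(t) > 1) t[2] - t[1] else 1
      med <- median(x)
      on <- if (identical(threshold, "auto")) {
        med + max(k_mad * trace_noise_sigma(x), 0.25 * (max(x) - med))
      } else threshold
      off <- off_threshold %||% (med + 0.5 * (on - med))
      above_on <- x > on
      if (!any(above_on)) {
        return(tibble::tibble(onset_s = numeric(0), offset_s = numeric(0),
                              peak = numeric(0)))
      }
      above_off <- x >= off
      runs <- rle(above_off)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- runs$values &
        vapply(seq_along(runs$values), function(i) {
          runs$values[i] && any(above_on[starts[i]:ends[i]])
        }, logical(1))
      tibble::tibble(
        onset_s = t[starts[keep]],
        offset_s = t[ends[keep]] + dt,
        peak = vapply(which(keep), function(i) max(x[starts[i]:ends[i]]),
                      numeric(1))
      )
    }) |>
    dplyr::ungroup()
}

#' Link activation events into multicellular waves
#'
#' Builds a graph whose nodes are activation events; two events are linked
#' when their cells share a wave-conducting contact (an adjacency edge
#' with nonzero permeability) and their onsets differ by at most
#' `link_window`. Waves are the connected components
#' (single-linkage), which accommodates splitting and colliding fronts.
#' Every activation belongs to exactly one wave; an isolated event is a
#' wave of extent 1.
#'
#' Per wave the summary reports extent (distinct member cells), duration,
#' net displacement from the earliest to the latest activation's cell
#' centroid (with angle), speed (net displacement over onset span), and
#' the fraction of member activations per cell type.
#'
#' @param activations Tibble from [detect_activations()].
#' @param tissue The `tissue_map` supplying adjacency and centroids.
#' @param link_window Onset-difference window in seconds (a natural choice
#'   is 3 x the simulator's propagation delay).
#' @return A `wave_set`: list with `waves` (wave_id, extent, n_events,
#'   duration_s, dx_um, dy_um, angle_deg, speed_um_s, frac_IC, frac_CC,
#'   frac_EE, frac_PROG) and `members` (wave_id + activation columns).
#' @export
link_waves <- function(activations, tissue, link_window = 3) {
  acts <- activations
  if (nrow(acts) == 0) {
    return(structure(list(
      waves = tibble::tibble(wave_id = integer(0), extent = integer(0),
                             n_events = integer(0), duration_s = numeric(0),
                             dx_um = numeric(0), dy_um = numeric(0),
                             angle_deg = numeric(0), speed_um_s = numeric(0),
                             frac_IC = numeric(0), frac_CC = numeric(0),
                             frac_EE = numeric(0), frac_PROG = numeric(0)),
      members = dplyr::mutate(acts, wave_id = integer(0))),
      class = "wave_set"))
  }
  n <- nrow(acts)
  adj <- tissue$edges[tissue$edges$permeability > 0, ]
  # candidate node pairs: activations in adjacent cells with close onsets
  edge_from <- integer(0); edge_to <- integer(0)
  if (nrow(adj) > 0) {
    by_cell <- split(seq_len(n), acts$cell_id)
    for (k in seq_len(nrow(adj))) {
      ia <- by_cell[[as.character(adj$from[k])]]
      ib <- by_cell[[as.character(adj$to[k])]]
      if (is.null(ia) || is.null(ib)) next
      for (i in ia) {
        close <- ib[abs(acts$onset_s[ib] - acts$onset_s[i]) <= link_window]
        edge_from <- c(edge_from, rep.int(i, length(close)))
        edge_to <- c(edge_to, close)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edge_from) > 0) {
    g <- igraph::add_edges(g, rbind(edge_from, edge_to))
  }
  comp <- igraph::components(g)$membership
  # renumber waves by earliest onset for reproducible ids
  first_onset <- tapply(acts$onset_s, comp, min)
  remap <- rank(first_onset, ties.method = "first")
  acts$wave_id <- as.integer(remap[as.character(comp)])

  cent <- tissue$cells
  pos <- match(acts$cell_id, cent$cell_id)
  acts$cx_um <- cent$centroid_x_um[pos]
  acts$cy_um <- cent$centroid_y_um[pos]

  waves <- acts |>
    dplyr::group_by(.data$wave_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$onset_s), ]
      span <- d$onset_s[nrow(d)] - d$onset_s[1]
      dx <- d$cx_um[nrow(d)] - d$cx_um[1]
      dy <- d$cy_um[nrow(d)] - d$cy_um[1]
      disp <- sqrt(dx^2 + dy^2)
      tibble::tibble(
        extent = length(unique(d$cell_id)),
        n_events = nrow(d),
        duration_s = max(d$offset_s) - min(d$onset_s),
        dx_um = dx, dy_um = dy,
        angle_deg = if (disp > 0) atan2(dy, dx) * 180 / pi else NA_real_,
        speed_um_s = if (span > 0) disp / span else NA_real_,
        frac_IC = mean(d$cell_type == "IC"),
        frac_CC = mean(d$cell_type == "CC"),
        frac_EE = mean(d$cell_type == "EE"),
        frac_PROG = mean(d$cell_type == "PROG")
      )
    }) |>
    dplyr::ungroup()
  structure(list(waves = waves,
                 members = acts[, setdiff(names(acts),
                                          c("cx_um", "cy_um"))]),
            class = "wave_set")
}

#' @export
print.wave_set <- function(x, ...) {
  cat("<wave_set> ", nrow(x$waves), " waves; max extent ",
      if (nrow(x$waves)) max(x$waves$extent) else 0, "\n", sep = "")
  invisible(x)
}

#' Summarize a set of detected waves
#'
#' Counts, the extent distribution, copper-cell involvement, and
#' optionally recurrence in a query region: how many waves have at least
#' one member cell whose centroid lies within `region` (a list with
#' `cx_um`, `cy_um`, `radius_um`). Copper-cell involvement is measured on
#' the propagation paths, i.e. over multicellular waves only (an isolated
#' intrinsic spike in a copper cell is not a path): the fraction of
#' member activations in CC cells, and the fraction of waves containing
#' any CC cell.
#'
#' @param waves A `wave_set` from [link_waves()].
#' @param tissue The `tissue_map` (needed when `region` is given).
#' @param region Optional query circle in microns.
#' @return List with `n_waves`, `n_multicellular` (extent >= 2),
#'   `max_extent`, `extent_table`, `cc_member_fraction`,
#'   `cc_wave_fraction`, and `n_waves_in_region` when a region is given.
#' @export
wave_report <- function(waves, tissue = NULL, region = NULL) {
  w <- waves$waves
  m <- waves$members
  multi <- w$wave_id[w$extent >= 2]
  mm <- m[m$wave_id %in% multi, ]
  out <- list(
    n_waves = nrow(w),
    n_multicellular = length(multi),
    max_extent = if (nrow(w)) max(w$extent) else 0L,
    extent_table = if (nrow(w)) table(w$extent) else table(integer(0)),
    cc_member_fraction = if (nrow(mm)) mean(mm$cell_type == "CC") else 0,
    cc_wave_fraction = if (length(multi))
      mean(w$frac_CC[w$extent >= 2] > 0) else 0
  )
  if (!is.null(region)) {
    stopifnot(!is.null(tissue))
    cent <- tissue$cells
    pos <- match(m$cell_id, cent$cell_id)
    inside <- (cent$centroid_x_um[pos] - region$cx_um)^2 +
      (cent$centroid_y_um[pos] - region$cy_um)^2 <= region$radius_um^2
    out$n_waves_in_region <- length(unique(m$wave_id[inside]))
  }
  out
}
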