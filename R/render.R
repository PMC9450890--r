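#' Indicator response kernel
#'
#' Difference-of-exponentials impulse response of the fluorescent Ca2+
#' indicator, normalized to unit peak: rise time constant `tau_rise`,
#' decay `tau_decay`, zero for `t < 0`.
#'
#' @param t Times in seconds (numeric vector).
#' @param tau_rise,tau_decay Time constants in seconds, `tau_rise < tau_decay`.
#' @return Kernel values in \[0, 1\].
#' @export
ca_kernel <- function(t, tau_rise = 1, tau_decay = 3) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  tp <- kernel_peak_time(tau_rise, tau_decay)
  kmax <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / kmax
  out
}

#' @rdname ca_kernel
#' @export
kernel_peak_time <- function(tau_rise = 1, tau_decay = 3) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# Per-cell noiseless fluorescence matrix (n_cells x T), rows in cell order.
#' @noRd
cell_fluorescence <- function(tissue, spikes, config) {
  nt <- floor(config$duration / config$frame_interval)
  t_frames <- (seq_len(nt) - 1L) * config$frame_interval
  cells <- tissue$cells
  base <- rep(config$baseline, nrow(cells))
  if (config$cbx) {
    base[cells$cell_type == "CC"] <-
      config$baseline * config$cbx_cc_baseline_factor
  }
  f <- matrix(rep(base, each = nt), nrow = nrow(cells), ncol = nt,
              byrow = TRUE)
  if (nrow(spikes) > 0) {
    row_of <- match(spikes$cell_id, cells$cell_id)
    for (k in seq_len(nrow(spikes))) {
      f[row_of[k], ] <- f[row_of[k], ] + config$amplitude *
        ca_kernel(t_frames - spikes$time_s[k], config$tau_rise,
                  config$tau_decay)
    }
  }
  list(f = f, t = t_frames)
}

#' Render per-cell fluorescence traces
#'
#' Evaluates the indicator model directly at the cell level: baseline plus
#' `amplitude` times the response kernel summed over the cell's spikes,
#' with optional additive Gaussian noise on the cell-mean trace. This is
#' the fast path used when pixel-level rendering is not needed.
#'
#' @param tissue A `tissue_map`.
#' @param spikes Spike table from [simulate_spikes()].
#' @param config A `sim_config`.
#' @param noise_sd Trace-level additive Gaussian noise s.d. (a.u.);
#'   default 0 gives the noiseless ground-truth trace.
#' @param gut_id,channel Metadata carried into the trace table.
#' @param seed Seed for the noise draw (default: `config$seed + 1`).
#' @return A trace table: tibble with `gut_id`, `cell_id`, `cell_type`,
#'   `channel`, `t_s`, `F`.
#' @export
render_traces <- function(tissue, spikes, config, noise_sd = 0,
                          gut_id = "gut1", channel = "GCaMP",
                          seed = config$seed + 1L) {
  cf <- cell_fluorescence(tissue, spikes, config)
  f <- cf$f
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      f <- f + matrix(rnorm(length(f), 0, noise_sd), nrow(f), ncol(f))
    })
  }
  cells <- tissue$cells
  nt <- length(cf$t)
  tibble::tibble(
    gut_id = gut_id,
    cell_id = rep(cells$cell_id, each = nt),
    cell_type = rep(cells$cell_type, each = nt),
    channel = channel,
    t_s = rep(cf$t, times = nrow(cells)),
    F = as.numeric(t(f))
  )
}

#' Render a fluorescence movie
#'
#' Paints each frame by assigning every pixel the fluorescence of the cell
#' owning it (baseline + kernel responses to the cell's spikes), then adds
#' per-pixel Gaussian noise of s.d. `config$noise_sd` and, if
#' `config$drift_sd > 0`, a rigid integer-pixel jitter drawn per frame with
#' that s.d. (in microns). Intensities are clamped at 0.
#'
#' @inheritParams render_traces
#' @return A `ca_movie`: list with `data` (T x Y x X array), `frame_interval`
#'   (s), `channel`, `um_per_px`.
#' @export
render_movie <- function(tissue, spikes, config, channel = "GCaMP",
                         seed = config$seed + 2L) {
  cf <- cell_fluorescence(tissue, spikes, config)
  nt <- length(cf$t)
  ny <- tissue$field_size[["ny"]]; nx <- tissue$field_size[["nx"]]
  lut_idx <- tissue$label + 1L             # 0 (background) -> slot 1
  arr <- array(0, dim = c(nt, ny, nx))
  withr::with_seed(seed, {
    for (k in seq_len(nt)) {
      lut <- c(config$baseline, cf$f[, k])[lut_idx]
      img <- matrix(lut, ny, nx)
      if (config$drift_sd > 0) {
        sd_px <- config$drift_sd / tissue$um_per_px
        img <- shift_matrix(img, round(rnorm(1, 0, sd_px)),
                            round(rnorm(1, 0, sd_px)),
                            fill = config$baseline)
      }
      if (config$noise_sd > 0) {
        img <- img + matrix(rnorm(ny * nx, 0, config$noise_sd), ny, nx)
      }
      arr[k, , ] <- pmax(img, 0)
    }
  })
  new_movie(arr, config$frame_interval, channel, tissue$um_per_px)
}

#' @noRd
new_movie <- function(data, frame_interval, channel = "GCaMP",
                      um_per_px = 1) {
  stopifnot(length(dim(data)) %in% c(3L, 4L))
  structure(list(data = data, frame_interval = frame_interval,
                 channel = channel, um_per_px = um_per_px),
            class = "ca_movie")
}

#' Construct a movie object from an array
#'
#' @param data Numeric array, `T x Y x X` or `T x Z x Y x X`.
#' @param frame_interval Frame interval in seconds.
#' @param channel Channel name.
#' @param um_per_px Microns per pixel.
#' @return A `ca_movie`.
#' @export
ca_movie <- function(data, frame_interval, channel = "GCaMP",
                     um_per_px = 1) {
  if (any(data < 0)) stop("movie intensities must be nonnegative")
  new_movie(data, frame_interval, channel, um_per_px)
}

#' @export
print.ca_movie <- function(x, ...) {
  cat("<ca_movie> [", paste(dim(x$data), collapse = " x "), "] ",
      x$channel, ", ", x$frame_interval, " s/frame, ", x$um_per_px,
      " um/px\n", sep = "")
  invisible(x)
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' One TIFF file per channel; frames (and z-slices, if present) are stored
#' as 32-bit pages scaled into \[0, 1\] by a power-of-two factor recorded
#' in the sidecar (`<path>.json`), together with frame interval, pixel
#' size, channel name and array dimensions.
#' `read_movie(write_movie(m, p))` reproduces `m` to the 32-bit sample
#' quantization, i.e. within one part in 2^32 of the intensity scale.
#'
#' @param movie A `ca_movie`.
#' @param path Path of the TIFF file to write/read.
#' @return `write_movie` returns `path` invisibly; `read_movie` a `ca_movie`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$data)
  scale <- 2^max(0, ceiling(log2(max(movie$data, 1))))
  flat <- movie$data / scale
  pages <- if (length(d) == 3) {
    lapply(seq_len(d[1]), function(k) matrix(flat[k, , ], d[2], d[3]))
  } else {
    unlist(lapply(seq_len(d[1]), function(k) {
      lapply(seq_len(d[2]), function(z) matrix(flat[k, z, , ], d[3], d[4]))
    }), recursive = FALSE)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(frame_interval_s = movie$frame_interval,
               um_per_px = movie$um_per_px,
               channel = movie$channel,
               dims = as.integer(d),
               intensity_scale = scale)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar '", sidecar,
         "': frame-interval metadata is required to read a movie")
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(side$dims)
  arr <- array(0, dim = d)
  if (length(d) == 3) {
    for (k in seq_len(d[1])) arr[k, , ] <- pages[[k]]
  } else {
    i <- 0L
    for (k in seq_len(d[1])) for (z in seq_len(d[2])) {
      i <- i + 1L
      arr[k, z, , ] <- pages[[i]]
    }
  }
  new_movie(arr * side$intensity_scale, side$frame_interval_s,
            side$channel, side$um_per_px)
}

#' Maximum-intensity projection over z
#'
#' Converts a `T x Z x Y x X` stack into a `T x Y x X` movie by pixelwise
#' maximum over the z axis, the standard preprocessing for tracking small
#' basal cells. Movies without a z axis are returned unchanged with a
#' warning.
#'
#' @param movie A `ca_movie`.
#' @return A `ca_movie` with 3-dimensional data.
#' @export
max_project <- function(movie) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$data)
  if (length(d) == 3) {
    warning("movie has no z axis; returning it unchanged")
    return(movie)
  }
  out <- array(0, dim = d[c(1, 3, 4)])
  for (z in seq_len(d[2])) out <- pmax(out, movie$data[, z, , ])
  new_movie(out, movie$frame_interval, movie$channel, movie$um_per_px)
}
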