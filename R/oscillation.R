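#' Normalize a fluorescence trace to its minimum (F/F_min)
#'
#' The standard normalization for these recordings: each time point is
#' divided by the minimum fluorescence of the trace, giving a dimensionless
#' ratio >= 1 with units-free peak heights.
#'
#' When the trace minimum is not positive (possible for background- or
#' offset-subtracted data, or for very low-SNR recordings whose noise floor
#' crosses zero) the ratio is undefined; pass a positive `offset` to shift
#' the trace first. With the automatic detection threshold of
#' [detect_peaks()], which is invariant to affine rescaling, the choice of
#' offset does not change which peaks are found.
#'
#' @param trace Either a numeric vector of fluorescence values, or a
#'   single-cell trace table with columns `t_s` and `F`.
#' @param t_s Sample times (seconds), required when `trace` is numeric.
#' @param offset Constant added to the trace before normalizing (default 0).
#' @return A `normalized_trace`: list with `t_s`, `ratio`, `f_min`.
#' @export
normalize_trace <- function(trace, t_s = NULL, offset = 0) {
  if (is.data.frame(trace)) {
    if (length(unique(trace$cell_id %||% 1)) > 1) {
      stop("normalize_trace() expects a single cell's trace")
    }
    t_s <- trace$t_s
    f <- trace$F
  } else {
    f <- as.numeric(trace)
    t_s <- t_s %||% seq_along(f) - 1
  }
  if (length(f) == 0) stop("empty trace")
  if (any(!is.finite(f))) stop("trace contains non-finite values")
  f <- f + offset
  fmin <- min(f)
  if (fmin <= 0) {
    stop("F_min <= 0: apply an offset correction before normalizing ",
         "(pass `offset`; F/F_min is undefined for non-positive baselines)")
  }
  structure(list(t_s = t_s, ratio = f / fmin, f_min = fmin),
            class = "normalized_trace")
}

#' Detect oscillation peaks in a normalized trace
#'
#' Local maxima of the smoothed F/F_min ratio are kept when their
#' topographic prominence reaches a threshold, their height above the
#' running-median baseline reaches the same threshold (prominence alone
#' would always admit the global maximum of a pure-noise trace, whose
#' prominence is the trace's full range), and they are separated by at
#' least `min_separation`. With `min_prominence = "auto"` the threshold is
#' `k_mad` times a robust estimate of the noise on the smoothed series:
#' the median absolute deviation of the successive differences of the raw
#' ratio divided by `sqrt(2)` (insensitive to the smooth spike waveforms),
#' scaled by `1/sqrt(smoothing window)`. The threshold therefore tracks
#' the noise floor and is invariant to affine rescaling of the trace. Smoothing is a centered moving
#' average. Defaults: 3-frame smoothing, 2-frame minimum separation,
#' `k_mad = 5`.
#'
#' @param ntrace A `normalized_trace` (or numeric ratio vector with `t_s`
#'   attribute-free spacing of 1 s).
#' @param smooth_window Smoothing window in seconds (`NULL` = 3 frames).
#' @param min_prominence `"auto"` or a prominence threshold in ratio units.
#' @param min_separation Minimum peak separation in seconds
#'   (`NULL` = 2 frames).
#' @param k_mad Multiplier for the automatic threshold.
#' @return A `peak_set`: list with `peak_times` (s), `peak_heights`
#'   (ratio units, measured on the unsmoothed ratio), `n_peaks`, `params`.
#' @export
detect_peaks <- function(ntrace, smooth_window = NULL,
                         min_prominence = "auto", min_separation = NULL,
                         k_mad = 5) {
  if (!inherits(ntrace, "normalized_trace")) {
    ntrace <- structure(list(t_s = seq_along(ntrace) - 1,
                             ratio = as.numeric(ntrace), f_min = 1),
                        class = "normalized_trace")
  }
  x <- ntrace$ratio
  t <- ntrace$t_s
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to detect peaks")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1))) {
    stop("trace is not evenly sampled")
  }
  dt <- dt[1]

  to_frames <- function(w_s, default_frames) {
    if (is.null(w_s)) return(default_frames)
    if (w_s < dt) stop("window of ", w_s, " s is shorter than the frame ",
                       "interval (", dt, " s)")
    max(1L, round(w_s / dt))
  }
  w_smooth <- to_frames(smooth_window, 3L)
  if (w_smooth %% 2 == 0) w_smooth <- w_smooth + 1L
  sep_frames <- to_frames(min_separation, 2L)

  sm <- moving_average(x, w_smooth)
  cand <- local_maxima(sm)
  thr <- if (identical(min_prominence, "auto")) {
    # robust noise on the smoothed series the prominences are measured on
    k_mad * trace_noise_sigma(x) / sqrt(w_smooth)
  } else {
    assert_scalar_number(min_prominence, "min_prominence", min = 0)
    min_prominence
  }
  if (length(cand) > 0) {
    prom <- peak_prominence(sm, cand)
    wb <- min(31L, n - (1 - n %% 2))        # odd local-baseline window
    height <- sm[cand] - running_median(sm, wb)[cand]
    ok <- prom >= thr & height >= thr
    cand <- cand[ok]
    prom <- prom[ok]
    # enforce separation, keeping the most prominent peaks first
    if (length(cand) > 1) {
      ord <- order(-prom, cand)
      kept <- integer(0)
      for (i in ord) {
        if (length(kept) == 0 ||
            min(abs(cand[i] - kept)) >= sep_frames) {
          kept <- c(kept, cand[i])
        }
      }
      cand <- sort(kept)
    }
  }
  structure(
    list(peak_times = t[cand], peak_heights = x[cand],
         n_peaks = length(cand),
         params = list(smooth_frames = w_smooth, threshold = thr,
                       min_separation_frames = sep_frames, k_mad = k_mad)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", x$n_peaks, " peaks (prominence >= ",
      signif(x$params$threshold, 3), ")\n", sep = "")
  invisible(x)
}

#' Per-cell oscillation frequency in mHz
#'
#' `1000 * n_peaks / duration`. Recordings shorter than `min_duration`
#' (default 290 s, the inclusion threshold for frequency statistics) are
#' excluded: the function warns with the reason and returns `NA`.
#'
#' @param peaks A `peak_set` or an integer peak count.
#' @param duration Trace duration in seconds.
#' @param min_duration Minimum admissible duration in seconds.
#' @return Frequency in mHz, or `NA_real_` for excluded recordings.
#' @export
cell_frequency <- function(peaks, duration, min_duration = 290) {
  n <- if (inherits(peaks, "peak_set")) peaks$n_peaks else as.integer(peaks)
  assert_scalar_number(duration, "duration", min = .Machine$double.eps)
  if (duration < min_duration) {
    warning(sprintf(
      "trace excluded: duration %.1f s is below the %.0f s minimum",
      duration, min_duration))
    return(NA_real_)
  }
  1000 * n / duration
}

#' Peak detection and frequency for every cell of a trace table
#'
#' Normalizes each (gut, cell, channel) trace, detects peaks, and computes
#' the per-cell frequency. The duration used is the span from the first
#' sample to one frame past the last (`n * dt`).
#'
#' @param traces A trace table.
#' @param min_duration Passed to [cell_frequency()].
#' @param offset Passed to [normalize_trace()].
#' @param ... Passed to [detect_peaks()].
#' @return Tibble with `gut_id`, `cell_id`, `cell_type`, `channel`,
#'   `n_peaks`, `duration_s`, `freq_mhz`.
#' @export
trace_frequencies <- function(traces, min_duration = 290, offset = 0, ...) {
  traces |>
    dplyr::group_by(.data$gut_id, .data$cell_id, .data$cell_type,
                    .data$channel) |>
    dplyr::group_modify(function(d, key) {
      nt <- normalize_trace(d$F, d$t_s, offset = offset)
      pk <- detect_peaks(nt, ...)
      dur <- length(d$t_s) * (d$t_s[2] - d$t_s[1])
      tibble::tibble(n_peaks = pk$n_peaks, duration_s = dur,
                     freq_mhz = cell_frequency(pk, dur, min_duration))
    }) |>
    dplyr::ungroup()
}

#' Per-gut and cross-gut oscillation-frequency summary
#'
#' Aggregates per-cell frequencies within each gut and cell type, both
#' including and excluding non-oscillating cells (cells with zero detected
#' peaks), then summarizes across guts as mean and s.e.m. (s.d. across gut
#' means divided by the square root of the number of guts).
#'
#' @param freqs Tibble with at least `gut_id`, `cell_type`, `n_peaks`,
#'   `freq_mhz` (see [trace_frequencies()]); rows with `NA` frequency
#'   (excluded recordings) are dropped.
#' @param include_nonoscillating If `FALSE`, the cross-gut summary uses the
#'   per-gut means over oscillating cells only; guts with no oscillating
#'   cells of a type are omitted from that type's summary with a warning.
#' @return A `frequency_summary`: list with `per_gut` (gut_id, cell_type,
#'   n_cells, n_oscillating, mean_all_mhz, mean_oscillating_mhz) and
#'   `across_guts` (cell_type, n_guts, mean_mhz, sem_mhz,
#'   include_nonoscillating).
#' @export
gut_summary <- function(freqs, include_nonoscillating = TRUE) {
  freqs <- dplyr::filter(freqs, !is.na(.data$freq_mhz))
  if (nrow(freqs) == 0) stop("no eligible cells")
  per_gut <- freqs |>
    dplyr::group_by(.data$gut_id, .data$cell_type) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_oscillating = sum(.data$n_peaks > 0),
      mean_all_mhz = mean(.data$freq_mhz),
      mean_oscillating_mhz = ifelse(
        sum(.data$n_peaks > 0) > 0,
        mean(.data$freq_mhz[.data$n_peaks > 0]), NA_real_),
      .groups = "drop"
    )
  use <- if (include_nonoscillating) {
    dplyr::mutate(per_gut, gut_mean = .data$mean_all_mhz)
  } else {
    dropped <- per_gut[is.na(per_gut$mean_oscillating_mhz), ]
    if (nrow(dropped) > 0) {
      warning("omitting ", nrow(dropped), " gut/type group(s) with no ",
              "oscillating cells from the cross-gut summary")
    }
    per_gut |>
      dplyr::filter(!is.na(.data$mean_oscillating_mhz)) |>
      dplyr::mutate(gut_mean = .data$mean_oscillating_mhz)
  }
  across <- use |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_guts = dplyr::n(),
      mean_mhz = mean(.data$gut_mean),
      sem_mhz = ifelse(dplyr::n() > 1,
                       sd(.data$gut_mean) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(include_nonoscillating = include_nonoscillating)
  structure(list(per_gut = per_gut, across_guts = across),
            class = "frequency_summary")
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat("<frequency_summary>\n")
  print(x$across_guts)
  invisible(x)
}

#' Box-plot statistics
#'
#' Median and quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7), with whiskers at `q75 + 1.5 * IQR` and
#' `q25 - 1.5 * IQR` and outliers beyond the whiskers — the convention used
#' for the per-condition frequency distributions.
#'
#' @param values Numeric vector (NAs dropped).
#' @return List with `n`, `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  wl <- q[1] - 1.5 * iqr
  wh <- q[3] + 1.5 * iqr
  list(n = length(values), median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = wl, whisker_high = wh,
       outliers = values[values < wl | values > wh])
}

#' Compare oscillation frequencies between conditions
#'
#' Produces paired per-type box statistics for a control and a
#' gap-junction-blocked (CBX) condition. No hypothesis test is attached;
#' the comparison is descriptive.
#'
#' @param freq_control,freq_cbx Per-cell frequency tibbles
#'   (see [trace_frequencies()]).
#' @return A `condition_report`: list with `table` (tibble: cell_type,
#'   condition, n, median, q25, q75, whisker_low, whisker_high, n_outliers,
#'   mean_mhz) and `box` (nested list of [box_stats()] results by
#'   condition and cell type).
#' @export
compare_conditions <- function(freq_control, freq_cbx) {
  one <- function(freqs, condition) {
    freqs <- dplyr::filter(freqs, !is.na(.data$freq_mhz))
    sp <- split(freqs$freq_mhz, freqs$cell_type)
    rows <- lapply(names(sp), function(tp) {
      b <- box_stats(sp[[tp]])
      tibble::tibble(cell_type = tp, condition = condition, n = b$n,
                     median = b$median, q25 = b$q25, q75 = b$q75,
                     whisker_low = b$whisker_low,
                     whisker_high = b$whisker_high,
                     n_outliers = length(b$outliers),
                     mean_mhz = mean(sp[[tp]]))
    })
    list(table = dplyr::bind_rows(rows), box = lapply(sp, box_stats))
  }
  ctl <- one(freq_control, "control")
  cbx <- one(freq_cbx, "cbx")
  structure(list(table = dplyr::bind_rows(ctl$table, cbx$table),
                 box = list(control = ctl$box, cbx = cbx$box)),
            class = "condition_report")
}

#' QC plot of a normalized trace with detected peaks
#'
#' The stand-in for manual peak verification: draws the F/F_min ratio and
#' marks detected peaks so each cell's detection can be eyeballed.
#'
#' @param ntrace A `normalized_trace`.
#' @param peaks A `peak_set` from [detect_peaks()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_peaks <- function(ntrace, peaks) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_peaks()")
  }
  d <- tibble::tibble(t_s = ntrace$t_s, ratio = ntrace$ratio)
  p <- tibble::tibble(t_s = peaks$peak_times, ratio = peaks$peak_heights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = p, colour = "red", size = 1.5) +
    ggplot2::labs(x = "time (s)", y = "F / F_min")
}
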