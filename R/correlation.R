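#' Lagged cross-correlation for finite time series
#'
#' For two equally sampled series E and p of length n and an integer lag h,
#'
#' \deqn{r(h) = \frac{\sum_i (E_{i+h} - \mu_E)(p_i - \mu_p)}
#'   {\sqrt{\sum_i (E_i - \mu_E)^2}\,\sqrt{\sum_i (p_i - \mu_p)^2}},}
#'
#' where the numerator sum runs over the indices at which both shifted
#' series exist (no padding) while the means and the denominator use the
#' entire series. This anchors the statistic at lag zero: `r(0)` is exactly
#' the product-moment (Pearson) correlation of the two full series.
#' Positive `h` shifts the first series (E) later relative to the second
#' (p), i.e. `r(h)` pairs `E[i + h]` with `p[i]`.
#'
#' With `denominator = "overlap"` the deviations in the denominator are
#' instead recomputed over the overlap window at each lag (means still
#' taken over the full series), an alternative normalization offered for
#' comparison.
#'
#' @param e,p Numeric series of equal length (>= 3), or single-cell trace
#'   tables with columns `t_s` and `F`.
#' @param max_lag Maximum lag in seconds (default 12); must not exceed
#'   `(n - 2) * dt`.
#' @param dt Sampling interval in seconds; taken from the trace tables when
#'   they are supplied, otherwise defaults to 1.
#' @param denominator `"full"` (default) or `"overlap"`.
#' @return A `lagged_correlation`: tibble with `h_frames`, `h_s`, `r` for
#'   all integer lags in `-H..H`, `H = floor(max_lag / dt)`.
#' @export
cross_correlation <- function(e, p, max_lag = 12, dt = NULL,
                              denominator = c("full", "overlap")) {
  denominator <- match.arg(denominator)
  get <- function(x, other_dt) {
    if (is.data.frame(x)) {
      d <- diff(x$t_s)
      if (length(d) > 0 && any(abs(d - d[1]) > 1e-9 * max(d[1], 1))) {
        stop("unevenly sampled series are rejected; resample before ",
             "correlating")
      }
      list(v = x$F, dt = if (length(d)) d[1] else other_dt)
    } else {
      list(v = as.numeric(x), dt = other_dt)
    }
  }
  E <- get(e, dt); P <- get(p, dt)
  dt <- dt %||% E$dt %||% P$dt %||% 1
  if (!is.null(E$dt) && !is.null(P$dt) &&
      abs(E$dt - P$dt) > 1e-9 * max(E$dt, 1)) {
    stop("series have different sampling intervals")
  }
  ev <- E$v; pv <- P$v
  n <- length(ev)
  if (length(pv) != n) stop("series lengths differ (", n, " vs ",
                            length(pv), ")")
  if (n < 3) stop("need at least 3 samples")
  if (max_lag > (n - 2) * dt) {
    stop("max_lag exceeds (n - 2) * dt = ", (n - 2) * dt, " s")
  }
  mu_e <- mean(ev); mu_p <- mean(pv)
  de <- ev - mu_e; dp <- pv - mu_p
  sse <- sum(de^2); ssp <- sum(dp^2)
  if (sse == 0 || ssp == 0) {
    stop("zero-variance series: correlation is undefined")
  }
  H <- floor(max_lag / dt)
  hs <- (-H):H
  r <- vapply(hs, function(h) {
    i <- max(1L, 1L - h):min(n, n - h)       # indices where both exist
    num <- sum(de[i + h] * dp[i])
    den <- if (denominator == "full") {
      sqrt(sse * ssp)
    } else {
      sqrt(sum(de[i + h]^2) * sum(dp[i]^2))
    }
    num / den
  }, numeric(1))
  structure(tibble::tibble(h_frames = hs, h_s = hs * dt, r = r),
            class = c("lagged_correlation", "tbl_df", "tbl", "data.frame"))
}

#' Cross-correlations for a set of series pairs
#'
#' Computes `r(h)` for every requested ordered pair of series in a trace
#' table, carrying a direct/non-direct flag (direct pairs are juxtaposed
#' cells, e.g. an enterocyte and the progenitor it contacts).
#'
#' @param traces Trace table; series are identified by `cell_id` (each id
#'   must be one evenly sampled series).
#' @param pairs Tibble with columns `series_a`, `series_b` and optionally
#'   `direct` (logical, default `NA`).
#' @param max_lag Maximum lag in seconds (default 12).
#' @param denominator Passed to [cross_correlation()].
#' @return Tibble with `series_a`, `series_b`, `direct`, `h_frames`, `h_s`,
#'   `r`.
#' @export
pair_matrix <- function(traces, pairs, max_lag = 12,
                        denominator = "full") {
  sp <- split(traces[, c("t_s", "F")], traces$cell_id)
  if (!"direct" %in% names(pairs)) pairs$direct <- NA
  unknown <- setdiff(unique(c(pairs$series_a, pairs$series_b)), names(sp))
  if (length(unknown) > 0) {
    stop("unknown series id(s): ", paste(unknown, collapse = ", "))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    cc <- cross_correlation(sp[[as.character(pairs$series_a[k])]],
                            sp[[as.character(pairs$series_b[k])]],
                            max_lag = max_lag, denominator = denominator)
    tibble::tibble(series_a = pairs$series_a[k],
                   series_b = pairs$series_b[k],
                   direct = pairs$direct[k],
                   h_frames = cc$h_frames, h_s = cc$h_s, r = cc$r)
  }))
}

#' Summarize a correlation matrix against independence thresholds
#'
#' For each pair: the lag-0 correlation, the maximum absolute correlation
#' over non-zero lags (with its lag), and the maximum over all lags. Per
#' group (direct vs non-direct): group maxima and counts of pairs whose
#' `|r(0)|` exceeds `thresholds[1]` (default 0.2) or whose overall
#' `max |r(h)|` exceeds `thresholds[2]` (default 0.32) — the two reference
#' levels below which juxtaposed cell pairs are considered uncorrelated.
#'
#' @param mat Output of [pair_matrix()].
#' @param thresholds Length-2 numeric: lag-0 threshold, any-lag threshold.
#' @return List with `per_pair` (series_a, series_b, direct, r0,
#'   max_abs_r_nonzero, lag_at_max_s, max_abs_r_all) and `summary`
#'   (grouped by `direct`: n_pairs, max_abs_r0, max_abs_r_all,
#'   n_r0_above, n_any_above).
#' @export
summarize_independence <- function(mat, thresholds = c(0.2, 0.32)) {
  stopifnot(length(thresholds) == 2)
  per_pair <- mat |>
    dplyr::group_by(.data$series_a, .data$series_b, .data$direct) |>
    dplyr::summarise(
      r0 = .data$r[.data$h_frames == 0],
      max_abs_r_nonzero = max(abs(.data$r[.data$h_frames != 0])),
      lag_at_max_s = .data$h_s[.data$h_frames != 0][
        which.max(abs(.data$r[.data$h_frames != 0]))],
      max_abs_r_all = max(abs(.data$r)),
      .groups = "drop"
    )
  summary <- per_pair |>
    dplyr::group_by(.data$direct) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      max_abs_r0 = max(abs(.data$r0)),
      max_abs_r_all = max(.data$max_abs_r_all),
      n_r0_above = sum(abs(.data$r0) > thresholds[1]),
      n_any_above = sum(.data$max_abs_r_all > thresholds[2]),
      .groups = "drop"
    )
  list(per_pair = per_pair, summary = summary, thresholds = thresholds)
}
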