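# Internal numeric helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered moving average with shrinking windows at the edges; w must be odd.
#' @noRd
moving_average <- function(x, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1) return(x)
  n <- length(x)
  half <- (w - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Running median with shrinking windows at the edges; w must be odd.
#' @noRd
running_median <- function(x, w) {
  n <- length(x)
  w <- min(w, if (n %% 2 == 1) n else n - 1L)
  if (w <= 1) return(x)
  half <- (w - 1L) / 2L
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Strict local maxima: x[i] > x[i-1] and x[i] > x[i+1]. Plateaus are not
# maxima, which makes exactly-constant (noiseless baseline) segments inert.
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}

# Topographic prominence of peaks at indices `peaks` in series x: height of
# the peak above the higher of the two key saddles found walking left and
# right until a strictly higher point (or the series end) is met.
#' @noRd
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left_min <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      left_min <- min(left_min, x[i])
      i <- i - 1L
    }
    if (i < 1L) left_min <- min(x[1:p])
    right_min <- h
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= h) {
      right_min <- min(right_min, x[i])
      i <- i + 1L
    }
    if (i > n) right_min <- min(x[p:n])
    h - max(left_min, right_min)
  }, numeric(1))
}

# Integer-shift a matrix by (dy, dx), filling exposed pixels with `fill`.
#' @noRd
shift_matrix <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  ys <- seq_len(nrow(m))
  xs <- seq_len(ncol(m))
  ysrc <- ys - dy
  xsrc <- xs - dx
  oky <- ysrc >= 1 & ysrc <= nrow(m)
  okx <- xsrc >= 1 & xsrc <= ncol(m)
  out[ys[oky], xs[okx]] <- m[ysrc[oky], xsrc[okx]]
  out
}

# Scanline rasterization of a polygon onto 0-based pixel centers with the
# half-open top/left rule: a pixel center is inside when an edge crossing
# lies strictly to its right, and edges are half-open in y so shared
# vertices are counted once. Returns a 2-column matrix (y, x), 0-based.
#' @noRd
rasterize_polygon <- function(xs, ys, ny, nx) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  out_y <- integer(0)
  out_x <- integer(0)
  x2 <- c(xs[-1], xs[1])
  y2 <- c(ys[-1], ys[1])
  ymin <- max(0L, floor(min(ys)))
  ymax <- min(ny - 1L, ceiling(max(ys)))
  if (ymax < ymin) return(cbind(y = integer(0), x = integer(0)))
  for (yc in ymin:ymax) {
    cross <- numeric(0)
    for (e in seq_along(xs)) {
      ylo <- min(ys[e], y2[e])
      yhi <- max(ys[e], y2[e])
      if (ylo == yhi) next                    # horizontal edge
      if (yc >= ylo && yc < yhi) {            # half-open in y
        t <- (yc - ys[e]) / (y2[e] - ys[e])
        cross <- c(cross, xs[e] + t * (x2[e] - xs[e]))
      }
    }
    if (length(cross) < 2) next
    cross <- sort(cross)
    for (k in seq(1, length(cross) - 1, by = 2)) {
      xa <- ceiling(cross[k])
      xb <- ceiling(cross[k + 1]) - 1L       # half-open in x
      xa <- max(xa, 0L)
      xb <- min(xb, nx - 1L)
      if (xb >= xa) {
        out_y <- c(out_y, rep.int(yc, xb - xa + 1L))
        out_x <- c(out_x, xa:xb)
      }
    }
  }
  cbind(y = out_y, x = out_x)
}

# Pixels (0-based centers) inside a circle, boundary included.
#' @noRd
rasterize_circle <- function(cx, cy, r, ny, nx) {
  y0 <- max(0L, floor(cy - r)); y1 <- min(ny - 1L, ceiling(cy + r))
  x0 <- max(0L, floor(cx - r)); x1 <- min(nx - 1L, ceiling(cx + r))
  if (y1 < y0 || x1 < x0) return(cbind(y = integer(0), x = integer(0)))
  g <- expand.grid(y = y0:y1, x = x0:x1)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  cbind(y = g$y[keep], x = g$x[keep])
}

# Robust per-sample noise s.d. of an evenly sampled trace: MAD of the
# successive differences over sqrt(2). Insensitive to spike waveforms,
# which are smooth at the frame scale.
#' @noRd
trace_noise_sigma <- function(x) {
  if (length(x) < 2) return(0)
  mad(diff(x)) / sqrt(2)
}

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
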