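test_that("uniform frames give constant traces; 1-px ROI gives that pixel", {
  arr <- array(3.5, dim = c(4, 8, 8))
  set.seed(1)
  arr[, 3, 5] <- c(1, 2, 3, 4)     # y=2, x=4 in 0-based coords
  mv <- ca_movie(arr, frame_interval = 2)
  r_big <- roi_circle("big", cx = 1, cy = 1, radius = 0.4)
  tr <- extract_trace(mv, r_big)
  expect_equal(tr$F, rep(3.5, 4))
  expect_equal(tr$t_s, c(0, 2, 4, 6))
  r_px <- roi_circle("px", cx = 4, cy = 2, radius = 0.4)
  expect_equal(extract_trace(mv, r_px)$F, c(1, 2, 3, 4))
})

test_that("polygon rasterization follows the half-open top/left rule", {
  # axis-aligned square [0,2) x [0,2): exactly pixels {0,1} x {0,1}
  px <- midgutCa:::rasterize_polygon(c(0, 2, 2, 0), c(0, 0, 2, 2), 8, 8)
  expect_equal(nrow(px), 4)
  expect_setequal(paste(px[, "y"], px[, "x"]),
                  c("0 0", "0 1", "1 0", "1 1"))
  # two squares sharing an edge tile without double-counting
  a <- midgutCa:::rasterize_polygon(c(0, 2, 2, 0), c(0, 0, 2, 2), 8, 8)
  b <- midgutCa:::rasterize_polygon(c(2, 4, 4, 2), c(0, 0, 2, 2), 8, 8)
  expect_equal(length(intersect(paste(a[, 1], a[, 2]),
                                paste(b[, 1], b[, 2]))), 0)
})

test_that("polygon ROI mean matches a brute-force pixel average", {
  set.seed(2)
  arr <- array(runif(2 * 10 * 10), dim = c(2, 10, 10))
  mv <- ca_movie(arr, frame_interval = 1)
  roi <- roi_polygon("tri", xs = c(1, 8, 1), ys = c(1, 1, 8))
  tr <- extract_trace(mv, roi)
  px <- midgutCa:::rasterize_polygon(c(1, 8, 1), c(1, 1, 8), 10, 10)
  for (k in 1:2) {
    img <- matrix(arr[k, , ], 10, 10)
    expect_equal(tr$F[k], mean(img[cbind(px[, "y"] + 1, px[, "x"] + 1)]))
  }
})

test_that("out-of-bounds ROIs error; extraction is affine-linear", {
  arr <- array(runif(3 * 6 * 6), dim = c(3, 6, 6))
  mv <- ca_movie(arr, frame_interval = 1)
  expect_error(extract_trace(mv, roi_circle("out", 50, 50, 2)),
               "no pixels")
  roi <- roi_circle("in", 3, 3, 2)
  f1 <- extract_trace(mv, roi)$F
  mv2 <- ca_movie(2.5 * arr + 1, frame_interval = 1)
  expect_equal(extract_trace(mv2, roi)$F, 2.5 * f1 + 1)
})

test_that("ROI JSON and trace CSV round trips are faithful", {
  rois <- list(roi_circle("c1", 3.5, 4.25, 2, "PROG", "gutA", "RCaMP"),
               roi_polygon("p1", c(0, 5, 5), c(0, 0, 5), "IC"))
  p <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, p)
  back <- read_rois(p)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$center, rois[[1]]$center)
  expect_equal(back[[1]]$radius, 2)
  expect_equal(back[[1]]$cell_type, "PROG")
  expect_equal(back[[2]]$xs, c(0, 5, 5))

  tr <- tibble::tibble(gut_id = "g1", cell_id = c("a", "a", "b", "b"),
                       cell_type = "IC", channel = "GCaMP",
                       t_s = c(0, 2, 0, 2), F = c(1.25, 3.5, 2.125, 4.75))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, p2)
  expect_identical(readLines(p2)[1], "gut_id,cell_id,cell_type,channel,t_s,F")
  expect_equal(read_traces(p2), tr)
})

test_that("tracking follows a drifting cell and holds still otherwise", {
  # gaussian blob drifting 0.2 px/frame along x
  nt <- 30; ny <- 24; nx <- 32
  arr <- array(0, dim = c(nt, ny, nx))
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  truth_x <- 8 + 0.2 * (0:(nt - 1))
  for (k in seq_len(nt)) {
    arr[k, , ] <- 100 + 50 * exp(-((xs - truth_x[k])^2 + (ys - 12)^2) / 8)
  }
  mv <- ca_movie(arr, frame_interval = 2)
  ctr <- track_roi(mv, roi_circle("c", 8, 12, 4), search_radius = 5)
  expect_true(all(abs(ctr$cx - truth_x) <= 1))
  expect_true(all(abs(ctr$cy - 12) <= 1))
  # static cell: centers identical across frames
  arr2 <- array(rep(arr[1, , ], nt), dim = c(ny, nx, nt))
  arr2 <- aperm(arr2, c(3, 1, 2))
  ctr2 <- track_roi(ca_movie(arr2, 2), roi_circle("c", 8, 12, 4), 5)
  expect_equal(ctr2$cx, rep(ctr2$cx[1], nt))
  # zero contrast: fallback keeps the initial center
  flat <- ca_movie(array(7, dim = c(5, ny, nx)), 2)
  ctr3 <- track_roi(flat, roi_circle("c", 8, 12, 4), 5)
  expect_equal(ctr3$cx, rep(8, 5))
  expect_equal(ctr3$cy, rep(12, 5))
})

test_that("tracked extraction recovers the drifting cell's trace", {
  nt <- 20; ny <- 20; nx <- 30
  arr <- array(10, dim = c(nt, ny, nx))
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  truth_x <- 6 + 0.5 * (0:(nt - 1))
  amp <- 10 + (0:(nt - 1))          # known per-frame amplitude ramp
  for (k in seq_len(nt)) {
    arr[k, , ] <- 10 + amp[k] * ((xs - round(truth_x[k]))^2 +
                                   (ys - 10)^2 <= 4)
  }
  mv <- ca_movie(arr, frame_interval = 1)
  roi <- roi_circle("c", 6, 10, 2.2)
  ctr <- track_roi(mv, roi, search_radius = 4)
  tracked <- extract_trace(mv, roi, centers = ctr)
  static <- extract_trace(mv, roi)
  # the tracked trace keeps the bright cell; the static one loses it
  expect_gt(min(tracked$F), 10)
  expect_gt(tracked$F[nt], static$F[nt])
})
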