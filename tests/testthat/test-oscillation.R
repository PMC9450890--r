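test_that("F/F_min normalization is the ratio to the trace minimum", {
  n <- normalize_trace(c(5, 5, 5), t_s = c(0, 2, 4))
  expect_equal(n$ratio, c(1, 1, 1))
  expect_equal(n$f_min, 5)
  expect_equal(normalize_trace(c(2, 4, 6))$ratio, c(1, 2, 3))
  expect_error(normalize_trace(c(-1, 2, 3)), "offset")
  expect_error(normalize_trace(c(0, 2, 3)), "F_min")
  # offset correction makes a non-positive trace usable
  expect_equal(normalize_trace(c(-1, 2, 3), offset = 2)$f_min, 1)
  expect_error(normalize_trace(numeric(0)), "empty")
})

test_that("simulated peak ratio approaches 1 + amplitude/baseline", {
  tis <- line_tissue(1)
  cfg <- sim_config(duration = 100, frame_interval = 1, noise_sd = 0,
                    seed = 1)
  tr <- render_traces(tis, spike_tbl(1L, 50), cfg)
  n <- normalize_trace(tr$F, tr$t_s)
  expect_equal(max(n$ratio), 1 + cfg$amplitude / cfg$baseline,
               tolerance = 0.02)
})

test_that("constant traces yield no peaks; spike trains are counted exactly", {
  expect_equal(detect_peaks(normalize_trace(rep(2, 50)))$n_peaks, 0)
  tis <- line_tissue(1)
  cfg <- sim_config(duration = 300, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  times <- 15 + (0:6) * 40
  tr <- render_traces(tis, spike_tbl(1L, times), cfg)
  pk <- detect_peaks(normalize_trace(tr$F, tr$t_s))
  expect_equal(pk$n_peaks, 7)
  expected <- times + kernel_peak_time(cfg$tau_rise, cfg$tau_decay)
  expect_true(all(abs(pk$peak_times - expected) <= cfg$frame_interval))
})

test_that("auto-threshold detection is invariant to affine rescaling", {
  tis <- line_tissue(1)
  cfg <- sim_config(duration = 300, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  tr <- render_traces(tis, spike_tbl(1L, c(30, 100, 170, 240)), cfg,
                      noise_sd = 20, seed = 5)
  base <- detect_peaks(normalize_trace(tr$F, tr$t_s, offset = 100))
  for (a in c(0.5, 3, 100)) {
    for (b in c(0, 50)) {
      nt <- normalize_trace(a * tr$F + b, tr$t_s, offset = 100)
      pk <- detect_peaks(nt)
      expect_equal(pk$peak_times, base$peak_times)
    }
  }
})

test_that("windows shorter than the frame interval are rejected", {
  nt <- normalize_trace(c(1, 2, 1, 2, 1), t_s = seq(0, 8, by = 2))
  expect_error(detect_peaks(nt, smooth_window = 1), "shorter than")
  expect_error(detect_peaks(normalize_trace(c(1, 2))), "3 samples")
})

test_that("frequency is 1000 x peaks / duration with a 290 s floor", {
  expect_equal(cell_frequency(0, 300), 0)
  expect_equal(cell_frequency(12, 400), 30)
  expect_warning(f <- cell_frequency(5, 100), "excluded")
  expect_true(is.na(f))
  expect_equal(cell_frequency(5, 100, min_duration = 50), 50)
  # monotone in the peak count
  expect_true(all(diff(vapply(0:10, cell_frequency, numeric(1),
                              duration = 300)) > 0))
})

test_that("a 23 s spiking interval yields ~44 mHz", {
  tis <- line_tissue(1)
  cfg <- sim_config(duration = 1200, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  times <- seq(10, 1190, by = 23)
  tr <- render_traces(tis, spike_tbl(1L, times), cfg)
  pk <- detect_peaks(normalize_trace(tr$F, tr$t_s))
  f <- cell_frequency(pk, 1200)
  expect_equal(f, 1000 / 23, tolerance = 0.05)
})

test_that("gut summaries aggregate with and without silent cells", {
  freqs <- tibble::tibble(
    gut_id = "g1", cell_id = 1:3, cell_type = "IC", channel = "GCaMP",
    n_peaks = c(0, 0, 9), duration_s = 300, freq_mhz = c(0, 0, 30))
  s_in <- gut_summary(freqs, include_nonoscillating = TRUE)
  expect_equal(s_in$across_guts$mean_mhz, 10)
  s_ex <- gut_summary(freqs, include_nonoscillating = FALSE)
  expect_equal(s_ex$across_guts$mean_mhz, 30)
  expect_gte(s_ex$across_guts$mean_mhz, s_in$across_guts$mean_mhz)

  freqs2 <- tibble::tibble(
    gut_id = "g1", cell_id = 1:3, cell_type = "IC", channel = "GCaMP",
    n_peaks = c(3, 6, 9), duration_s = 300, freq_mhz = c(10, 20, 30))
  expect_equal(gut_summary(freqs2)$across_guts$mean_mhz, 20)

  # s.e.m. across guts
  freqs3 <- dplyr::bind_rows(
    dplyr::mutate(freqs2, gut_id = "g1", freq_mhz = c(10, 10, 10)),
    dplyr::mutate(freqs2, gut_id = "g2", freq_mhz = c(30, 30, 30)))
  s3 <- gut_summary(freqs3)
  expect_equal(s3$across_guts$mean_mhz, 20)
  expect_equal(s3$across_guts$sem_mhz, sd(c(10, 30)) / sqrt(2))

  # a gut with no oscillating cells is omitted under exclusion
  freqs4 <- dplyr::bind_rows(
    freqs2,
    dplyr::mutate(freqs2, gut_id = "g2", n_peaks = 0, freq_mhz = 0))
  expect_warning(s4 <- gut_summary(freqs4, include_nonoscillating = FALSE),
                 "omitting")
  expect_equal(s4$across_guts$n_guts, 1L)
})

test_that("box statistics follow the interpolated-quartile whisker rule", {
  b <- box_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q25, 25.75)
  expect_equal(b$q75, 75.25)
  expect_equal(b$whisker_high, b$q75 + 1.5 * (b$q75 - b$q25))
  expect_equal(b$whisker_low, b$q25 - 1.5 * (b$q75 - b$q25))
  expect_equal(length(b$outliers), 0)
  b1 <- box_stats(7)
  expect_equal(b1$median, 7)
  expect_equal(b1$q25, 7)
  expect_equal(b1$whisker_low, 7)
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(box_stats(sym)$median, mean(sym))
  expect_equal(box_stats(c(1:10, 100))$outliers, 100)
})

test_that("condition comparison pairs per-type box statistics", {
  mk <- function(f, gut) tibble::tibble(
    gut_id = gut, cell_id = seq_along(f), cell_type = rep(c("IC", "CC"),
                                                          length.out = length(f)),
    channel = "GCaMP", n_peaks = round(f), duration_s = 300, freq_mhz = f)
  rep_ <- compare_conditions(mk(c(30, 32, 5, 6, 28, 4), "g1"),
                             mk(c(0, 0, 0, 1, 0, 0), "g2"))
  expect_setequal(unique(rep_$table$condition), c("control", "cbx"))
  ic_ctl <- rep_$table[rep_$table$cell_type == "IC" &
                         rep_$table$condition == "control", ]
  ic_cbx <- rep_$table[rep_$table$cell_type == "IC" &
                         rep_$table$condition == "cbx", ]
  expect_gt(ic_ctl$median, ic_cbx$median)
  expect_equal(rep_$box$control$IC$median, ic_ctl$median)
})
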