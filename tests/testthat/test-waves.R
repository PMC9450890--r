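test_that("kymograph of a uniform movie is constant", {
  mv <- ca_movie(array(4.2, dim = c(6, 12, 20)), frame_interval = 2,
                 um_per_px = 2)
  ky <- compute_kymograph(mv, rbind(c(1, 6), c(18, 6)), width = 3)
  expect_true(all(ky$mat == 4.2))
  expect_equal(ncol(ky$mat), 6)
  expect_equal(nrow(ky$mat), 18)   # 17 px of arc length, 1 px steps
  expect_error(compute_kymograph(mv, rbind(c(1, 1), c(1.2, 1))),
               "degenerate")
})

test_that("a static bright cell appears as a horizontal band", {
  arr <- array(1, dim = c(5, 10, 30))
  arr[, 5:7, 10:13] <- 9
  mv <- ca_movie(arr, frame_interval = 2, um_per_px = 1)
  ky <- compute_kymograph(mv, rbind(c(0, 5), c(29, 5)), width = 3)
  bright_rows <- which(rowMeans(ky$mat) > 2)
  expect_true(all(bright_rows >= 10 & bright_rows <= 15))
  # the band spans all time points
  expect_true(all(ky$mat[11, ] > 2))
})

test_that("kymograph streak slope recovers a simulated wave's speed", {
  # chain of 8 IC cells; a cascade marches down the line at
  # (cell size um) / delay um/s
  tis <- line_tissue(8, block = 5L, um_per_px = 2)
  delay <- 2
  times <- 10 + (0:7) * delay
  sp <- spike_tbl(1:8, times, origin = c("intrinsic",
                                         rep("propagated", 7)),
                  wave_id = rep(1L, 8))
  cfg <- sim_config(duration = 60, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  mv <- render_movie(tis, sp, cfg)
  ky <- compute_kymograph(mv, rbind(c(0, 2), c(39, 2)), width = 3)
  # per-frame argmax distance during the wave's transit
  active <- which(apply(ky$mat, 2, max) > cfg$baseline + 0.5 * cfg$amplitude)
  dist_um <- ky$distance_um[apply(ky$mat[, active], 2, which.max)]
  t_s <- ky$t_s[active]
  v_hat <- unname(coef(lm(dist_um ~ t_s))[2])
  v_true <- (5 * 2) / delay          # 5 px * 2 um/px per 2 s = 5 um/s
  expect_lt(abs(v_hat - v_true) / v_true, 0.2)
})

test_that("activation events discretize spikes one-to-one", {
  tis <- line_tissue(1)
  cfg <- sim_config(duration = 300, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  # flat trace: no activations
  flat <- render_traces(tis, spike_tbl(integer(0), numeric(0)), cfg)
  expect_equal(nrow(detect_activations(flat)), 0)
  times <- 20 + (0:5) * 45
  tr <- render_traces(tis, spike_tbl(1L, times), cfg)
  acts <- detect_activations(tr)
  expect_equal(nrow(acts), 6)
  expect_true(all(acts$onset_s < acts$offset_s))
  expect_true(all(abs(acts$onset_s - times) <= 2 * cfg$frame_interval))
  # threshold above the excursion: nothing
  expect_equal(nrow(detect_activations(tr, threshold = 100,
                                       off_threshold = 99)), 0)
})

test_that("linked waves recover a chain cascade and partition activations", {
  tis <- line_tissue(5, block = 5L)
  delay <- 1
  sp <- spike_tbl(1:5, 30 + (0:4) * delay,
                  origin = c("intrinsic", rep("propagated", 4)),
                  wave_id = rep(1L, 5))
  # plus an isolated late spike in cell 5
  sp <- dplyr::bind_rows(sp, spike_tbl(5L, 120, wave_id = 2L))
  cfg <- sim_config(duration = 200, frame_interval = 2, noise_sd = 0,
                    seed = 1)
  tr <- render_traces(tis, sp, cfg)
  acts <- detect_activations(tr)
  ws <- link_waves(acts, tis, link_window = 3 * delay)
  expect_equal(nrow(ws$waves), 2)
  expect_setequal(ws$waves$extent, c(5L, 1L))
  # partition: every activation in exactly one wave
  expect_equal(nrow(ws$members), nrow(acts))
  expect_false(any(is.na(ws$members$wave_id)))
  big <- ws$waves[ws$waves$extent == 5, ]
  expect_equal(big$n_events, 5)
  # rightward displacement along the chain, speed ~ cell size / delay
  expect_gt(big$dx_um, 0)
  expect_equal(big$angle_deg, 0, tolerance = 1)
  expect_equal(big$speed_um_s, (4 * 5 * 2) / 4, tolerance = 3)
})

test_that("an empty activation set yields an empty wave report", {
  tis <- line_tissue(2)
  ws <- link_waves(tibble::tibble(gut_id = character(0),
                                  cell_id = integer(0),
                                  cell_type = character(0),
                                  channel = character(0),
                                  onset_s = numeric(0),
                                  offset_s = numeric(0),
                                  peak = numeric(0)), tis)
  rep_ <- wave_report(ws)
  expect_equal(rep_$n_waves, 0)
  expect_equal(rep_$max_extent, 0)
  expect_equal(rep_$cc_member_fraction, 0)
})

test_that("ground-truth wave count and region recurrence are reported", {
  # a single pacemaker cell guarantees waves are temporally separated, so
  # the detected count must equal the ground-truth count exactly
  tis <- lattice_tissue(4, 4, block = 5L)
  cfg <- sim_config(duration = 3000, frame_interval = 2, noise_sd = 0,
                    rates_mhz = c(IC = 0), refractory = 30,
                    propagation_delay = 1, seed = 21)
  cfg$propagation_prob["IC", "IC"] <- 0.9
  sp <- simulate_spikes(tis, cfg, rate_override_mhz = c("6" = 3))
  tr <- render_traces(tis, sp, cfg)
  acts <- detect_activations(tr)
  ws <- link_waves(acts, tis, link_window = 3)
  expect_equal(nrow(ws$waves), length(unique(sp$wave_id)))
  rep_ <- wave_report(ws, tis,
                      region = list(cx_um = 10, cy_um = 10, radius_um = 12))
  expect_lte(rep_$n_waves_in_region, rep_$n_waves)
  expect_gt(rep_$n_waves_in_region, 0)
})

test_that("CBX simulations contain no waves at all", {
  tis <- lattice_tissue(3, 3)
  cfg <- sim_config(duration = 900, rates_mhz = c(IC = 31), cbx = TRUE,
                    noise_sd = 0, seed = 8)
  sp <- simulate_spikes(tis, cfg)
  expect_equal(nrow(sp), 0)
  tr <- render_traces(tis, sp, cfg)
  ws <- link_waves(detect_activations(tr), tis, link_window = 3)
  expect_equal(nrow(ws$waves), 0)
  # residual intrinsic spiking (partial suppression) yields only
  # ground-truth waves of extent 1
  cfg2 <- sim_config(duration = 900, rates_mhz = c(IC = 31), cbx = TRUE,
                     cbx_suppression = 0.3, noise_sd = 0, seed = 8)
  sp2 <- simulate_spikes(tis, cfg2)
  expect_gt(nrow(sp2), 0)
  expect_true(all(table(sp2$wave_id) == 1))
})

test_that("noisy wave memberships agree with ground truth (adjusted Rand)", {
  library(mclust)
  aris <- coverage <- numeric(20)
  for (s in 1:20) {
    tis <- lattice_tissue(6, 6, block = 4L)
    cfg <- sim_config(duration = 600, frame_interval = 2,
                      rates_mhz = c(IC = 0), refractory = 30,
                      propagation_delay = 1, seed = 400 + s)
    cfg$propagation_prob["IC", "IC"] <- 0.9
    sp <- simulate_spikes(tis, cfg, rate_override_mhz = c("15" = 5))
    if (nrow(sp) < 2) next
    mv <- render_movie(tis, sp, cfg)        # default per-pixel noise
    acts <- detect_activations(tissue_traces(mv, tis))
    ws <- link_waves(acts, tis, link_window = 3)
    truth <- rep(NA_integer_, nrow(ws$members))
    for (i in seq_len(nrow(ws$members))) {
      cand <- which(sp$cell_id == ws$members$cell_id[i] &
                      abs(sp$time_s - ws$members$onset_s[i]) <= 6)
      if (length(cand) == 1) truth[i] <- sp$wave_id[cand]
    }
    ok <- !is.na(truth)
    coverage[s] <- sum(ok) / nrow(sp)
    aris[s] <- adjustedRandIndex(truth[ok], ws$members$wave_id[ok])
  }
  expect_gte(mean(coverage[coverage > 0]), 0.95)
  expect_gte(mean(aris[coverage > 0]), 0.9)
})
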