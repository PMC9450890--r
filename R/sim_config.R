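#' Simulation configuration
#'
#' Collects and validates all parameters of the synthetic-midgut dynamics
#' and indicator model. Defaults reflect the imaging regime the pipeline is
#' designed for: recordings of at least 290 s at a cycle time of 4.7 s or
#' faster, cell-type intrinsic spike rates of tens of mHz and below
#' (IC 31, CC 5.2, EE 15, PROG 7.1 mHz), GCaMP6s-scale indicator kinetics
#' (1 s rise, 3 s decay) and peak excursions about 3-fold over baseline.
#'
#' @param duration Recording duration in seconds (default 300).
#' @param frame_interval Frame interval in seconds (default 2; must be
#'   positive).
#' @param rates_mhz Named intrinsic spike rates in mHz, one per cell type.
#' @param refractory Minimum separation between consecutive spikes of one
#'   cell, seconds. The default (12 s) exceeds the peak detector's
#'   resolution limit at the default cycle time (smoothing plus separation,
#'   about 10 s), so that consecutive spikes of a cell are countable; it is
#'   well below the observed mean interval of ~23 s for the fastest cells.
#' @param propagation_prob 4 x 4 matrix of propagation probabilities per
#'   ordered (from, to) cell-type pair; `NULL` for the default (IC->IC 0.15,
#'   IC<->CC 0.05, all else 0). The IC->IC value keeps cascades subcritical
#'   on the contact graph, giving multicellular waves of a handful of cells
#'   (the longest observed waves cover about five); waves travel almost
#'   exclusively through interstitial cells.
#' @param propagation_delay Seconds between a spike and the propagated
#'   spike it triggers in a neighbour.
#' @param tau_rise,tau_decay Indicator kernel time constants, seconds
#'   (`tau_rise < tau_decay`).
#' @param amplitude Peak fluorescence added by a single spike (a.u.).
#' @param baseline Resting fluorescence (a.u.).
#' @param noise_sd Additive Gaussian noise s.d. per pixel per frame (a.u.);
#'   the default gives per-pixel peak SNR ~ 10.
#' @param drift_sd Frame-to-frame rigid jitter s.d. in microns (0 = none).
#' @param cbx Simulate the gap-junction-blocked (carbenoxolone) condition:
#'   all propagation probabilities become 0, intrinsic rates are multiplied
#'   by `cbx_suppression`, and copper-cell baseline is multiplied by
#'   `cbx_cc_baseline_factor`.
#' @param cbx_suppression Multiplier on intrinsic rates under `cbx`
#'   (default 0: oscillations fully abolished).
#' @param cbx_cc_baseline_factor Copper-cell baseline elevation factor under
#'   `cbx` (no quantitative estimate exists for the real tissue; 2 is a
#'   free-parameter default).
#' @param seed Integer seed used by all stochastic stages.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration = 300,
                       frame_interval = 2,
                       rates_mhz = c(IC = 31, CC = 5.2, EE = 15, PROG = 7.1),
                       refractory = 12,
                       propagation_prob = NULL,
                       propagation_delay = 1,
                       tau_rise = 1,
                       tau_decay = 3,
                       amplitude = 300,
                       baseline = 100,
                       noise_sd = 30,
                       drift_sd = 0,
                       cbx = FALSE,
                       cbx_suppression = 0,
                       cbx_cc_baseline_factor = 2,
                       seed = 1L) {
  assert_scalar_number(duration, "duration", min = .Machine$double.eps)
  assert_scalar_number(frame_interval, "frame_interval",
                       min = .Machine$double.eps)
  assert_scalar_number(refractory, "refractory", min = 0)
  assert_scalar_number(propagation_delay, "propagation_delay", min = 0)
  assert_scalar_number(tau_rise, "tau_rise", min = .Machine$double.eps)
  assert_scalar_number(tau_decay, "tau_decay", min = .Machine$double.eps)
  if (tau_rise >= tau_decay) stop("`tau_rise` must be < `tau_decay`")
  assert_scalar_number(amplitude, "amplitude", min = 0)
  assert_scalar_number(baseline, "baseline", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(drift_sd, "drift_sd", min = 0)
  assert_scalar_number(cbx_suppression, "cbx_suppression", min = 0)

  full <- setNames(rep(0, 4), cell_types())
  full[names(rates_mhz)] <- rates_mhz
  if (any(full < 0)) stop("intrinsic rates must be >= 0")
  bad <- names(rates_mhz)[!names(rates_mhz) %in% cell_types()]
  if (length(bad)) stop("unknown cell types in rates_mhz: ",
                        paste(bad, collapse = ", "))

  if (is.null(propagation_prob)) {
    propagation_prob <- matrix(0, 4, 4,
                               dimnames = list(cell_types(), cell_types()))
    propagation_prob["IC", "IC"] <- 0.15
    propagation_prob["IC", "CC"] <- 0.05
    propagation_prob["CC", "IC"] <- 0.05
  }
  stopifnot(is.matrix(propagation_prob),
            identical(dim(propagation_prob), c(4L, 4L)),
            all(propagation_prob >= 0 & propagation_prob <= 1))
  if (is.null(dimnames(propagation_prob))) {
    dimnames(propagation_prob) <- list(cell_types(), cell_types())
  }

  structure(
    list(duration = duration, frame_interval = frame_interval,
         rates_mhz = full, refractory = refractory,
         propagation_prob = propagation_prob,
         propagation_delay = propagation_delay,
         tau_rise = tau_rise, tau_decay = tau_decay,
         amplitude = amplitude, baseline = baseline,
         noise_sd = noise_sd, drift_sd = drift_sd,
         cbx = isTRUE(cbx), cbx_suppression = cbx_suppression,
         cbx_cc_baseline_factor = cbx_cc_baseline_factor,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$duration, " s @ ", x$frame_interval, " s/frame; ",
      "rates (mHz): ",
      paste(names(x$rates_mhz), x$rates_mhz, sep = "=", collapse = " "),
      if (x$cbx) "; CBX" else "", "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
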