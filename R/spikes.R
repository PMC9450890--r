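#' Simulate ground-truth spike dynamics on a tissue map
#'
#' Each cell fires intrinsic Ca2+ spikes as a stationary renewal process: a
#' refractory dead time followed by an exponential gap whose rate is
#' corrected so the realized long-run rate equals the configured rate in
#' mHz (the first gap is drawn from the equilibrium forward-recurrence
#' distribution, so the expected spike count over the recording is exactly
#' rate x duration). Every accepted spike then attempts, once per adjacency
#' edge, to trigger a propagated spike in the neighbour after
#' `propagation_delay` seconds with probability
#' `propagation_prob[from_type, to_type] * edge permeability`; a neighbour
#' still refractory from its previous spike ignores the trigger. A cascade
#' of propagated spikes shares the `wave_id` of the intrinsic spike that
#' started it, so single intrinsic events are waves of extent 1.
#'
#' Under `cbx = TRUE` all propagation probabilities are forced to 0 and
#' intrinsic rates are multiplied by `cbx_suppression` (default 0, i.e. the
#' spike table is empty), mirroring gap-junction blockade abolishing both
#' multicellular waves and single-cell oscillations.
#'
#' @param tissue A `tissue_map` from [build_tissue_map()].
#' @param config A `sim_config`.
#' @param rate_override_mhz Optional named numeric vector (names are cell
#'   ids) replacing the type-level intrinsic rate for specific cells, e.g.
#'   to model localized initiation sites or heterogeneous excitability.
#'   Overrides are applied before the CBX suppression factor.
#' @return A tibble (`spike_table`) with columns `cell_id`, `time_s`,
#'   `origin` (`"intrinsic"` or `"propagated"`) and `wave_id`, ordered by
#'   time. Identical seed and config give a bit-identical table.
#' @export
simulate_spikes <- function(tissue, config, rate_override_mhz = NULL) {
  stopifnot(inherits(tissue, "tissue_map"), inherits(config, "sim_config"))
  D <- config$refractory
  cell_rates <- config$rates_mhz[tissue$cells$cell_type] / 1000  # -> Hz
  names(cell_rates) <- tissue$cells$cell_id
  if (!is.null(rate_override_mhz)) {
    ids <- names(rate_override_mhz)
    if (is.null(ids) || !all(ids %in% names(cell_rates))) {
      stop("rate_override_mhz must be named by existing cell ids")
    }
    cell_rates[ids] <- rate_override_mhz / 1000
  }
  if (config$cbx) cell_rates <- cell_rates * config$cbx_suppression
  if (any(cell_rates > 0 & cell_rates * D >= 1)) {
    stop("intrinsic rate incompatible with refractory period: need ",
         "rate * refractory < 1 (mean interval must exceed the dead time)")
  }

  cells <- tissue$cells
  type_of <- setNames(cells$cell_type, cells$cell_id)
  n_types <- config$propagation_prob
  if (config$cbx) n_types[] <- 0

  # neighbour lookup: list of (neighbour id, permeability), sorted
  nbrs <- vector("list", max(cells$cell_id))
  if (nrow(tissue$edges) > 0) {
    e <- tissue$edges
    both <- rbind(
      data.frame(a = e$from, b = e$to, perm = e$permeability),
      data.frame(a = e$to, b = e$from, perm = e$permeability)
    )
    both <- both[order(both$a, both$b), ]
    sp <- split(both[, c("b", "perm")], both$a)
    nbrs[as.integer(names(sp))] <- sp
  }

  withr::with_seed(config$seed, {
    # intrinsic candidate times, cell by cell in id order
    ev_time <- numeric(0); ev_cell <- integer(0)
    ev_origin <- integer(0); ev_wave <- integer(0)   # origin 1=intr, 2=prop
    for (i in seq_len(nrow(cells))) {
      r <- cell_rates[[i]]
      if (r <= 0) next
      lam <- 1 / (1 / r - D)                  # dead-time-corrected rate
      mu <- 1 / r
      # equilibrium first arrival: U(0,D) w.p. D/mu, else D + Exp(lam)
      t <- if (runif(1) < D / mu) runif(1, 0, D) else D + rexp(1, lam)
      while (t <= config$duration) {
        ev_time <- c(ev_time, t)
        ev_cell <- c(ev_cell, cells$cell_id[i])
        ev_origin <- c(ev_origin, 1L)
        ev_wave <- c(ev_wave, NA_integer_)
        t <- t + D + rexp(1, lam)
      }
    }

    alive <- rep(TRUE, length(ev_time))
    last_spike <- rep(-Inf, max(cells$cell_id))
    next_wave <- 0L
    out_cell <- integer(0); out_time <- numeric(0)
    out_origin <- character(0); out_wave <- integer(0)
    guard <- 0L

    while (any(alive)) {
      guard <- guard + 1L
      if (guard > 1e6) stop("event cascade exceeded 1e6 events")
      idx <- which(alive)
      j <- idx[which.min(ev_time[idx])]
      alive[j] <- FALSE
      cid <- ev_cell[j]; t <- ev_time[j]
      if (t > config$duration) next
      if (t - last_spike[cid] < D) next       # refractory: spike suppressed
      last_spike[cid] <- t
      if (ev_origin[j] == 1L) {
        next_wave <- next_wave + 1L
        w <- next_wave
      } else {
        w <- ev_wave[j]
      }
      out_cell <- c(out_cell, cid)
      out_time <- c(out_time, t)
      out_origin <- c(out_origin,
                      if (ev_origin[j] == 1L) "intrinsic" else "propagated")
      out_wave <- c(out_wave, w)
      nb <- nbrs[[cid]]
      if (!is.null(nb) && nrow(nb) > 0) {
        for (k in seq_len(nrow(nb))) {
          p <- n_types[type_of[[as.character(cid)]],
                       type_of[[as.character(nb$b[k])]]] * nb$perm[k]
          if (p > 0 && runif(1) < p) {
            ev_time <- c(ev_time, t + config$propagation_delay)
            ev_cell <- c(ev_cell, as.integer(nb$b[k]))
            ev_origin <- c(ev_origin, 2L)
            ev_wave <- c(ev_wave, w)
            alive <- c(alive, TRUE)
          }
        }
      }
    }

    ord <- order(out_time, out_cell)
    tibble::tibble(cell_id = out_cell[ord], time_s = out_time[ord],
                   origin = out_origin[ord], wave_id = out_wave[ord])
  })
}

#' Write / read a ground-truth spike table
#'
#' CSV with header `cell_id,time_s,origin,wave_id`; reading back a written
#' table reproduces it exactly.
#'
#' @param spikes Spike table from [simulate_spikes()].
#' @param path File path.
#' @return `write_spike_table` returns `path` invisibly; `read_spike_table`
#'   returns the tibble.
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(all(c("cell_id", "time_s", "origin", "wave_id") %in%
                  names(spikes)))
  df <- as.data.frame(spikes[, c("cell_id", "time_s", "origin", "wave_id")])
  df$time_s <- sprintf("%.17g", df$time_s)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- read.csv(path, colClasses = c(cell_id = "integer",
                                      time_s = "numeric",
                                      origin = "character",
                                      wave_id = "integer"))
  tibble::as_tibble(df)
}
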