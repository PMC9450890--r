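#' Pipeline run configuration
#'
#' Bundles the simulator and analysis parameters for an end-to-end run on
#' synthetic tissue. Any `sim_config()` argument can be overridden through
#' `...`; analysis thresholds mirror the defaults of the stage functions.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @param outdir Output directory (created if missing).
#' @param gut_id Label for the simulated gut.
#' @param cbx Run the gap-junction-blocked condition.
#' @param n_cc,type_counts,field_size Tissue layout (see
#'   [build_tissue_map()]).
#' @param trace_noise_sd Trace-level noise added by the rendering shortcut
#'   used for analysis (`NULL` = derive cell-mean noise from the movie).
#' @param max_lag Correlation lag bound in seconds.
#' @param link_window Wave-linking window in seconds (`NULL` = 3 x the
#'   propagation delay).
#' @param min_duration Minimum trace duration for frequency inclusion (s).
#' @param n_pairs Maximum number of direct and of non-direct
#'   enterocyte-progenitor pairs to correlate.
#' @param ... Passed to [sim_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("midgutca_run_"),
                       gut_id = "gut1", cbx = FALSE,
                       n_cc = 15,
                       type_counts = c(IC = 15, EE = 10, PROG = 10),
                       field_size = c(64L, 64L),
                       trace_noise_sd = NULL,
                       max_lag = 12, link_window = NULL,
                       min_duration = 290, n_pairs = 8, ...) {
  sim <- sim_config(cbx = cbx, seed = seed, ...)
  structure(list(seed = as.integer(seed), outdir = outdir, gut_id = gut_id,
                 n_cc = n_cc, type_counts = type_counts,
                 field_size = field_size, sim = sim,
                 trace_noise_sd = trace_noise_sd,
                 max_lag = max_lag,
                 link_window = link_window %||% (3 * sim$propagation_delay),
                 min_duration = min_duration, n_pairs = n_pairs),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a tissue, spike dynamics (two spectrally separate channels:
#' GCaMP over all cells, and an independent RCaMP channel carrying only
#' progenitor spikes), renders and writes movies, extracts per-cell traces,
#' detects peaks and summarizes oscillation frequencies (tables both
#' including and excluding non-oscillating cells), computes lagged
#' cross-correlations for direct and non-direct enterocyte-progenitor
#' pairs, links multicellular waves, and writes a machine-readable
#' manifest. All outputs are deterministic functions of the seed.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory objects (`tissue`,
#'   `spikes`, `traces`, `frequencies`, `summary_incl`, `summary_excl`,
#'   `correlations`, `waves`, `manifest`) and `files` (named paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$outdir, ...)
  files <- list()
  sim <- config$sim

  tissue <- build_tissue_map(n_cc = config$n_cc,
                             field_size = config$field_size,
                             type_counts = config$type_counts,
                             seed = config$seed)
  files$tissue <- write_tissue_map(tissue, fp("tissue.json"))

  spikes <- simulate_spikes(tissue, sim)
  files$ground_truth <- write_spike_table(spikes, fp("spikes_gcamp.csv"))

  # independent second channel: progenitor spikes only
  rates2 <- sim$rates_mhz * c(IC = 0, CC = 0, EE = 0, PROG = 1)[
    names(sim$rates_mhz)]
  sim2 <- sim
  sim2$rates_mhz <- rates2
  sim2$propagation_prob[] <- 0
  sim2$seed <- sim$seed + 1000L
  spikes2 <- simulate_spikes(tissue, sim2)
  files$ground_truth_rcamp <- write_spike_table(spikes2,
                                                fp("spikes_rcamp.csv"))

  movie <- render_movie(tissue, spikes, sim, channel = "GCaMP")
  movie2 <- render_movie(tissue, spikes2, sim2, channel = "RCaMP",
                         seed = sim$seed + 3L)
  files$movie_gcamp <- write_movie(movie, fp("movie_gcamp.tif"))
  files$movie_rcamp <- write_movie(movie2, fp("movie_rcamp.tif"))

  traces <- tissue_traces(movie, tissue, gut_id = config$gut_id)
  traces2 <- tissue_traces(movie2, tissue, gut_id = config$gut_id,
                           channel = "RCaMP")
  files$traces <- write_traces(dplyr::bind_rows(traces, traces2),
                               fp("traces.csv"))

  freqs <- trace_frequencies(traces, min_duration = config$min_duration)
  files$frequencies <- local({
    p <- fp("frequency_cells.csv")
    write.csv(as.data.frame(freqs), p, row.names = FALSE)
    p
  })
  sum_incl <- gut_summary(freqs, include_nonoscillating = TRUE)
  sum_excl <- tryCatch(gut_summary(freqs, include_nonoscillating = FALSE),
                       warning = function(w) {
                         suppressWarnings(
                           gut_summary(freqs, include_nonoscillating = FALSE))
                       },
                       error = function(e) NULL)
  files$frequency_guts_including <- local({
    p <- fp("frequency_guts_including.csv")
    write.csv(as.data.frame(sum_incl$across_guts), p, row.names = FALSE)
    p
  })
  files$frequency_guts_excluding <- local({
    p <- fp("frequency_guts_excluding.csv")
    df <- if (is.null(sum_excl)) data.frame() else
      as.data.frame(sum_excl$across_guts)
    write.csv(df, p, row.names = FALSE)
    p
  })

  # enterocyte (IC, GCaMP) vs progenitor (PROG, RCaMP) pairs
  peaks_detected <- NULL
  files$peaks <- local({
    p <- fp("peaks.csv")
    pk <- traces |>
      dplyr::group_by(.data$gut_id, .data$cell_id, .data$cell_type) |>
      dplyr::group_modify(function(d, key) {
        ps <- detect_peaks(normalize_trace(d$F, d$t_s))
        tibble::tibble(peak_time_s = ps$peak_times,
                       height = ps$peak_heights)
      }) |>
      dplyr::ungroup()
    peaks_detected <<- pk
    write.csv(as.data.frame(pk), p, row.names = FALSE)
    p
  })

  corr <- correlate_pairs(traces, traces2, tissue,
                          max_lag = config$max_lag,
                          n_pairs = config$n_pairs)
  files$correlations <- local({
    p <- fp("correlations.csv")
    write.csv(as.data.frame(corr$matrix), p, row.names = FALSE)
    p
  })
  files$correlation_summary <- local({
    p <- fp("correlation_summary.json")
    s <- summarize_independence(corr$matrix)
    jsonlite::write_json(list(summary = s$summary,
                              thresholds = s$thresholds),
                         p, auto_unbox = TRUE, digits = NA)
    p
  })

  acts <- detect_activations(traces)
  waves <- link_waves(acts, tissue, link_window = config$link_window)
  files$waves <- local({
    p <- fp("waves.csv")
    write.csv(as.data.frame(waves$waves), p, row.names = FALSE)
    p
  })
  rep <- wave_report(waves)
  files$wave_report <- local({
    p <- fp("wave_report.json")
    jsonlite::write_json(
      list(n_waves = rep$n_waves, n_multicellular = rep$n_multicellular,
           max_extent = rep$max_extent,
           cc_member_fraction = rep$cc_member_fraction,
           cc_wave_fraction = rep$cc_wave_fraction),
      p, auto_unbox = TRUE, digits = NA)
    p
  })

  cfg_path <- fp("config.json")
  cfg_json <- list(seed = config$seed, gut_id = config$gut_id,
                   n_cc = config$n_cc,
                   type_counts = as.list(config$type_counts),
                   field_size = as.integer(config$field_size),
                   sim = unclass(sim)[setdiff(names(sim),
                                              "propagation_prob")],
                   propagation_prob = sim$propagation_prob,
                   max_lag = config$max_lag,
                   link_window = config$link_window,
                   min_duration = config$min_duration)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_path))

  # manifest paths are relative to the run directory so that a run is
  # byte-identical wherever it is placed
  rel <- function(x) basename(unlist(x))
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash,
    artifact_classes = list(
      movie = rel(c(files$movie_gcamp, files$movie_rcamp)),
      ground_truth = rel(c(files$ground_truth, files$ground_truth_rcamp)),
      traces = rel(files$traces),
      peaks = rel(files$peaks),
      frequency = rel(c(files$frequencies, files$frequency_guts_including,
                        files$frequency_guts_excluding)),
      correlation = rel(c(files$correlations, files$correlation_summary)),
      waves = rel(c(files$waves, files$wave_report))
    )
  )
  files$manifest <- fp("manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(tissue = tissue, spikes = spikes,
                 traces = dplyr::bind_rows(traces, traces2),
                 frequencies = freqs, summary_incl = sum_incl,
                 summary_excl = sum_excl, peaks = peaks_detected,
                 correlations = corr, waves = waves, report = rep,
                 manifest = manifest, files = files))
}

# Direct pairs: (IC enterocyte, PROG progenitor) sharing a tissue edge,
# correlating the enterocyte's GCaMP trace against the progenitor's
# independent RCaMP trace. Non-direct pairs: non-adjacent combinations.
#' @noRd
correlate_pairs <- function(traces_g, traces_r, tissue, max_lag = 12,
                            n_pairs = 8) {
  cells <- tissue$cells
  ics <- cells$cell_id[cells$cell_type == "IC"]
  progs <- cells$cell_id[cells$cell_type == "PROG"]
  if (length(ics) == 0 || length(progs) == 0) {
    return(list(matrix = tibble::tibble(), pairs = tibble::tibble()))
  }
  e <- tissue$edges
  adj <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  combos <- expand.grid(ec = ics, pr = progs)
  combos$direct <- paste(pmin(combos$ec, combos$pr),
                         pmax(combos$ec, combos$pr)) %in% adj
  direct <- head(combos[combos$direct, ], n_pairs)
  indirect <- head(combos[!combos$direct, ], n_pairs)
  pairs <- rbind(direct, indirect)
  if (nrow(pairs) == 0) {
    return(list(matrix = tibble::tibble(), pairs = tibble::tibble()))
  }
  # assemble a joint trace table with unique series ids per channel
  tg <- traces_g[traces_g$cell_id %in% pairs$ec, ]
  tg$cell_id <- paste0("EC", tg$cell_id)
  tr <- traces_r[traces_r$cell_id %in% pairs$pr, ]
  tr$cell_id <- paste0("PR", tr$cell_id)
  joint <- dplyr::bind_rows(tg, tr)
  ptab <- tibble::tibble(series_a = paste0("EC", pairs$ec),
                         series_b = paste0("PR", pairs$pr),
                         direct = pairs$direct)
  list(matrix = pair_matrix(joint, ptab, max_lag = max_lag), pairs = ptab)
}
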