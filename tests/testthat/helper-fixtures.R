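# Fixtures built in code: hand-constructed tissues with known geometry, and
# independent oracles used across tests.

# Tissue map from an explicit label matrix and per-cell types.
make_tissue <- function(label, types, um_per_px = 2, cc_permeability = 1) {
  structure(
    list(cells = midgutCa:::tissue_cells_table(label, types, um_per_px),
         edges = midgutCa:::tissue_edges(label, types, cc_permeability),
         label = label,
         field_size = c(ny = nrow(label), nx = ncol(label)),
         um_per_px = um_per_px, seed = 0L),
    class = "tissue_map"
  )
}

# n square cells of side `block` px in a single row (a 1-D chain).
line_tissue <- function(n, types = rep("IC", n), block = 4L,
                        um_per_px = 2, cc_permeability = 1) {
  label <- matrix(0L, block, n * block)
  for (i in seq_len(n)) {
    label[, ((i - 1L) * block + 1L):(i * block)] <- i
  }
  make_tissue(label, types, um_per_px, cc_permeability)
}

# nr x nc lattice of square IC cells.
lattice_tissue <- function(nr, nc, block = 4L, um_per_px = 2) {
  label <- matrix(0L, nr * block, nc * block)
  id <- 0L
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    id <- id + 1L
    label[((r - 1L) * block + 1L):(r * block),
          ((co - 1L) * block + 1L):(co * block)] <- id
  }
  make_tissue(label, rep("IC", nr * nc), um_per_px)
}

# n cells with no gap-junction contacts (independent-cell control).
isolated_tissue <- function(n, types = rep("IC", n), block = 4L) {
  tis <- line_tissue(n, types, block)
  tis$edges <- tis$edges[0, ]
  tis
}

# Hand-rolled spike table for driving the renderer directly.
spike_tbl <- function(cell_id, times, origin = "intrinsic",
                      wave_id = seq_along(times)) {
  tibble::tibble(cell_id = as.integer(cell_id), time_s = as.numeric(times),
                 origin = origin, wave_id = as.integer(wave_id))
}

# Independent brute-force double-loop oracle for the lagged
# cross-correlation (full-series means and denominators).
xcorr_oracle <- function(e, p, H) {
  n <- length(e)
  mu_e <- mean(e); mu_p <- mean(p)
  den <- sqrt(sum((e - mu_e)^2)) * sqrt(sum((p - mu_p)^2))
  vapply((-H):H, function(h) {
    num <- 0
    for (i in seq_len(n)) {
      if (i + h >= 1 && i + h <= n) {
        num <- num + (e[i + h] - mu_e) * (p[i] - mu_p)
      }
    }
    num / den
  }, numeric(1))
}

# Match detected peak/activation times to ground-truth spike times within
# a tolerance; returns counts of true/false positives and false negatives.
match_events <- function(detected, truth, tol) {
  tp <- sum(vapply(detected, function(t) any(abs(t - truth) <= tol),
                   logical(1)))
  fp <- length(detected) - tp
  fn <- sum(!vapply(truth, function(t) any(abs(detected - t) <= tol),
                    logical(1)))
  list(tp = tp, fp = fp, fn = fn)
}
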