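# Small in-code fixtures shared across test files.

# registry restricted to a few populations with tiny cell counts
mini_geometry <- function(pops = c("pyrRS23", "bask23", "TCR"),
                          n = c(2L, 2L, 1L), radius = 200) {
  reg <- build_registry(1)
  reg <- reg[match(pops, reg$abbreviation), ]
  reg$n_cells <- n
  rownames(reg) <- NULL
  column_geometry(column_radius = radius, populations = reg)
}

# desk-scale pulse preset (stimulus onset 20 ms, 50 ms run)
mini_preset <- function(stop = 50, stim_delay = 20, components = TRUE,
                        kind = "pulse", f = 12.5,
                        depol_pop5 = 0.5, depol_pop6 = 0.375) {
  stim <- if (kind == "pulse")
    stimulus_spec("pulse", t0 = stim_delay, pulse_amplitude = 3,
                  pulse_width = 2)
  else if (kind == "none")
    stimulus_spec("none")
  else
    stimulus_spec(kind, I_inj = 2, f = f, t0 = stim_delay,
                  duration = stop - stim_delay)
  structure(list(id = 24L, label = "desk-scale fixture",
                 size_fraction = 0.01, stop = stop,
                 stim_delay = stim_delay, stim_duration = 2,
                 depol_pop5 = depol_pop5, depol_pop6 = depol_pop6,
                 stimulus = stim, input_source = NULL,
                 records_channel_components = components),
            class = "dataset_preset")
}

# full small fixture: geometry, segments, activity (with components),
# spikes; memoised per test file
.fixture_cache <- new.env(parent = emptyenv())
make_fixture <- function(seed = 42, components = TRUE) {
  key <- paste0("f", seed, components)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  geom <- mini_geometry()
  somas <- place_somas(geom, seed)
  segments <- build_morphologies(geom, somas, seed + 1L)
  preset <- mini_preset(components = components)
  run <- synthesize_activity(segments, preset, seed + 2L)
  fx <- list(geometry = geom, segments = segments, preset = preset,
             activity = run$activity, spikes = run$spikes)
  .fixture_cache[[key]] <- fx
  fx
}

# degenerate segment table whose midpoints sit exactly at `pos`
point_segments <- function(pos, cell_id = "cellA", population = "pyrRS23",
                           diameter = 2) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  data.frame(
    segment_id = if (n == 0) character(0)
                 else paste0(rep(cell_id, length.out = n), "/seg_",
                             seq_len(n)),
    cell_id = rep(cell_id, length.out = n),
    population = rep(population, length.out = n),
    x0 = pos[, 1], y0 = pos[, 2], z0 = pos[, 3],
    x1 = pos[, 1], y1 = pos[, 2], z1 = pos[, 3],
    diameter = rep(diameter, length.out = n), stringsAsFactors = FALSE)
}

# hand-built activity_traces around a current matrix (segments x samples)
make_activity <- function(segments, i_total,
                          v = matrix(-65, nrow(i_total), ncol(i_total)),
                          components = NULL, dt = 0.1) {
  structure(list(time_start = 0, dt = dt, n_samples = ncol(i_total),
                 i_total = i_total, v = v, components = components,
                 segment_id = segments$segment_id,
                 cell_id = segments$cell_id,
                 population = segments$population),
            class = "activity_traces")
}

# hand-built potential_recording around a trace matrix
make_recording <- function(phi, electrodes = NULL, dt = 0.1) {
  if (is.null(electrodes))
    electrodes <- electrode_array(cbind(seq_len(nrow(phi)), 0, 0))
  structure(list(phi = phi, electrodes = electrodes, dt = dt,
                 time_start = 0,
                 provenance = list(sigma = 0.3, filter = "none")),
            class = "potential_recording")
}
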