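# LFP extraction and display preparation.

#' Low-pass filter specification for LFP extraction
#'
#' A 2nd-order Butterworth low-pass, cutoff 100 Hz by default (the
#' convention used for the published LFP panels). Two application
#' modes: `zero_phase_two_pass` filters forward and backward (squared
#' magnitude response, no phase lag; the display default) and
#' `causal_single_pass` applies the filter once.
#'
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist
#'   frequency of the recording (5000 Hz at the 0.1 ms time base).
#' @param order filter order.
#' @param application `"zero_phase_two_pass"` or
#'   `"causal_single_pass"`.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 100, order = 2,
                        application = c("zero_phase_two_pass",
                                        "causal_single_pass")) {
  stopifnot(cutoff > 0, order >= 1)
  structure(list(cutoff = cutoff, order = order,
                 application = match.arg(application)),
            class = "filter_spec")
}

# Reflective (odd) padding of one settling length at each end, so the
# filter transient falls on padding, not data.
.pad_reflect <- function(x, p) {
  p <- min(p, length(x) - 1L)
  if (p < 1L) return(list(x = x, p = 0L))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - p)]
  list(x = c(left, x, right), p = p)
}

.butter_apply <- function(x, ba, two_pass, p) {
  pad <- .pad_reflect(x, p)
  y <- as.numeric(signal::filter(ba, pad$x))
  if (two_pass)
    y <- rev(as.numeric(signal::filter(ba, rev(y))))
  if (pad$p > 0) y <- y[(pad$p + 1):(pad$p + length(x))]
  y
}

#' Extract the LFP from a potential recording
#'
#' Filters each electrode trace independently with the Butterworth
#' low-pass of `spec`. DC gain is 1. Edge handling: odd-reflective
#' padding of several settling lengths (`5 * fs / cutoff` samples)
#' at both ends.
#'
#' @param recording a `potential_recording`.
#' @param spec a [filter_spec()].
#' @return a `potential_recording` with filtered traces; the filter is
#'   recorded in the provenance.
#' @export
lowpass_lfp <- function(recording, spec = filter_spec()) {
  # padding of ~5 settling lengths keeps the residual start-up
  # transient below 1e-9 of the trace scale
  stopifnot(inherits(recording, "potential_recording"),
            inherits(spec, "filter_spec"))
  fs <- 1000 / recording$dt                 # Hz
  if (spec$cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, fs / 2))
  ba <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  p <- as.integer(ceiling(5 * fs / spec$cutoff))
  two <- spec$application == "zero_phase_two_pass"
  out <- recording
  out$phi <- t(apply(recording$phi, 1, .butter_apply, ba = ba,
                     two_pass = two, p = p))
  rownames(out$phi) <- recording$electrodes$labels
  out$provenance$filter <- sprintf("butterworth order %d, %g Hz, %s",
                                   spec$order, spec$cutoff,
                                   spec$application)
  out
}

#' Bilinearly interpolate an MEA recording in its plane
#'
#' For a recording made on a regular grid (from [mea_grid()]),
#' interpolates the potential at one time point onto a finer grid in
#' the electrode plane. Values at the electrode sites are reproduced
#' exactly.
#'
#' @param recording a `potential_recording` whose electrode array is a
#'   regular grid.
#' @param t time, ms (snapped to the nearest sample).
#' @param resolution upsampling factor per electrode pitch.
#' @param query optional n x 2 matrix of (y, z) query points; overrides
#'   the regular upsampled grid.
#' @return list with `y`, `z` (coordinates, um) and `values` (matrix
#'   z x y, mV), or a vector of values at `query` points.
#' @export
interpolate_plane <- function(recording, t, resolution = 5,
                              query = NULL) {
  grid <- recording$electrodes$grid
  if (is.null(grid))
    stop("electrode array is not a regular grid; build it with mea_grid()")
  k <- round((t - recording$time_start) / recording$dt) + 1
  if (k < 1 || k > ncol(recording$phi))
    stop("time outside the recording")
  # phi rows are ordered row-fastest (depth) within column (lateral)
  Z <- matrix(recording$phi[, k], grid$n_rows, grid$n_cols)
  if (!is.null(query)) {
    query <- as.matrix(query)
    return(pracma::interp2(grid$y, grid$z, Z,
                           query[, 1], query[, 2], method = "linear"))
  }
  yq <- seq(min(grid$y), max(grid$y), length.out =
              (grid$n_cols - 1) * resolution + 1)
  zq <- seq(min(grid$z), max(grid$z), length.out =
              (grid$n_rows - 1) * resolution + 1)
  vals <- outer(zq, yq, function(zz, yy)
    pracma::interp2(grid$y, grid$z, Z, yy, zz, method = "linear"))
  list(y = yq, z = zq, values = vals)
}

#' Prepare spike data for a raster plot
#'
#' Rows are ordered by population (registry order) then cell; each
#' population gets a colour; excitatory cells get an up marker,
#' inhibitory cells a down marker.
#'
#' @param spikes a `spike_events`.
#' @param registry a registry from [build_registry()].
#' @return `data.frame` with one row per spike: `cell_id`,
#'   `population`, `row`, `time`, `cell_class`, `marker`
#'   (`"up"`/`"down"`), `color`.
#' @export
raster <- function(spikes, registry) {
  cells <- names(spikes)
  if (length(cells) == 0)
    return(data.frame(cell_id = character(0), population = character(0),
                      row = integer(0), time = numeric(0),
                      cell_class = character(0), marker = character(0),
                      color = character(0), stringsAsFactors = FALSE))
  pop_of <- sub("_[0-9]+$", "", cells)
  bad <- setdiff(pop_of, registry$abbreviation)
  if (length(bad))
    stop("unknown cell id(s) for population(s): ",
         paste(unique(bad), collapse = ", "))
  pal <- grDevices::hcl.colors(nrow(registry), "Dark 3")
  ord <- order(match(pop_of, registry$abbreviation), cells)
  cells <- cells[ord]; pop_of <- pop_of[ord]
  ridx <- match(pop_of, registry$abbreviation)
  n_sp <- lengths(spikes[cells])
  data.frame(
    cell_id = rep(cells, n_sp),
    population = rep(pop_of, n_sp),
    row = rep(seq_along(cells), n_sp),
    time = unlist(spikes[cells], use.names = FALSE),
    cell_class = rep(registry$cell_class[ridx], n_sp),
    marker = rep(ifelse(registry$cell_class[ridx] == "excitatory",
                        "up", "down"), n_sp),
    color = rep(pal[ridx], n_sp),
    stringsAsFactors = FALSE)
}

#' Plot a raster of network spiking
#'
#' Up/down triangles per excitatory/inhibitory cell, coloured by
#' population, with an optional stimulus-onset line.
#'
#' @param rast output of [raster()].
#' @param stim_onset optional stimulus onset time, ms (vertical line).
#' @param file optional PNG path; `NULL` draws on the active device.
#' @return `NULL`, invisibly.
#' @export
plot_raster <- function(rast, stim_onset = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  plot(NULL, xlim = range(c(rast$time, stim_onset, 0, 1)),
       ylim = c(0, max(c(rast$row, 1)) + 1), xlab = "time (ms)",
       ylab = "cell", main = "network spiking")
  if (nrow(rast))
    graphics::points(rast$time, rast$row,
                     pch = ifelse(rast$marker == "up", 24, 25),
                     col = rast$color, bg = rast$color, cex = 0.6)
  if (!is.null(stim_onset))
    graphics::abline(v = stim_onset, col = "black", lwd = 2)
  invisible(NULL)
}

#' Depth-by-time image of a laminar recording
#'
#' @param recording a `potential_recording` from a laminar probe.
#' @param file optional PNG path.
#' @return `NULL`, invisibly.
#' @export
plot_laminar <- function(recording, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  tt <- recording$time_start +
    (seq_len(ncol(recording$phi)) - 1) * recording$dt
  depth <- recording$electrodes$positions[, "z"]
  graphics::image(tt, seq_along(depth), t(recording$phi),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "time (ms)", ylab = "electrode",
                  main = "extracellular potential (mV)")
  graphics::axis(4, at = seq_along(depth), labels = round(depth))
  invisible(NULL)
}

#' Interpolated MEA frame at one time point
#'
#' @param recording a `potential_recording` from [mea_grid()].
#' @param t time, ms.
#' @param file optional PNG path.
#' @return `NULL`, invisibly.
#' @export
plot_plane <- function(recording, t, file = NULL) {
  fld <- interpolate_plane(recording, t)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 800)
    on.exit(grDevices::dev.off())
  }
  graphics::image(fld$y, fld$z, t(fld$values), ylim = rev(range(fld$z)),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "y (um)", ylab = "depth (um)",
                  main = sprintf("potential at %g ms (mV)", t))
  invisible(NULL)
}
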