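# Point-source forward model: phi(x, t) = 1/(4 pi sigma) * sum_n
# I_n(t) / |x - x_n|, sources at segment midpoints, infinite homogeneous
# resistive medium, ideal point electrodes.
#
# Units contract (asserted by a dedicated test): with currents in nA,
# distances in um and sigma in S/m, the potential comes out directly in
# mV, because 1 nA / (S/m * um) = 1e-9 A / (1e-6 S) = 1e-3 V.

#' Volume-conductor model
#'
#' @param sigma extracellular conductivity, S/m.
#' @param min_distance_clamp minimum source-electrode distance, um.
#'   `NULL` (default) clamps each source at half its segment diameter;
#'   `0` disables clamping and raises an error if an electrode
#'   coincides with a source.
#' @return object of class `medium_model`.
#' @export
medium_model <- function(sigma = 0.3, min_distance_clamp = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  structure(list(sigma = sigma, min_distance_clamp = min_distance_clamp),
            class = "medium_model")
}

#' Electrode array constructor
#'
#' @param positions numeric matrix (n x 3) of x, y, z in um.
#' @param labels unique electrode labels; default E001, E002, ...
#' @return object of class `electrode_array`.
#' @export
electrode_array <- function(positions, labels = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(labels))
    labels <- sprintf("E%03d", seq_len(nrow(positions)))
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, labels = labels),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d electrodes%s\n", nrow(x$positions),
              if (!is.null(x$grid))
                sprintf(" (%d x %d grid)", x$grid$n_rows, x$grid$n_cols)
              else ""))
  invisible(x)
}

#' Laminar (linear depth) probe
#'
#' Electrodes colinear along the depth axis, as used for the published
#' laminar recordings (28 contacts, 92.6 um spacing).
#'
#' @param n_electrodes number of contacts.
#' @param spacing inter-electrode distance, um.
#' @param lateral_offset x offset from the column axis, um.
#' @param top_depth depth of the shallowest contact, um.
#' @return an `electrode_array`; contact k sits at depth
#'   `top_depth + (k-1) * spacing`.
#' @export
laminar_probe <- function(n_electrodes = 28, spacing = 92.6,
                          lateral_offset = 0, top_depth = 0) {
  stopifnot(n_electrodes >= 1, spacing > 0)
  z <- top_depth + (seq_len(n_electrodes) - 1) * spacing
  electrode_array(cbind(lateral_offset, 0, z),
                  sprintf("L%02d", seq_len(n_electrodes)))
}

#' Planar multielectrode array (MEA) beside the column
#'
#' Regular grid in a plane parallel to the column axis, at
#' `plane_offset` from it (the published MEA is 16 x 20 at 25 um). The
#' inter-electrode pitch is not part of the published geometry and must
#' be supplied. The grid is centred laterally on the axis and vertically
#' on `center_depth` (default: the cortical depth midline, 850 um).
#'
#' @param n_rows rows along depth (z).
#' @param n_cols columns along the lateral (y) direction.
#' @param pitch inter-electrode spacing, um (required).
#' @param plane_offset distance of the plane from the axis (x), um.
#' @param center_depth depth of the grid centre, um.
#' @param center_lateral lateral (y) centre, um.
#' @return an `electrode_array` carrying its grid structure.
#' @export
mea_grid <- function(n_rows = 16, n_cols = 20, pitch,
                     plane_offset = 25, center_depth = 850,
                     center_lateral = 0) {
  if (missing(pitch)) stop("'pitch' is required (no published default)")
  stopifnot(pitch > 0, n_rows >= 1, n_cols >= 1)
  z <- center_depth + (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  y <- center_lateral + (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  pos <- cbind(plane_offset, rep(y, each = n_rows), rep(z, n_cols))
  arr <- electrode_array(pos,
                         sprintf("M%02d_%02d",
                                 rep(seq_len(n_rows), n_cols),
                                 rep(seq_len(n_cols), each = n_rows)))
  arr$grid <- list(n_rows = n_rows, n_cols = n_cols, z = z, y = y,
                   plane_offset = plane_offset)
  arr
}

#' Load an electrode layout from a plain-text table
#'
#' One electrode per line: `label x y z` (um), whitespace-delimited,
#' `#` comments allowed. Covers arbitrary 1D/2D/3D setups.
#'
#' @param path file path.
#' @return an `electrode_array`.
#' @export
read_electrode_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  electrode_array(as.matrix(tab[, c("x", "y", "z")]), tab$label)
}

.cortical_pops <- function() {
  tab <- .population_table()
  tab$abbreviation[tab$is_cortical]
}

# resolve the (population, component) selection against an activity
# object; returns list(rows, sources) where sources is a list of
# segments x samples matrices to be summed
.resolve_selection <- function(activity, populations, components) {
  if (is.null(populations)) {
    populations <- intersect(.cortical_pops(), unique(activity$population))
  } else {
    bad <- setdiff(populations, unique(activity$population))
    if (length(bad))
      stop("unknown population(s) in selection: ",
           paste(bad, collapse = ", "))
  }
  rows <- which(activity$population %in% populations)
  if (is.null(components)) {
    src <- activity$i_total[rows, , drop = FALSE]
  } else {
    channel_labels(check = components)
    if (is.null(activity$components))
      stop("activity carries no per-channel components")
    bad <- setdiff(components, names(activity$components))
    if (length(bad))
      stop("component(s) not recorded: ", paste(bad, collapse = ", "))
    src <- 0
    for (l in components)
      src <- src + activity$components[[l]][rows, , drop = FALSE]
  }
  list(rows = rows, populations = populations, current = src)
}

#' Extracellular potential at an electrode array
#'
#' Evaluates the point-source sum for every electrode and sample. The
#' default selection is the total transmembrane current of all cortical
#' populations (the thalamic populations are excluded unless named
#' explicitly).
#'
#' @param activity an `activity_traces`.
#' @param segments segment table aligned with `activity`.
#' @param electrodes an `electrode_array`.
#' @param medium a [medium_model()].
#' @param populations populations to include (`NULL` = all cortical).
#' @param components channel labels to include (`NULL` = total current).
#' @return object of class `potential_recording`: matrix `phi`
#'   (electrodes x samples, mV), the electrode array, time base, and a
#'   `provenance` list (populations, components, sigma, clamp).
#' @export
extracellular_potential <- function(activity, segments, electrodes,
                                    medium = medium_model(),
                                    populations = NULL,
                                    components = NULL) {
  stopifnot(inherits(electrodes, "electrode_array"),
            inherits(medium, "medium_model"))
  if (!identical(segments$segment_id, activity$segment_id))
    stop("segments and activity rows are not aligned")
  sel <- .resolve_selection(activity, populations, components)
  pos <- segment_midpoints(segments)[sel$rows, , drop = FALSE]
  clamp <- medium$min_distance_clamp
  clamp_vec <- if (is.null(clamp)) segments$diameter[sel$rows] / 2
               else rep(clamp, length(sel$rows))
  ep <- electrodes$positions
  nE <- nrow(ep)
  G <- matrix(0, nE, length(sel$rows))
  for (e in seq_len(nE)) {
    r <- sqrt((pos[, 1] - ep[e, 1])^2 + (pos[, 2] - ep[e, 2])^2 +
              (pos[, 3] - ep[e, 3])^2)
    r <- pmax(r, clamp_vec)
    if (any(r == 0))
      stop("electrode coincides with a source midpoint and ",
           "min_distance_clamp is 0")
    G[e, ] <- 1 / (4 * pi * medium$sigma * r)
  }
  phi <- G %*% sel$current
  rownames(phi) <- electrodes$labels
  structure(list(phi = phi, electrodes = electrodes,
                 dt = activity$dt, time_start = activity$time_start,
                 provenance = list(populations = sel$populations,
                                   components = components,
                                   sigma = medium$sigma,
                                   min_distance_clamp = clamp,
                                   empty = length(sel$rows) == 0,
                                   filter = "none")),
            class = "potential_recording")
}

#' Contribution of a (population, component) subset to the potential
#'
#' Same computation as [extracellular_potential()] restricted to the
#' subset; contributions over a partition of populations or components
#' superpose to the total recording. An empty subset yields a zero
#' recording whose provenance notes the emptiness.
#'
#' @inheritParams extracellular_potential
#' @param populations character vector of populations (possibly empty).
#' @param components character vector of channel labels, or `NULL` for
#'   the total current.
#' @return a `potential_recording`.
#' @export
contribution <- function(activity, segments, electrodes,
                         medium = medium_model(),
                         populations, components = NULL) {
  if ((!is.null(populations) && length(populations) == 0) ||
      (!is.null(components) && length(components) == 0)) {
    nT <- activity$n_samples
    phi <- matrix(0, nrow(electrodes$positions), nT)
    rownames(phi) <- electrodes$labels
    return(structure(list(phi = phi, electrodes = electrodes,
                          dt = activity$dt,
                          time_start = activity$time_start,
                          provenance = list(populations = populations,
                                            components = components,
                                            sigma = medium$sigma,
                                            min_distance_clamp =
                                              medium$min_distance_clamp,
                                            empty = TRUE,
                                            filter = "none")),
                     class = "potential_recording"))
  }
  extracellular_potential(activity, segments, electrodes, medium,
                          populations = populations,
                          components = components)
}

#' @export
print.potential_recording <- function(x, ...) {
  cat(sprintf("<potential_recording> %d electrodes x %d samples (mV), sigma = %g S/m, filter = %s\n",
              nrow(x$phi), ncol(x$phi), x$provenance$sigma,
              x$provenance$filter))
  invisible(x)
}

#' Export a potential recording as delimited text
#'
#' Tab-separated matrix, one column per electrode, with a one-line
#' header of `label:depth` tokens (depth = electrode z, um); first
#' column is time in ms.
#'
#' @param recording a `potential_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(recording, path) {
  hdr <- c("time_ms", sprintf("%s:%g", recording$electrodes$labels,
                              recording$electrodes$positions[, "z"]))
  tt <- recording$time_start +
    (seq_len(ncol(recording$phi)) - 1) * recording$dt
  tab <- cbind(tt, t(recording$phi))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
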