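# End-to-end pipeline: config handling plus the generate / lfp / plot
# commands wrapped by the exec/lfpsim command-line script.

#' Run configuration
#'
#' A fully serializable description of one pipeline run; a run is
#' reproducible from its config and seed alone.
#'
#' @param preset_id dataset preset id, 1..28.
#' @param seed integer seed covering all randomness of the run.
#' @param size_fraction optional override of the preset's model size
#'   (e.g. 0.01 for desk-scale runs).
#' @param stop optional override of the preset's stop time, ms.
#' @param probe probe description: `list(type = "laminar", ...)` with
#'   [laminar_probe()] arguments, `list(type = "mea", ...)` with
#'   [mea_grid()] arguments, or `list(type = "file", path = ...)`.
#' @param sigma extracellular conductivity, S/m.
#' @param cutoff LFP low-pass cutoff, Hz.
#' @param filter_mode filter application mode, see [filter_spec()].
#' @param populations population selection (`NULL` = cortical).
#' @param components channel-label selection (`NULL` = total current).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset_id = 24, seed = 1, size_fraction = NULL,
                       stop = NULL, probe = list(type = "laminar"),
                       sigma = 0.3, cutoff = 100,
                       filter_mode = "zero_phase_two_pass",
                       populations = NULL, components = NULL,
                       out_dir = ".") {
  structure(list(preset_id = preset_id, seed = seed,
                 size_fraction = size_fraction, stop = stop,
                 probe = probe, sigma = sigma, cutoff = cutoff,
                 filter_mode = filter_mode, populations = populations,
                 components = components, out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration (JSON or YAML)
#'
#' Format follows the file extension: `.json` or `.yml`/`.yaml`.
#'
#' @param path config file path.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  defaults <- run_config()
  for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  class(defaults) <- "run_config"
  defaults
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(unclass(config), path)
  else
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

.config_preset <- function(config) {
  preset <- get_preset(config$preset_id)
  if (!is.null(config$size_fraction))
    preset$size_fraction <- config$size_fraction
  if (!is.null(config$stop)) {
    preset$stop <- config$stop
    preset$stimulus$duration <- min(preset$stimulus$duration,
                                    max(0.1, config$stop -
                                          preset$stim_delay))
  }
  preset
}

.config_probe <- function(config) {
  p <- config$probe
  args <- p[setdiff(names(p), "type")]
  switch(p$type,
         laminar = do.call(laminar_probe, args),
         mea = do.call(mea_grid, args),
         file = read_electrode_table(p$path),
         stop("unknown probe type '", p$type, "'"))
}

#' Generate a dataset and write it as a validating NSDF file
#'
#' Builds the registry at the preset's (or overridden) size, places
#' somas and morphologies, synthesizes activity, writes the NSDF file
#' and validates it. Registry totals and the Kirchhoff residual are
#' logged to stderr.
#'
#' @param config a [run_config()].
#' @param nsdf_path output file; default `<out_dir>/dataset_<id>.h5`.
#' @param overwrite overwrite an existing file?
#' @return path of the written file, invisibly.
#' @export
cmd_generate <- function(config, nsdf_path = NULL, overwrite = FALSE) {
  preset <- .config_preset(config)
  if (is.null(nsdf_path))
    nsdf_path <- file.path(config$out_dir,
                           sprintf("dataset_%02d.h5", preset$id))
  reg <- build_registry(preset$size_fraction)
  geom <- column_geometry(populations = reg)
  somas <- place_somas(geom, config$seed)
  segments <- build_morphologies(geom, somas, config$seed + 1L)
  run <- synthesize_activity(segments, preset, config$seed + 2L)
  message(sprintf("registry: %d populations, %d cells, %d segments",
                  nrow(reg), sum(reg$n_cells), nrow(segments)))
  if (!dir.exists(dirname(nsdf_path)))
    dir.create(dirname(nsdf_path), recursive = TRUE)
  write_nsdf(nsdf_path, segments, run$activity, run$spikes,
             overwrite = overwrite)
  write_run_config(config, paste0(nsdf_path, ".config.json"))
  message(sprintf("kirchhoff residual (relative): %.3g",
                  kirchhoff_residual(run$activity)))
  rep <- validate_nsdf(nsdf_path)
  message(sprintf("validation: %d checks, %d violation(s)",
                  nrow(rep$checks), rep$n_violations))
  if (!rep$ok) stop("generated file failed validation")
  invisible(nsdf_path)
}

#' Compute raw potential and filtered LFP from an NSDF file
#'
#' Reads the file, builds the configured probe, computes the raw
#' extracellular potential and the low-pass LFP, and writes both as
#' delimited text together with a provenance JSON.
#'
#' @param config a [run_config()].
#' @param nsdf_path input NSDF file.
#' @return list with `potential` and `lfp` recordings and the output
#'   paths, invisibly.
#' @export
cmd_lfp <- function(config, nsdf_path) {
  rep <- validate_nsdf(nsdf_path)
  if (!rep$ok) stop("input file failed validation: ", nsdf_path)
  ds <- read_nsdf(nsdf_path)
  probe <- .config_probe(config)
  medium <- medium_model(sigma = config$sigma)
  empty_sel <- (!is.null(config$populations) &&
                  length(config$populations) == 0)
  phi <- contribution(ds$activity, ds$segments, probe, medium,
                      populations = config$populations,
                      components = config$components)
  if (empty_sel) warning("empty population selection: zero traces")
  lfp <- lowpass_lfp(phi, filter_spec(cutoff = config$cutoff,
                                      application = config$filter_mode))
  base <- file.path(config$out_dir,
                    sub("\\.h5$", "", basename(nsdf_path)))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  pot_path <- paste0(base, "_potential.tsv")
  lfp_path <- paste0(base, "_lfp.tsv")
  write_recording_tsv(phi, pot_path)
  write_recording_tsv(lfp, lfp_path)
  prov <- c(phi$provenance[c("populations", "components", "sigma")],
            list(filter = lfp$provenance$filter, seed = config$seed,
                 nsdf = nsdf_path, config = unclass(config)))
  jsonlite::write_json(prov, paste0(base, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  message(sprintf("wrote %d traces x %d samples to %s",
                  nrow(phi$phi), ncol(phi$phi), pot_path))
  invisible(list(potential = phi, lfp = lfp,
                 paths = c(pot_path, lfp_path)))
}

#' Plot pipeline outputs
#'
#' Writes a depth-by-time image of the laminar LFP (or MEA potential),
#' an interpolated 2D frame for MEA probes, and a raster figure.
#'
#' @param config a [run_config()].
#' @param nsdf_path input NSDF file.
#' @param lfp_result optional result of [cmd_lfp()] (recomputed if
#'   missing).
#' @param t_frame time of the 2D frame, ms (MEA probes only); default
#'   mid-recording.
#' @return character vector of figure paths, invisibly.
#' @export
cmd_plot <- function(config, nsdf_path, lfp_result = NULL,
                     t_frame = NULL) {
  if (!file.exists(nsdf_path)) stop("missing input: ", nsdf_path)
  if (is.null(lfp_result)) lfp_result <- cmd_lfp(config, nsdf_path)
  ds <- read_nsdf(nsdf_path)
  base <- file.path(config$out_dir,
                    sub("\\.h5$", "", basename(nsdf_path)))
  figs <- character(0)
  f1 <- paste0(base, "_lfp.png")
  plot_laminar(lfp_result$lfp, file = f1)
  figs <- c(figs, f1)
  if (!is.null(lfp_result$potential$electrodes$grid)) {
    if (is.null(t_frame))
      t_frame <- lfp_result$potential$time_start +
        lfp_result$potential$dt *
        floor(ncol(lfp_result$potential$phi) / 2)
    f2 <- paste0(base, "_frame.png")
    plot_plane(lfp_result$potential, t_frame, file = f2)
    figs <- c(figs, f2)
  }
  preset <- .config_preset(config)
  reg <- build_registry(preset$size_fraction)
  f3 <- paste0(base, "_raster.png")
  plot_raster(raster(ds$spikes, reg), stim_onset = preset$stim_delay,
              file = f3)
  figs <- c(figs, f3)
  invisible(figs)
}
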