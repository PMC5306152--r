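# NSDF (Neuroscience Simulation Data Format) v1.0 persistence.
#
# Layout written (h5py / C-order view):
#   /data/static/morphology/<pop>   compound rows x0,y0,z0,x1,y1,z1,d
#   /data/uniform/<pop>/i , /v      2-D, rows = segments, cols = samples
#   /data/uniform/<pop>/<label>     optional per-channel components
#   /data/event/<pop>/spikes        variable-length rows = cells
#   /map/static/<pop>_names, /map/uniform/<pop>_names,
#   /map/event/<pop>_spikes         id lists, attached to the data
#                                   arrays as HDF5 Dimension Scales
# rhdf5 reverses array dimensions relative to the file's C order, so
# uniform matrices are passed through t() on write and read; round
# trips are bit-exact (datasets are written contiguous, uncompressed).

#' NSDF file metadata
#'
#' The attribute set required at file level: units, start time and time
#' step of the simulation, and provenance (software, method, creator,
#' license).
#'
#' @param software,method,creator,license free-text provenance.
#' @param title dataset title.
#' @return named list of attributes.
#' @export
nsdf_metadata <- function(software = paste0("lfpsim ",
                            as.character(utils::packageVersion("lfpsim"))),
                          method = "synthetic stand-in activity generator",
                          creator = Sys.info()[["user"]],
                          license = "ODbL-1.0",
                          title = "synthetic thalamocortical column dataset") {
  list(title = title, nsdf_version = "1.0",
       tstart = 0, dt = 0.1, time_unit = "ms", length_unit = "um",
       current_unit = "nA", voltage_unit = "mV",
       software = software, method = method, creator = creator,
       license = license)
}

.h5_write_attr <- function(file, path, name, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, obj, name)
  invisible(NULL)
}

.required_file_attrs <- c("nsdf_version", "tstart", "dt", "time_unit",
                          "length_unit", "current_unit", "voltage_unit",
                          "software", "method", "creator", "license")

#' Write a dataset to an NSDF/HDF5 file
#'
#' @param path output file path.
#' @param segments segment table from [build_morphologies()]; rows must
#'   be grouped contiguously by population.
#' @param activity an `activity_traces` whose rows align with
#'   `segments`.
#' @param spikes a `spike_events` (cells may be silent: empty rows are
#'   written).
#' @param metadata attribute list from [nsdf_metadata()].
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_nsdf <- function(path, segments, activity, spikes,
                       metadata = nsdf_metadata(), overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite)
      stop("file exists: '", path, "' (use overwrite = TRUE)")
    unlink(path)
  }
  if (!is.null(activity) &&
      !identical(segments$segment_id, activity$segment_id))
    stop("segments and activity rows are not aligned")
  pops <- unique(segments$population)
  if (anyDuplicated(rle(segments$population)$values))
    stop("segments must be grouped contiguously by population")

  rhdf5::h5createFile(path)
  for (g in c("data", "data/static", "data/static/morphology",
              "data/uniform", "data/event", "map", "map/static",
              "map/uniform", "map/event"))
    rhdf5::h5createGroup(path, g)

  comp_labs <- if (!is.null(activity$components))
    names(activity$components) else character(0)
  spike_cells <- if (!is.null(spikes)) names(spikes) else character(0)
  vlen_jobs <- list()

  for (pop in pops) {
    rows <- which(segments$population == pop)
    morph <- segments[rows, c("x0", "y0", "z0", "x1", "y1", "z1",
                              "diameter")]
    names(morph)[7] <- "d"
    rownames(morph) <- NULL
    rhdf5::h5write(morph, path, paste0("data/static/morphology/", pop))
    rhdf5::h5write(segments$segment_id[rows], path,
                   paste0("map/static/", pop, "_names"))
    if (!is.null(activity)) {
      rhdf5::h5createGroup(path, paste0("data/uniform/", pop))
      rhdf5::h5write(t(activity$i_total[rows, , drop = FALSE]), path,
                     paste0("data/uniform/", pop, "/i"))
      rhdf5::h5write(t(activity$v[rows, , drop = FALSE]), path,
                     paste0("data/uniform/", pop, "/v"))
      for (l in comp_labs)
        rhdf5::h5write(t(activity$components[[l]][rows, , drop = FALSE]),
                       path, paste0("data/uniform/", pop, "/", l))
      rhdf5::h5write(segments$segment_id[rows], path,
                     paste0("map/uniform/", pop, "_names"))
    }
    cells <- unique(segments$cell_id[rows])
    if (length(spike_cells)) {
      have <- intersect(cells, spike_cells)
      rhdf5::h5createGroup(path, paste0("data/event/", pop))
      rhdf5::h5write(have, path, paste0("map/event/", pop, "_spikes"))
      vlen_jobs[[pop]] <- list(
        path = paste0("/data/event/", pop, "/spikes"),
        data = lapply(unname(spikes[have]), as.double))
    }
  }
  rhdf5::h5closeAll()

  # variable-length spike rows (one per cell) via the C bridge
  for (job in vlen_jobs)
    .Call(C_h5vl_write, path, job$path, job$data)

  # input-spike event lists (replay protocols)
  isp <- if (!is.null(spikes)) attr(spikes, "input_spikes") else NULL
  if (!is.null(isp)) {
    rhdf5::h5createGroup(path, "data/event/input")
    rhdf5::h5write(names(isp), path, "map/event/input_spikes")
    rhdf5::h5closeAll()
    .Call(C_h5vl_write, path, "/data/event/input/spikes",
          lapply(unname(isp), as.double))
    .Call(C_h5ds_attach, path, "/data/event/input/spikes",
          "/map/event/input_spikes", 0L)
    .h5_write_attr(path, "data/event/input/spikes", "unit", "ms")
  }

  # file-level attributes
  meta <- metadata
  if (length(pops)) meta$population_order <- pops
  if (length(comp_labs)) meta$component_arrays <- comp_labs
  for (nm in names(meta))
    .h5_write_attr(path, "/", nm, meta[[nm]])

  # unit attributes and Dimension Scales links
  for (pop in pops) {
    mpath <- paste0("data/static/morphology/", pop)
    .h5_write_attr(path, mpath, "unit", "um")
    .Call(C_h5ds_attach, path, paste0("/", mpath),
          paste0("/map/static/", pop, "_names"), 0L)
    if (!is.null(activity)) {
      for (ds in c("i", "v", comp_labs)) {
        dpath <- paste0("data/uniform/", pop, "/", ds)
        .h5_write_attr(path, dpath, "unit", if (ds == "v") "mV" else "nA")
        .h5_write_attr(path, dpath, "dt", activity$dt)
        .h5_write_attr(path, dpath, "tstart", activity$time_start)
        .h5_write_attr(path, dpath, "tunit", "ms")
        .Call(C_h5ds_attach, path, paste0("/", dpath),
              paste0("/map/uniform/", pop, "_names"), 0L)
      }
    }
    if (!is.null(vlen_jobs[[pop]])) {
      spath <- paste0("data/event/", pop, "/spikes")
      .h5_write_attr(path, spath, "unit", "ms")
      .Call(C_h5ds_attach, path, paste0("/", spath),
            paste0("/map/event/", pop, "_spikes"), 0L)
    }
  }
  invisible(path)
}

.known_nsdf_paths <- function(ls_tab) {
  full <- sub("^/", "", paste0(ls_tab$group,
                               ifelse(ls_tab$group == "/", "", "/"),
                               ls_tab$name))
  known <- grepl(paste0("^(data|map)$|",
                        "^data/(static|uniform|event)$|",
                        "^data/static/morphology(/[^/]+)?$|",
                        "^data/uniform/[^/]+(/[^/]+)?$|",
                        "^data/event/[^/]+(/(spikes|input_spikes))?$|",
                        "^map/(static|uniform|event)(/[^/]+)?$"), full)
  list(full = full, unknown = full[!known])
}

#' Read an NSDF file written by [write_nsdf()]
#'
#' Tolerant reader: unknown extra groups do not fail the read; they are
#' returned in `$unknown_paths` and reported as a message.
#'
#' @param path NSDF file path.
#' @return list with `segments`, `activity`, `spikes`, `metadata`,
#'   `unknown_paths`. A write/read round trip is the identity: float
#'   arrays bit-exact, id lists order-preserving.
#' @export
read_nsdf <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  meta <- rhdf5::h5readAttributes(path, "/")
  ls_tab <- rhdf5::h5ls(path)
  paths <- .known_nsdf_paths(ls_tab)
  if (length(paths$unknown))
    message("ignoring unknown paths: ",
            paste(paths$unknown, collapse = ", "))
  pops <- as.character(meta$population_order)
  if (!length(pops))
    pops <- ls_tab$name[ls_tab$group == "/data/static/morphology"]

  seg_list <- list(); i_list <- list(); v_list <- list()
  comp_labs <- as.character(meta$component_arrays)
  comp_list <- stats::setNames(
    replicate(length(comp_labs), list(), simplify = FALSE), comp_labs)
  spikes <- list()
  for (pop in pops) {
    morph <- rhdf5::h5read(path, paste0("data/static/morphology/", pop))
    ids <- as.character(rhdf5::h5read(path,
                                      paste0("map/static/", pop, "_names")))
    names(morph)[names(morph) == "d"] <- "diameter"
    morph[] <- lapply(morph, as.vector)  # drop h5read's 1-d dims
    seg_list[[pop]] <- data.frame(
      segment_id = ids, cell_id = sub("/.*$", "", ids), population = pop,
      morph[c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")],
      stringsAsFactors = FALSE)
    ip <- paste0("data/uniform/", pop, "/i")
    if (ip %in% paths$full == FALSE)
      ip <- NULL
    if (!is.null(ip)) {
      i_list[[pop]] <- t(rhdf5::h5read(path, ip))
      v_list[[pop]] <- t(rhdf5::h5read(path,
                                       paste0("data/uniform/", pop, "/v")))
      for (l in comp_labs)
        comp_list[[l]][[pop]] <-
          t(rhdf5::h5read(path, paste0("data/uniform/", pop, "/", l)))
    }
    sp <- paste0("/data/event/", pop, "/spikes")
    if (paste0("data/event/", pop, "/spikes") %in% paths$full) {
      cells <- as.character(rhdf5::h5read(path,
                              paste0("map/event/", pop, "_spikes")))
      rhdf5::h5closeAll()
      spikes[c(cells)] <- .Call(C_h5vl_read, path, sp)
    }
  }
  rhdf5::h5closeAll()
  segments <- do.call(rbind, unname(seg_list))
  rownames(segments) <- NULL
  activity <- NULL
  if (length(i_list)) {
    i_total <- do.call(rbind, unname(i_list))
    activity <- structure(list(
      time_start = as.numeric(meta$tstart), dt = as.numeric(meta$dt),
      n_samples = ncol(i_total), i_total = i_total,
      v = do.call(rbind, unname(v_list)),
      components = if (length(comp_labs))
        lapply(comp_list, function(x) do.call(rbind, unname(x))) else NULL,
      segment_id = segments$segment_id, cell_id = segments$cell_id,
      population = segments$population), class = "activity_traces")
  }
  sp_obj <- structure(spikes, stop = as.numeric(meta$tstart) +
                        (if (!is.null(activity))
                           activity$n_samples * activity$dt else NA_real_),
                      class = "spike_events")
  if ("data/event/input/spikes" %in% paths$full) {
    nms <- as.character(rhdf5::h5read(path, "map/event/input_spikes"))
    rhdf5::h5closeAll()
    attr(sp_obj, "input_spikes") <-
      stats::setNames(.Call(C_h5vl_read, path, "/data/event/input/spikes"),
                      nms)
  }
  list(segments = segments, activity = activity, spikes = sp_obj,
       metadata = meta, unknown_paths = paths$unknown)
}

.check <- function(rule, where, ok, detail = "") {
  data.frame(rule = rule, path = where,
             status = ifelse(ok, "pass", "fail"), detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate an NSDF file
#'
#' Checks, per rule: required file attributes; required per-population
#' paths; Dimension Scales linkage between data and map arrays; unit
#' attributes; row-count consistency between data arrays and their map
#' arrays; per-cell Kirchhoff residual of the total current; and a
#' monotone uniform time base.
#'
#' @param path NSDF file path.
#' @param kirchhoff_tol maximum allowed per-cell current sum, relative
#'   to the cell's current scale.
#' @return object of class `nsdf_validation`: a check table plus an
#'   overall `ok` flag.
#' @export
validate_nsdf <- function(path, kirchhoff_tol = 1e-9) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  meta <- rhdf5::h5readAttributes(path, "/")
  ls_tab <- rhdf5::h5ls(path)
  full <- .known_nsdf_paths(ls_tab)$full
  checks <- list()
  add <- function(x) checks[[length(checks) + 1L]] <<- x

  miss <- setdiff(.required_file_attrs, names(meta))
  add(.check("file attributes", "/", length(miss) == 0,
             if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
             else ""))
  dt <- suppressWarnings(as.numeric(meta$dt))
  add(.check("monotone time base", "/",
             length(dt) == 1 && !is.na(dt) && dt > 0,
             sprintf("dt = %s", paste(meta$dt, collapse = ","))))

  pops <- as.character(meta$population_order)
  if (!length(pops))
    pops <- ls_tab$name[ls_tab$group == "/data/static/morphology"]
  rhdf5::h5closeAll()

  for (pop in pops) {
    mpath <- paste0("data/static/morphology/", pop)
    mnames <- paste0("map/static/", pop, "_names")
    ipath <- paste0("data/uniform/", pop, "/i")
    vpath <- paste0("data/uniform/", pop, "/v")
    unames <- paste0("map/uniform/", pop, "_names")
    need <- c(mpath, mnames, ipath, vpath, unames)
    present <- need %in% full
    add(.check("required paths", pop, all(present),
               if (!all(present))
                 paste("missing:", paste(need[!present], collapse = ", "))
               else ""))
    if (!all(present)) next

    ids <- as.character(rhdf5::h5read(path, mnames))
    uids <- as.character(rhdf5::h5read(path, unames))
    morph <- rhdf5::h5read(path, mpath)
    im <- rhdf5::h5read(path, ipath)        # samples x segments in R
    S <- ncol(im)
    add(.check("row counts", pop,
               length(morph$x0) == length(ids) && S == length(uids),
               sprintf("morphology %d vs names %d; i rows %d vs names %d",
                       length(morph$x0), length(ids), S, length(uids))))

    # DIMENSION_LIST is a vlen-of-references attribute rhdf5 cannot
    # decode; it is checked via the H5DS API below, so silence the
    # reader here
    iattr <- suppressWarnings(rhdf5::h5readAttributes(path, ipath))
    vattr <- suppressWarnings(rhdf5::h5readAttributes(path, vpath))
    add(.check("unit attributes", pop,
               identical(as.character(iattr$unit), "nA") &&
                 identical(as.character(vattr$unit), "mV"),
               sprintf("i unit '%s', v unit '%s'",
                       paste(iattr$unit, collapse = ","),
                       paste(vattr$unit, collapse = ","))))
    rhdf5::h5closeAll()

    ds_ok <- .Call(C_h5ds_is_scale, path, paste0("/", mnames)) == 1L &&
      .Call(C_h5ds_is_attached, path, paste0("/", mpath),
            paste0("/", mnames), 0L) == 1L &&
      .Call(C_h5ds_is_attached, path, paste0("/", ipath),
            paste0("/", unames), 0L) == 1L &&
      .Call(C_h5ds_is_attached, path, paste0("/", vpath),
            paste0("/", unames), 0L) == 1L
    add(.check("dimension scales", pop, ds_ok,
               if (!ds_ok) "data array not linked to its map array" else ""))

    if (S == length(uids) && S > 0) {
      cell_of <- sub("/.*$", "", uids)
      worst <- 0; worst_cell <- ""
      for (cell in unique(cell_of)) {
        cols <- which(cell_of == cell)
        resid <- max(abs(rowSums(im[, cols, drop = FALSE])))
        scale <- max(abs(im[, cols]), 1e-12)
        if (resid / scale > worst) {
          worst <- resid / scale; worst_cell <- cell
        }
      }
      add(.check("kirchhoff residual", pop, worst <= kirchhoff_tol,
                 sprintf("max relative residual %.3g (cell %s)",
                         worst, worst_cell)))
    }

    comp_labs <- as.character(meta$component_arrays)
    comp_here <- comp_labs[paste0("data/uniform/", pop, "/",
                                  comp_labs) %in% full]
    if (length(comp_here)) {
      tot <- 0
      conformable <- TRUE
      for (l in comp_here) {
        cl <- rhdf5::h5read(path, paste0("data/uniform/", pop, "/", l))
        if (!identical(dim(cl), dim(im))) { conformable <- FALSE; break }
        tot <- tot + cl
      }
      if (conformable) {
        err <- max(abs(tot - im)) / max(abs(im), 1e-12)
        add(.check("component closure", pop, err <= 1e-9,
                   sprintf("max relative error %.3g", err)))
      } else {
        add(.check("component closure", pop, FALSE,
                   "component dimensions do not match /i"))
      }
      rhdf5::h5closeAll()
    }
  }
  tab <- do.call(rbind, checks)
  structure(list(checks = tab, ok = all(tab$status == "pass"),
                 n_violations = sum(tab$status == "fail"), path = path),
            class = "nsdf_validation")
}

# detach a Dimension Scale link (internal; used to construct broken
# files when exercising the validator)
h5ds_detach <- function(path, data_path, scale_path, idx = 0L) {
  .Call(C_h5ds_detach, path, data_path, scale_path, as.integer(idx))
}

#' @export
print.nsdf_validation <- function(x, ...) {
  cat(sprintf("<nsdf_validation> %s: %d checks, %d violation(s)\n",
              x$path, nrow(x$checks), x$n_violations))
  bad <- x$checks[x$checks$status == "fail", ]
  if (nrow(bad))
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  FAIL %s [%s]: %s\n", bad$rule[i], bad$path[i],
                  bad$detail[i]))
  invisible(x)
}
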