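#' @importFrom stats runif rpois
#' @importFrom utils head tail
NULL

# Full-model population table: 14 populations, one row each, with section
# counts per cell, full-model cell counts and soma depth ranges (um).
# The TCR row is read as 139 sections / 100 cells.
.population_table <- function() {
  data.frame(
    name = c("pyramidal regular spiking L2/3",
             "pyramidal fast rhythmic bursting L2/3",
             "superficial basket interneuron",
             "superficial axoaxonic interneuron",
             "superficial low-threshold spiking interneuron",
             "spiny stellate L4",
             "pyramidal tufted intrinsic bursting L5",
             "pyramidal tufted regular spiking L5",
             "deep basket interneuron",
             "deep axoaxonic interneuron",
             "deep low-threshold spiking interneuron",
             "pyramidal nontufted regular spiking L6",
             "thalamocortical relay",
             "nucleus reticularis"),
    abbreviation = c("pyrRS23", "pyrFRB23", "bask23", "axax23", "LTS23",
                     "spinstel4", "tuftIB5", "tuftRS5", "bask56", "axax56",
                     "LTS56", "nontuftRS6", "TCR", "nRT"),
    layer = c("L23", "L23", "L23", "L23", "L23", "L4", "L5", "L5",
              "L56", "L56", "L56", "L6", "thalamus", "thalamus"),
    cell_class = c("excitatory", "excitatory", "inhibitory", "inhibitory",
                   "inhibitory", "excitatory", "excitatory", "excitatory",
                   "inhibitory", "inhibitory", "inhibitory", "excitatory",
                   "excitatory", "inhibitory"),
    sections_per_cell = c(74L, 74L, 59L, 59L, 59L, 59L, 61L, 61L, 59L,
                          59L, 59L, 50L, 139L, 59L),
    n_cells = c(1000L, 50L, 90L, 90L, 90L, 240L, 800L, 200L, 100L, 100L,
                100L, 500L, 100L, 100L),
    depth_min = c(0, 0, 0, 0, 0, 400, 700, 700, 700, 700, 700, 1200,
                  4900, 4900),
    depth_max = c(400, 400, 400, 400, 400, 700, 1200, 1200, 1700, 1700,
                  1700, 1700, 5200, 5200),
    is_cortical = c(rep(TRUE, 12), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

.round_half_up <- function(x) floor(x + 0.5)

#' Build the population registry, optionally scaled down
#'
#' Returns the 14-population registry of the thalamocortical column
#' model. The full model has 3560 cells; `size_fraction = 0.1` gives the
#' down-scaled 356-cell model used by the channel-decomposition
#' protocols. Scaled cell counts are rounded half up with a minimum of
#' one cell per population.
#'
#' @param size_fraction fraction of the full per-population cell counts
#'   to keep, in (0, 1].
#' @return A `data.frame` with one row per population: `name`,
#'   `abbreviation`, `layer`, `cell_class`, `sections_per_cell`,
#'   `n_cells`, `soma_depth_min`, `soma_depth_max` (um), `is_cortical`.
#' @examples
#' sum(build_registry(1)$n_cells)    # 3560
#' sum(build_registry(0.1)$n_cells)  # 356
#' @export
build_registry <- function(size_fraction = 1) {
  if (!is.numeric(size_fraction) || length(size_fraction) != 1 ||
      is.na(size_fraction) || size_fraction <= 0 || size_fraction > 1)
    stop("'size_fraction' must be a single number in (0, 1]")
  tab <- .population_table()
  tab$n_cells <- pmax(1L, as.integer(.round_half_up(tab$n_cells *
                                                    size_fraction)))
  names(tab)[names(tab) == "depth_min"] <- "soma_depth_min"
  names(tab)[names(tab) == "depth_max"] <- "soma_depth_max"
  attr(tab, "size_fraction") <- size_fraction
  class(tab) <- c("population_registry", "data.frame")
  tab
}

#' Column geometry: population registry plus cylinder dimensions
#'
#' @param column_radius radius (um) of the cylinder in which somas are
#'   placed; the model uses a 400 um diameter column, hence 200.
#' @param populations a registry from [build_registry()].
#' @return An object of class `column_geometry`.
#' @export
column_geometry <- function(column_radius = 200,
                            populations = build_registry(1)) {
  stopifnot(is.numeric(column_radius), length(column_radius) == 1,
            column_radius > 0)
  structure(list(column_radius = column_radius,
                 populations = populations,
                 axis = "z depth, pia at 0, increasing downward; axis x=0,y=0"),
            class = "column_geometry")
}

#' @export
print.column_geometry <- function(x, ...) {
  cat("<column_geometry> radius", x$column_radius, "um,",
      nrow(x$populations), "populations,",
      sum(x$populations$n_cells), "cells\n")
  invisible(x)
}

#' Place cell somas uniformly in the column cylinder
#'
#' Soma (x, y) positions are uniform per unit area over the disk of the
#' column radius (radius drawn as R*sqrt(u)), and z is uniform over each
#' population's soma depth range. Deterministic for a given seed.
#'
#' @param geometry a [column_geometry()].
#' @param seed integer RNG seed.
#' @return `data.frame` with columns `cell_id`, `population`, `x`, `y`,
#'   `z` (um).
#' @export
place_somas <- function(geometry, seed) {
  stopifnot(inherits(geometry, "column_geometry"))
  reg <- geometry$populations
  R <- geometry$column_radius
  out <- vector("list", nrow(reg))
  with_seed(seed, {
    for (i in seq_len(nrow(reg))) {
      n <- reg$n_cells[i]
      if (n == 0L) {
        out[[i]] <- data.frame(cell_id = character(0),
                               population = character(0),
                               x = numeric(0), y = numeric(0),
                               z = numeric(0), stringsAsFactors = FALSE)
        next
      }
      r <- R * sqrt(runif(n))
      th <- 2 * pi * runif(n)
      z <- runif(n, reg$soma_depth_min[i], reg$soma_depth_max[i])
      out[[i]] <- data.frame(
        cell_id = sprintf("%s_%04d", reg$abbreviation[i], seq_len(n)),
        population = reg$abbreviation[i],
        x = r * cos(th), y = r * sin(th), z = z,
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# Populations that get a vertical soma-apical/basal stick; the rest get
# compact radial stand-in dendrites.
.pyramidal_pops <- c("pyrRS23", "pyrFRB23", "tuftIB5", "tuftRS5",
                     "nontuftRS6")

#' Build stand-in segment geometries for every cell
#'
#' One segment per section (as in the source model's discretization).
#' Pyramidal cells get a vertical stick: a soma segment, an apical chain
#' spanning toward the pia and a short basal chain below the soma.
#' Interneurons, spiny stellate and thalamic cells get a soma segment
#' plus compact radial dendritic segments. These are stereotyped
#' morphologies whose contracts are segment count, soma position and
#' layer-consistent vertical extent - not the source model's shapes.
#'
#' @param geometry a [column_geometry()].
#' @param soma_positions output of [place_somas()].
#' @param seed integer RNG seed (orients the radial dendrites).
#' @return `data.frame` with columns `segment_id`
#'   (`"<cellname>/<section>"`), `cell_id`, `population`, `x0 y0 z0`
#'   (proximal, um), `x1 y1 z1` (distal, um) and `diameter` (um). The
#'   point source sits at the segment midpoint.
#' @export
build_morphologies <- function(geometry, soma_positions, seed) {
  stopifnot(inherits(geometry, "column_geometry"))
  reg <- geometry$populations
  secs <- stats::setNames(reg$sections_per_cell, reg$abbreviation)
  n_cells <- nrow(soma_positions)
  pieces <- vector("list", n_cells)
  with_seed(seed, {
    for (k in seq_len(n_cells)) {
      pop <- soma_positions$population[k]
      S <- secs[[pop]]
      cx <- soma_positions$x[k]; cy <- soma_positions$y[k]
      cz <- soma_positions$z[k]
      cell <- soma_positions$cell_id[k]
      if (pop %in% .pyramidal_pops) {
        nd <- S - 1L
        n_api <- max(1L, as.integer(ceiling(nd * 2 / 3)))
        n_bas <- nd - n_api
        # apical stick rises toward the pia, stopping at 10% of soma depth
        ext <- max(50, 0.85 * (cz - 10))
        la <- ext / n_api
        api_z0 <- (cz - 10) - (seq_len(n_api) - 1) * la
        seg <- data.frame(
          section = c("soma", sprintf("apical_%d", seq_len(n_api)),
                      if (n_bas > 0) sprintf("basal_%d", seq_len(n_bas))),
          x0 = cx, y0 = cy,
          z0 = c(cz + 10, api_z0,
                 if (n_bas > 0) (cz + 10) + (seq_len(n_bas) - 1) * (150 / n_bas)),
          x1 = cx, y1 = cy,
          z1 = c(cz - 10, api_z0 - la,
                 if (n_bas > 0) (cz + 10) + seq_len(n_bas) * (150 / n_bas)),
          diameter = c(15, rep(2.5, n_api), rep(2, max(0L, n_bas))),
          stringsAsFactors = FALSE)
      } else {
        nd <- S - 1L
        len <- runif(nd, 40, 80)
        az <- runif(nd, 0, 2 * pi)
        cosel <- runif(nd, -1, 1)
        sinel <- sqrt(pmax(0, 1 - cosel^2))
        seg <- data.frame(
          section = c("soma", sprintf("dend_%d", seq_len(nd))),
          x0 = c(cx, rep(cx, nd)), y0 = c(cy, rep(cy, nd)),
          z0 = c(cz + 10, rep(cz, nd)),
          x1 = c(cx, cx + len * sinel * cos(az)),
          y1 = c(cy, cy + len * sinel * sin(az)),
          z1 = c(cz - 10, cz + len * cosel),
          diameter = c(15, rep(1.5, nd)),
          stringsAsFactors = FALSE)
      }
      seg <- data.frame(
        segment_id = paste0(cell, "/", seg$section),
        cell_id = cell, population = pop,
        seg[c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")],
        stringsAsFactors = FALSE)
      pieces[[k]] <- seg
    }
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Segment midpoints (the point-source positions)
#'
#' @param segments a segment table from [build_morphologies()].
#' @return numeric matrix with columns x, y, z (um).
#' @export
segment_midpoints <- function(segments) {
  cbind(x = (segments$x0 + segments$x1) / 2,
        y = (segments$y0 + segments$y1) / 2,
        z = (segments$z0 + segments$z1) / 2)
}

#' Dump / load the population registry as JSON
#'
#' Flat JSON mirroring the registry columns, for interoperability with
#' non-R tooling.
#'
#' @param registry a registry from [build_registry()].
#' @param path file path.
#' @return `write_registry_json` returns `path` invisibly;
#'   `read_registry_json` returns the registry `data.frame`.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  tab <- jsonlite::fromJSON(path)
  tab$sections_per_cell <- as.integer(tab$sections_per_cell)
  tab$n_cells <- as.integer(tab$n_cells)
  class(tab) <- c("population_registry", "data.frame")
  tab
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
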