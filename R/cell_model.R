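#' 2-D cell / nucleus / extracellular-matrix geometry
#'
#' The simplified planar cell model: a circular cell with a concentric
#' circular nucleus centred in a square extracellular-matrix (ECM) region.
#' Defaults follow the LNCaP prostate-cancer-cell geometry used throughout
#' the package: 13.5 um cell, 8 um nucleus, 17.5 um ECM square.
#'
#' @param ecm_side side of the ECM square in um.
#' @param cell_diameter,nucleus_diameter diameters in um; the nucleus must fit
#'   inside the cell and the cell circle inside the ECM square.
#' @return Object of class \code{cell_geometry}; coordinates are measured
#'   from the ECM centre.
#' @export
cell_geometry <- function(ecm_side = 17.5, cell_diameter = 13.5,
                          nucleus_diameter = 8) {
  stopifnot(ecm_side > 0, cell_diameter > 0, nucleus_diameter > 0)
  if (nucleus_diameter >= cell_diameter)
    stop("nucleus must be smaller than the cell")
  if (cell_diameter > ecm_side)
    stop("cell circle must fit inside the ECM square")
  structure(list(ecm_side = ecm_side, cell_diameter = cell_diameter,
                 nucleus_diameter = nucleus_diameter, center = c(0, 0)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> ECM %g x %g um, cell %g um, nucleus %g um\n",
              x$ecm_side, x$ecm_side, x$cell_diameter, x$nucleus_diameter))
  invisible(x)
}

#' Mass of a single spherical nanoparticle
#'
#' @param np_diameter diameter in nm.
#' @param gold_density material density in g/cm^3 (bulk gold: 19.32).
#' @return Mass in picograms: (pi/6) d^3 rho.
#' @examples
#' np_mass(15, 19.32)  # ~3.414e-5 pg
#' @export
np_mass <- function(np_diameter = 15, gold_density = 19.32) {
  if (any(np_diameter <= 0) || any(gold_density <= 0))
    stop("np_diameter and gold_density must be > 0")
  d_cm <- np_diameter * 1e-7
  (pi / 6) * d_cm^3 * gold_density * 1e12   # g -> pg
}

#' Convert a nanoparticle load specification to a particle count
#'
#' Exactly one of \code{count}, \code{mass_per_cell} or
#' \code{weight_percent} must be given. A direct \code{count} passes through;
#' \code{mass_per_cell} (pg of gold per cell) is divided by the single-particle
#' mass; \code{weight_percent} is interpreted as the gold mass fraction of a
#' spherical cell of \code{cell_diameter} at \code{cell_density}. The 3-D
#' per-cell count is finally scaled by \code{slice_fraction} — the fraction of
#' the cell's particles attributed to the 2-D model plane — and rounded to the
#' nearest integer.
#'
#' @param count integer particle count (pass-through).
#' @param mass_per_cell gold mass per cell in pg.
#' @param weight_percent gold weight fraction of the cell in percent.
#' @param np_diameter nanoparticle diameter in nm.
#' @param gold_density,cell_density densities in g/cm^3.
#' @param geometry a \code{\link{cell_geometry}} (supplies the cell diameter).
#' @param slice_fraction fraction of the 3-D per-cell count assigned to the
#'   2-D plane (default 1).
#' @return Integer particle count; a warning is issued if rounding gives 0.
#' @examples
#' load_to_count(mass_per_cell = 10)          # ~292,901 particles
#' load_to_count(weight_percent = 0.1)        # ~37,733 particles
#' @export
load_to_count <- function(count = NULL, mass_per_cell = NULL,
                          weight_percent = NULL, np_diameter = 15,
                          gold_density = 19.32, cell_density = 1.0,
                          geometry = cell_geometry(), slice_fraction = 1.0) {
  given <- !c(is.null(count), is.null(mass_per_cell), is.null(weight_percent))
  if (sum(given) != 1L)
    stop("specify exactly one of count, mass_per_cell, weight_percent")
  stopifnot(slice_fraction > 0, slice_fraction <= 1)
  if (!is.null(count)) {
    stopifnot(count > 0)
    return(as.integer(round(count)))
  }
  m1 <- np_mass(np_diameter, gold_density)
  if (!is.null(mass_per_cell)) {
    stopifnot(mass_per_cell > 0)
    n <- mass_per_cell / m1
  } else {
    stopifnot(weight_percent > 0)
    d_cm <- geometry$cell_diameter * 1e-4
    cell_mass_pg <- (pi / 6) * d_cm^3 * cell_density * 1e12
    n <- (weight_percent / 100) * cell_mass_pg / m1
  }
  n <- as.integer(round(n * slice_fraction))
  if (n == 0L) warning("sub-single-particle load: count rounded to 0")
  n
}

#' Place nanoparticles in the 2-D cell model
#'
#' Two biodistributions are supported. \code{"homogeneous"}: positions i.i.d.
#' uniform over the whole ECM square (nucleus included), the naive model of a
#' well-mixed suspension. \code{"cytoplasm"}: positions i.i.d. uniform *by
#' area* over the annulus between the nucleus and the cell membrane, the
#' distribution observed for receptor-internalized nanoparticles that do not
#' enter the nucleus. Annulus sampling uses the inverse CDF in r^2 with a
#' uniform angle, which is exact. Nanoparticles are treated as points; the
#' same seed always reproduces the same positions.
#'
#' @param geometry a \code{\link{cell_geometry}}.
#' @param count number of particles (>= 0).
#' @param mode \code{"homogeneous"} or \code{"cytoplasm"}.
#' @param seed integer seed.
#' @return Object of class \code{np_placement}: \code{positions} (count x 2
#'   matrix of x, y in um from the ECM centre), \code{mode}, \code{seed},
#'   \code{geometry}.
#' @export
place_nps <- function(geometry, count, mode = c("homogeneous", "cytoplasm"),
                      seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "cell_geometry"), count >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (count == 0) {
    pos <- matrix(numeric(0), ncol = 2)
  } else if (mode == "homogeneous") {
    h <- geometry$ecm_side / 2
    pos <- cbind(stats::runif(count, -h, h), stats::runif(count, -h, h))
  } else {
    rn <- geometry$nucleus_diameter / 2
    rc <- geometry$cell_diameter / 2
    r <- sqrt(stats::runif(count, rn^2, rc^2))
    th <- stats::runif(count, 0, 2 * pi)
    pos <- cbind(r * cos(th), r * sin(th))
  }
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, mode = mode, seed = seed,
                 geometry = geometry),
            class = "np_placement")
}

#' @export
print.np_placement <- function(x, ...) {
  cat(sprintf("<np_placement> %d nanoparticles, mode '%s', seed %d\n",
              nrow(x$positions), x$mode, x$seed))
  invisible(x)
}
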