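#' Spherical shell scoring grid around a nanoparticle
#'
#' Builds the contiguous radial scoring grid used to tabulate dose around a
#' single nanoparticle: \code{n_fine} thin shells of width \code{w_fine}
#' followed by \code{n_coarse} shells of width \code{w_coarse}. Radii are
#' measured in nanometres from the nanoparticle *surface* (the first shell
#' starts at r = 0); the particle's own radius is not part of the grid.
#'
#' The default scheme used throughout the package is 200 shells of 1 nm
#' followed by 200 shells of 50 nm, covering ~10 um — the range over which
#' secondary electrons from a nanoparticle deposit appreciable dose under a
#' megavoltage beam.
#'
#' @param n_fine,n_coarse number of fine / coarse shells (non-negative).
#' @param w_fine,w_coarse shell widths in nm (positive).
#' @return An object of class \code{shell_grid} with numeric vectors
#'   \code{inner} and \code{outer} (nm per shell).
#' @examples
#' g <- shell_grid(200, 1, 200, 50)
#' max(g$outer)  # 10200 nm ~ 10 um
#' @export
shell_grid <- function(n_fine = 200, w_fine = 1, n_coarse = 200, w_coarse = 50) {
  stopifnot(n_fine >= 0, n_coarse >= 0, w_fine > 0, w_coarse > 0)
  if (n_fine + n_coarse < 1) stop("empty grid")
  widths <- c(rep(w_fine, n_fine), rep(w_coarse, n_coarse))
  outer <- cumsum(widths)
  structure(list(inner = c(0, outer[-length(outer)]), outer = outer),
            class = "shell_grid")
}

#' @export
print.shell_grid <- function(x, ...) {
  cat(sprintf("<shell_grid> %d shells, 0 .. %g nm (from nanoparticle surface)\n",
              length(x$outer), max(x$outer)))
  invisible(x)
}

shell_midpoints <- function(grid) (grid$inner + grid$outer) / 2

grids_identical <- function(a, b) {
  length(a$outer) == length(b$outer) &&
    isTRUE(all.equal(a$inner, b$inner)) && isTRUE(all.equal(a$outer, b$outer))
}

#' Radial dose profile scored around a nanoparticle
#'
#' Container for the per-shell dose (Gy, on the simulation batch scale)
#' deposited in water around a single gold nanoparticle (AuNP) or matched
#' water nanoparticle (WNP).
#'
#' @param grid a \code{\link{shell_grid}}.
#' @param dose numeric vector of per-shell doses in Gy, one per shell, >= 0.
#' @param source_label \code{"AuNP"} or \code{"WNP"}.
#' @param n_histories number of source histories that produced the profile.
#' @return Object of class \code{radial_dose_profile}.
#' @export
radial_dose_profile <- function(grid, dose, source_label = c("AuNP", "WNP"),
                                n_histories = 1) {
  source_label <- match.arg(source_label)
  stopifnot(inherits(grid, "shell_grid"), n_histories > 0)
  if (length(dose) != length(grid$outer))
    stop("dose length must equal shell count")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose values must be finite and >= 0")
  structure(list(grid = grid, dose = as.numeric(dose),
                 source_label = source_label, n_histories = n_histories),
            class = "radial_dose_profile")
}

#' Phase-space normalization factors
#'
#' The radial dose tables around the AuNP and WNP come from chained
#' simulations in which each stage resamples the previous stage's phase space.
#' Two bookkeeping ratios put both tables on a common per-incident-fluence
#' scale: \code{f1} (samples drawn from the macroscopic phase space divided by
#' the particles it contains, depth dependent) and \code{f2} (secondary
#' particles scored at the nanoparticle surface divided by the samples drawn
#' from them, one value per nanoparticle material). The background dose
#' \code{d_bg} is the dose the primary beam itself deposits in the
#' nanoparticle volume; it anchors the enhancement ratio far from the
#' particle at 1.
#'
#' @param n_phsp2_samples,n_phsp2 samples drawn from / particles contained in
#'   the macroscopic phase space (f1 = samples / contained).
#' @param n_phsp3_aunp,n_phsp3_wnp secondary particles scored at the AuNP /
#'   WNP surface.
#' @param n_phsp3_samples samples drawn from the secondary phase space
#'   (f2 = scored / samples).
#' @param d_bg background dose in Gy (>= 0; a value of 0 degenerates the
#'   enhancement ratio and triggers a warning).
#' @return Object of class \code{norm_factors} with fields \code{f1},
#'   \code{f2_aunp}, \code{f2_wnp}, \code{d_bg}.
#' @examples
#' nf <- norm_factors(1e9, 1.485e6, 110674, 110674, 5e5, d_bg = 1)
#' nf$f1        # ~673.4
#' nf$f2_aunp   # ~0.2213
#' @export
norm_factors <- function(n_phsp2_samples, n_phsp2, n_phsp3_aunp,
                         n_phsp3_wnp = n_phsp3_aunp, n_phsp3_samples,
                         d_bg) {
  counts <- c(n_phsp2_samples, n_phsp2, n_phsp3_aunp, n_phsp3_wnp,
              n_phsp3_samples)
  if (any(counts <= 0)) stop("all particle counts must be > 0")
  if (d_bg < 0) stop("d_bg must be >= 0")
  if (d_bg == 0)
    warning("d_bg = 0: dose enhancement ratio degenerates to a pure dose ratio")
  structure(list(f1 = n_phsp2_samples / n_phsp2,
                 f2_aunp = n_phsp3_aunp / n_phsp3_samples,
                 f2_wnp = n_phsp3_wnp / n_phsp3_samples,
                 d_bg = d_bg),
            class = "norm_factors")
}

#' Radial dose-enhancement-ratio kernel
#'
#' A \code{der_profile} is the dose point kernel applied around each
#' nanoparticle: the ratio of local dose with a gold nanoparticle present to
#' the dose with a water nanoparticle, as a function of radial distance from
#' the particle surface. Beyond \code{support_max} the ratio is defined to be
#' exactly 1 (no enhancement).
#'
#' @param radii shell midpoint radii in nm.
#' @param der dimensionless enhancement per shell (> 0, finite).
#' @param support_max radius (nm) beyond which DER is 1.
#' @param edges optional shell edge vector (length \code{length(radii) + 1})
#'   enabling exact piecewise-constant lookup on the original shells.
#' @return Object of class \code{der_profile}.
#' @export
der_profile <- function(radii, der, support_max = max(radii), edges = NULL) {
  stopifnot(length(radii) == length(der))
  if (any(!is.finite(der)) || any(der <= 0))
    stop("der values must be finite and > 0")
  if (!is.null(edges) && length(edges) != length(radii) + 1L)
    stop("edges must have length(radii) + 1 entries")
  structure(list(radii = as.numeric(radii), der = as.numeric(der),
                 support_max = support_max, edges = edges),
            class = "der_profile")
}

#' @export
print.der_profile <- function(x, ...) {
  cat(sprintf("<der_profile> %d shells, max DER %.3g, support %g nm\n",
              length(x$der), max(x$der), x$support_max))
  invisible(x)
}

#' Compute the DER kernel from paired radial dose tables
#'
#' Forms, shell by shell,
#' \deqn{DER(r) = \frac{D_{AuNP}(r) f_1 f_{2,AuNP} + D_{bg}}
#'                     {D_{WNP}(r) f_1 f_{2,WNP} + D_{bg}}}
#' from the AuNP and WNP radial dose profiles and the phase-space
#' normalization factors. Both profiles must share an identical shell grid.
#'
#' @param d_au,d_w \code{\link{radial_dose_profile}} objects for the AuNP and
#'   WNP sources (identical grids).
#' @param norm a \code{\link{norm_factors}} object.
#' @return A \code{\link{der_profile}} at the shell midpoints, with
#'   \code{support_max} equal to the outer grid radius.
#' @export
compute_der <- function(d_au, d_w, norm) {
  stopifnot(inherits(d_au, "radial_dose_profile"),
            inherits(d_w, "radial_dose_profile"),
            inherits(norm, "norm_factors"))
  if (!grids_identical(d_au$grid, d_w$grid))
    stop("mismatched shell grids between AuNP and WNP profiles")
  num <- d_au$dose * norm$f1 * norm$f2_aunp + norm$d_bg
  den <- d_w$dose * norm$f1 * norm$f2_wnp + norm$d_bg
  bad <- which(den == 0)
  if (length(bad))
    stop(sprintf("zero denominator in shell %d", bad[1]))
  grid <- d_au$grid
  der_profile(radii = shell_midpoints(grid), der = num / den,
              support_max = max(grid$outer),
              edges = c(grid$inner[1], grid$outer))
}

#' Evaluate a DER kernel at arbitrary radii
#'
#' Piecewise-constant lookup on the original shells (default) or linear
#' interpolation between shell midpoints. Radii inside the first shell clamp
#' to the first shell's value; radii beyond \code{support_max} return
#' exactly 1.
#'
#' @param profile a \code{\link{der_profile}}.
#' @param r_nm radii in nm (vectorised).
#' @param method \code{"constant"} (shell-averaged value of the containing
#'   shell) or \code{"linear"}.
#' @return Numeric vector of enhancement ratios.
#' @export
der_at <- function(profile, r_nm, method = c("constant", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "der_profile"))
  out <- rep(1, length(r_nm))
  inside <- r_nm <= profile$support_max
  r_in <- r_nm[inside]
  if (length(r_in)) {
    if (method == "constant") {
      if (!is.null(profile$edges)) {
        idx <- findInterval(r_in, profile$edges, rightmost.closed = TRUE)
        idx <- pmin(pmax(idx, 1L), length(profile$der))
      } else {
        idx <- findInterval(r_in, profile$radii) + 1L
        idx <- pmin(idx, length(profile$der))
      }
      out[inside] <- profile$der[idx]
    } else {
      out[inside] <- stats::approx(profile$radii, profile$der, xout = r_in,
                                   rule = 2)$y
    }
  }
  out
}

#' Weighted particle spectrum
#'
#' Phase-space-like particle records: type, energy, statistical weight and
#' direction cosine with respect to the beam axis.
#'
#' @param particle_type character vector, each \code{"photon"} or
#'   \code{"electron"}.
#' @param energy energies in MeV (> 0).
#' @param weight statistical weights (> 0), recycled.
#' @param cos_theta direction cosines in [-1, 1], recycled.
#' @return A data.frame of class \code{energy_spectrum}.
#' @export
energy_spectrum <- function(particle_type, energy, weight = 1, cos_theta = 1) {
  if (!all(particle_type %in% c("photon", "electron")))
    stop("particle_type must be 'photon' or 'electron'")
  if (any(energy <= 0)) stop("energies must be > 0")
  df <- data.frame(particle_type = particle_type, energy = energy,
                   weight = weight, cos_theta = cos_theta,
                   stringsAsFactors = FALSE)
  if (any(df$weight <= 0)) stop("weights must be > 0")
  if (any(abs(df$cos_theta) > 1)) stop("cos_theta must lie in [-1, 1]")
  class(df) <- c("energy_spectrum", "data.frame")
  df
}

#' Reweight a spectrum onto the beam axis
#'
#' Collapses oblique particle directions onto the beam axis while preserving
#' axial fluence: each forward-going record's weight is multiplied by
#' 1/cos(theta) and its direction set along the axis. Records with
#' cos(theta) <= 0 (backward or perpendicular) are dropped; the number dropped
#' is attached as attribute \code{"n_dropped"}.
#'
#' @param spectrum an \code{\link{energy_spectrum}}.
#' @return The reweighted spectrum (all \code{cos_theta} equal to 1).
#' @export
reweight_to_axis <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"), nrow(spectrum) > 0)
  keep <- spectrum$cos_theta > 0
  if (!any(keep)) stop("no forward-going particles")
  out <- spectrum[keep, , drop = FALSE]
  out$weight <- out$weight / out$cos_theta
  out$cos_theta <- 1
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

weighted_median <- function(x, w) {
  o <- order(x)                       # stable: ties keep record order
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)   # midpoint cumulative fractions
  stats::approx(p, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Summarise a particle spectrum
#'
#' Beam-quality summary statistics: weighted mean and median energy, the
#' percentage of total weight below 100 keV, the percentage of total weight
#' carried by electrons, and the record count. The weighted median linearly
#' interpolates between bracketing records (ties broken by a stable energy
#' sort), so it reduces to the ordinary median for equal weights.
#'
#' @param spectrum an \code{\link{energy_spectrum}} (non-empty).
#' @return A list with \code{e_mean}, \code{e_median} (MeV),
#'   \code{frac_below_100keV}, \code{electron_frac} (percent), \code{count}.
#' @export
spectrum_summary <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (nrow(spectrum) == 0) stop("empty spectrum")
  w <- spectrum$weight
  tot <- sum(w)
  list(e_mean = sum(w * spectrum$energy) / tot,
       e_median = weighted_median(spectrum$energy, w),
       frac_below_100keV = 100 * sum(w[spectrum$energy < 0.1]) / tot,
       electron_frac = 100 * sum(w[spectrum$particle_type == "electron"]) / tot,
       count = nrow(spectrum))
}

#' Beam hardening between two depths
#'
#' Percent increase in mean and median energy from a shallow to a deep
#' spectrum summary, the standard way to quantify how a megavoltage beam
#' hardens as low-energy photons are preferentially attenuated with depth.
#'
#' @param shallow,deep spectrum summaries (\code{\link{spectrum_summary}}
#'   output, or any list with \code{e_mean} and \code{e_median}).
#' @return List with \code{e_mean_increase_pct}, \code{e_median_increase_pct}.
#' @export
beam_hardening <- function(shallow, deep) {
  stopifnot(shallow$e_mean > 0, shallow$e_median > 0)
  list(e_mean_increase_pct = 100 * (deep$e_mean - shallow$e_mean) / shallow$e_mean,
       e_median_increase_pct = 100 * (deep$e_median - shallow$e_median) / shallow$e_median)
}

#' Relative photoelectric interaction probability
#'
#' The photoelectric cross-section scales approximately as (Z/E)^3, which is
#' why a high-Z material such as gold (Z = 79) enhances dose strongly for
#' low-energy photons but only weakly in the megavoltage regime. The returned
#' value is a relative (unnormalized) probability.
#'
#' @param z atomic number (> 0).
#' @param e photon energy (> 0, any fixed unit).
#' @return \code{(z / e)^3}.
#' @export
photoelectric_scaling <- function(z, e) {
  if (any(z <= 0) || any(e <= 0)) stop("z and e must be > 0")
  (z / e)^3
}
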