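#' Linear-quadratic parameters with optional threshold
#'
#' The local dose-response used by the local effect model. Below the
#' threshold dose \code{dt} survival is the ordinary linear-quadratic (LQ)
#' form \eqn{S_x(D) = \exp(-\alpha D - \beta D^2)}; above it the log-survival
#' continues with constant slope \eqn{S_{max} = \alpha + 2 \beta D_t}, the LQ
#' slope at the threshold. Leaving \code{dt} unset gives the pure LQ model
#' (equivalent to an infinite threshold).
#'
#' @param alpha Gy^-1, >= 0.
#' @param beta Gy^-2, >= 0.
#' @param dt threshold dose in Gy (> 0) or NULL for pure LQ.
#' @return Object of class \code{lq_parameters}.
#' @seealso \code{\link{lq_smax}}, \code{\link{local_log_survival}}
#' @export
lq_parameters <- function(alpha, beta, dt = NULL) {
  stopifnot(alpha >= 0, beta >= 0)
  if (alpha + beta <= 0) stop("alpha + beta must be > 0")
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0 when set")
  structure(list(alpha = alpha, beta = beta, dt = dt),
            class = "lq_parameters")
}

#' @export
print.lq_parameters <- function(x, ...) {
  cat(sprintf("<lq_parameters> alpha = %.4g /Gy, beta = %.4g /Gy^2", x$alpha, x$beta))
  if (!is.null(x$dt))
    cat(sprintf(", Dt = %.4g Gy (Smax = %.4g /Gy)", x$dt, lq_smax(x)))
  cat("\n")
  invisible(x)
}

#' Slope of the threshold log-survival tail
#'
#' \code{Smax = alpha + 2 beta Dt}, always derived from the current
#' parameters (never stored).
#'
#' @param lq an \code{\link{lq_parameters}} object with \code{dt} set.
#' @return Smax in Gy^-1.
#' @export
lq_smax <- function(lq) {
  stopifnot(inherits(lq, "lq_parameters"))
  if (is.null(lq$dt)) stop("dt is unset; Smax is undefined for pure LQ")
  lq$alpha + 2 * lq$beta * lq$dt
}

#' Local log-survival under the threshold LQ model
#'
#' For doses at or below the threshold (or with no threshold set) this is the
#' LQ exponent \eqn{-\alpha D - \beta D^2}. Above the threshold two forms are
#' available: \code{"standard"} (default) continues with the linear tail of
#' slope Smax, which is value- and slope-continuous at Dt and embodies the
#' usual motivation for the threshold (the pure LQ model over-predicts
#' killing at high dose); \code{"as_printed"} is the variant
#' \eqn{-\alpha D - \beta D^2 + S_{max}(D - D_t)}, retained for sensitivity
#' analysis (its tail curvature cancels the Smax slope at Dt).
#'
#' @param d dose in Gy (vectorised, >= 0).
#' @param lq an \code{\link{lq_parameters}} object.
#' @param form \code{"standard"} or \code{"as_printed"}.
#' @return ln survival (<= 0).
#' @export
local_log_survival <- function(d, lq, form = c("standard", "as_printed")) {
  form <- match.arg(form)
  stopifnot(inherits(lq, "lq_parameters"))
  if (any(d < 0)) stop("dose must be >= 0")
  ls <- -lq$alpha * d - lq$beta * d^2
  if (!is.null(lq$dt)) {
    over <- d > lq$dt
    if (any(over)) {
      smax <- lq_smax(lq)
      if (form == "standard") {
        ls[over] <- -lq$alpha * lq$dt - lq$beta * lq$dt^2 -
          smax * (d[over] - lq$dt)
      } else {
        ls[over] <- -lq$alpha * d[over] - lq$beta * d[over]^2 +
          smax * (d[over] - lq$dt)
      }
    }
  }
  ls
}

#' Nanoparticle-perturbed dose field
#'
#' Combines a uniform prescribed base dose with the dose-enhancement kernels
#' centred on each nanoparticle. Under the default \code{"additive_excess"}
#' rule the local dose at a point x is
#' \eqn{D(x) = D_0 (1 + \sum_i (DER(r_i) - 1))} — excess enhancements add,
#' matching the additivity of physical dose. The \code{"multiplicative"} rule
#' \eqn{D(x) = D_0 \prod_i DER(r_i)} applies each kernel literally as a
#' multiplier and is kept for sensitivity analysis. The kernel argument
#' \eqn{r_i} is the distance from the point to nanoparticle i minus the
#' nanoparticle radius, clamped at 0; kernels beyond their support contribute
#' exactly 1.
#'
#' @param base_dose prescribed uniform dose in Gy.
#' @param placement an \code{\link{np_placement}}.
#' @param kernel a \code{\link{der_profile}}.
#' @param combine_mode \code{"additive_excess"} or \code{"multiplicative"}.
#' @param np_diameter nanoparticle diameter in nm (the kernel is anchored at
#'   the particle surface).
#' @return Object of class \code{dose_field}.
#' @export
dose_field <- function(base_dose, placement, kernel,
                       combine_mode = c("additive_excess", "multiplicative"),
                       np_diameter = 15) {
  combine_mode <- match.arg(combine_mode)
  stopifnot(base_dose >= 0, inherits(placement, "np_placement"),
            inherits(kernel, "der_profile"), np_diameter > 0)
  structure(list(base_dose = base_dose, placement = placement,
                 kernel = kernel, combine_mode = combine_mode,
                 np_radius_nm = np_diameter / 2),
            class = "dose_field")
}

# Dose enhancement factor D(x)/D0 at each row of `points` (um), chunked so the
# points x nanoparticles distance matrix stays within memory.
enhancement_factor <- function(points, placement, kernel, combine_mode,
                               np_radius_nm) {
  n <- nrow(points)
  m <- nrow(placement$positions)
  if (m == 0) return(rep(1, n))
  px <- placement$positions[, 1]; py <- placement$positions[, 2]
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / m))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(points[s:e, 1], px, "-")
    dy <- outer(points[s:e, 2], py, "-")
    r_nm <- pmax(sqrt(dx * dx + dy * dy) * 1e3 - np_radius_nm, 0)
    der <- der_at(kernel, r_nm)
    dim(der) <- dim(r_nm)
    out[s:e] <- if (combine_mode == "additive_excess")
      1 + rowSums(der - 1) else apply(der, 1, prod)
  }
  out
}

#' Local dose at a point
#'
#' Evaluates the nanoparticle-perturbed dose field at one or more points.
#'
#' @param point numeric (x, y) in um, or an n x 2 matrix of points.
#' @param field a \code{\link{dose_field}}.
#' @return Local dose(s) in Gy.
#' @export
local_dose <- function(point, field) {
  stopifnot(inherits(field, "dose_field"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 2, byrow = TRUE)
  field$base_dose * enhancement_factor(point, field$placement, field$kernel,
                                       field$combine_mode, field$np_radius_nm)
}

sample_nucleus_points <- function(geometry, n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rn <- geometry$nucleus_diameter / 2
  r <- rn * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Expected number of lethal events and cell survival
#'
#' The local effect model asserts that equal local dose produces equal local
#' damage, so the expected number of lethal events is the average of
#' \eqn{-\ln S_x(D(x))} over the sensitive region — here the nucleus disc.
#' The average is estimated by Monte Carlo over \code{n_points} i.i.d.
#' uniform points in the nucleus, with the standard error of the estimate
#' reported; survival is \eqn{S = \exp(-\bar N)}. With an empty placement or
#' a unit kernel the local dose is constant and the estimate is exact (zero
#' variance).
#'
#' @param field a \code{\link{dose_field}}.
#' @param lq an \code{\link{lq_parameters}} object.
#' @param n_points number of integration points (>= 1).
#' @param seed integer seed for the integration points.
#' @param form threshold form passed to \code{\link{local_log_survival}}.
#' @return Object of class \code{survival_result}: \code{n_bar},
#'   \code{n_bar_se}, \code{survival}, \code{n_points}, \code{seed}.
#' @export
nbar <- function(field, lq, n_points = 2000, seed = 1L,
                 form = c("standard", "as_printed")) {
  form <- match.arg(form)
  stopifnot(inherits(field, "dose_field"), n_points >= 1)
  pts <- sample_nucleus_points(field$placement$geometry, n_points, seed)
  d <- local_dose(pts, field)
  ev <- -local_log_survival(d, lq, form)
  nb <- mean(ev)
  se <- if (n_points > 1) stats::sd(ev) / sqrt(n_points) else 0
  structure(list(n_bar = nb, n_bar_se = se, survival = exp(-nb),
                 n_points = n_points, seed = seed),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> N = %.4g +/- %.2g, S = %.4g (%d points)\n",
              x$n_bar, x$n_bar_se, x$survival, x$n_points))
  invisible(x)
}

derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Model survival curve from the full LEM pipeline
#'
#' For each replicate a fresh nanoparticle placement is drawn (sub-seeds
#' derived deterministically from \code{seed}) and the per-point dose
#' enhancement factor over the nucleus is computed once; survival at every
#' base dose then follows from the same enhancement field. Per-dose mean and
#' standard deviation over replicates are reported.
#'
#' @param geometry a \code{\link{cell_geometry}}.
#' @param count nanoparticle count for the 2-D model (see
#'   \code{\link{load_to_count}}).
#' @param mode placement mode, \code{"homogeneous"} or \code{"cytoplasm"}.
#' @param kernel a \code{\link{der_profile}}.
#' @param lq an \code{\link{lq_parameters}} object.
#' @param base_doses prescribed doses in Gy (default 2, 4, 6, 8).
#' @param replicates independent placements per dose.
#' @param n_points Monte Carlo integration points per placement.
#' @param seed master seed.
#' @param combine_mode kernel overlap rule, see \code{\link{dose_field}}.
#' @param np_diameter nanoparticle diameter in nm.
#' @param form threshold form for \code{\link{local_log_survival}}.
#' @return A \code{\link{survival_curve}} (source \code{"model"}) with
#'   columns \code{dose_Gy}, \code{sf}, \code{sf_se}, plus \code{sf_sd} and
#'   \code{n_replicates}.
#' @export
model_survival_curve <- function(geometry, count, mode, kernel, lq,
                                 base_doses = c(2, 4, 6, 8), replicates = 10,
                                 n_points = 2000, seed = 1L,
                                 combine_mode = "additive_excess",
                                 np_diameter = 15,
                                 form = "standard") {
  stopifnot(length(base_doses) >= 1, replicates >= 1)
  seeds <- derive_seeds(seed, 2L * replicates)
  sf <- matrix(NA_real_, nrow = replicates, ncol = length(base_doses))
  for (i in seq_len(replicates)) {
    pl <- place_nps(geometry, count, mode, seed = seeds[i])
    pts <- sample_nucleus_points(geometry, n_points, seed = seeds[replicates + i])
    ef <- enhancement_factor(pts, pl, kernel, combine_mode, np_diameter / 2)
    for (j in seq_along(base_doses)) {
      ev <- -local_log_survival(base_doses[j] * ef, lq, form)
      sf[i, j] <- exp(-mean(ev))
    }
  }
  sf_mean <- colMeans(sf)
  sf_sd <- if (replicates > 1) apply(sf, 2, stats::sd) else rep(0, ncol(sf))
  out <- survival_curve(doses = base_doses, sf = sf_mean,
                        sf_se = sf_sd / sqrt(replicates), source = "model")
  out$sf_sd <- sf_sd
  out$n_replicates <- replicates
  out
}
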