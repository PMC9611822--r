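#' Parameters of the synthetic DER kernel family
#'
#' A smooth monotone family emulating the steep radial falloff of
#' transport-code dose-enhancement kernels:
#' \deqn{DER(r) = 1 + (DER_{max} - 1) \left(\frac{r_{1/2}}{r_{1/2} + r}\right)^{p}.}
#' \code{r_half} is the distance at which the excess enhancement halves (for
#' p = 1) and \code{tail_exponent} p controls how fast the tail approaches 1.
#'
#' @param max_der peak enhancement at the particle surface (> 1).
#' @param r_half half-excess distance in nm (> 0; default 20).
#' @param tail_exponent tail decay exponent (> 0; default 1.5).
#' @param grid a \code{\link{shell_grid}} on which the kernel is tabulated.
#' @return Object of class \code{kernel_params}.
#' @export
kernel_params <- function(max_der, r_half = 20, tail_exponent = 1.5,
                          grid = shell_grid()) {
  if (max_der <= 1) stop("max_der must be > 1")
  stopifnot(r_half > 0, tail_exponent > 0, inherits(grid, "shell_grid"))
  structure(list(max_der = max_der, r_half = r_half,
                 tail_exponent = tail_exponent, grid = grid),
            class = "kernel_params")
}

der_truth <- function(params, r_nm) {
  1 + (params$max_der - 1) *
    (params$r_half / (params$r_half + r_nm))^params$tail_exponent
}

#' Generate a synthetic DER kernel
#'
#' Evaluates the \code{\link{kernel_params}} family at the shell midpoints of
#' its grid. Deterministic; the result is monotone non-increasing from
#' \code{max_der} toward 1.
#'
#' @param params a \code{\link{kernel_params}} object.
#' @return A \code{\link{der_profile}}.
#' @export
gen_kernel <- function(params) {
  stopifnot(inherits(params, "kernel_params"))
  grid <- params$grid
  mids <- shell_midpoints(grid)
  der_profile(radii = mids, der = der_truth(params, mids),
              support_max = max(grid$outer),
              edges = c(grid$inner[1], grid$outer))
}

#' Depth-indexed kernel presets
#'
#' Named members of the synthetic kernel family whose peak enhancements
#' follow the depth series observed for a 6 MV beam hardening through water:
#' maximum DER 5.5, 7, 7.5 and 8 at 2.5, 10, 20 and 30 cm depth.
#'
#' @param name one of \code{"depth2.5"}, \code{"depth10"}, \code{"depth20"},
#'   \code{"depth30"}.
#' @param ... passed on to \code{\link{kernel_params}} (e.g. \code{grid}).
#' @return A \code{\link{kernel_params}} object.
#' @export
kernel_preset <- function(name = c("depth2.5", "depth10", "depth20", "depth30"),
                          ...) {
  name <- match.arg(name)
  max_der <- c("depth2.5" = 5.5, "depth10" = 7, "depth20" = 7.5,
               "depth30" = 8)[[name]]
  kernel_params(max_der = max_der, ...)
}

#' Generate paired radial dose tables with a known DER ground truth
#'
#' Constructs a smooth decaying water-nanoparticle dose profile and the
#' gold-nanoparticle profile that, pushed through \code{\link{compute_der}}
#' with the same normalization factors, recovers the truth kernel exactly at
#' zero noise (the generator inverts the enhancement-ratio definition
#' algebraically). With \code{noise_cv > 0}, both profiles receive
#' independent multiplicative lognormal noise of that coefficient of
#' variation.
#'
#' @param kernel_truth a \code{\link{kernel_params}} object.
#' @param norm a \code{\link{norm_factors}} object.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed integer seed (used only when \code{noise_cv > 0}).
#' @param n_histories bookkeeping count stored on both profiles.
#' @return List with elements \code{aunp} and \code{wnp}, both
#'   \code{\link{radial_dose_profile}} objects on the truth grid.
#' @export
gen_radial_dose <- function(kernel_truth, norm, noise_cv = 0, seed = 1L,
                            n_histories = 5e5) {
  stopifnot(inherits(kernel_truth, "kernel_params"),
            inherits(norm, "norm_factors"), noise_cv >= 0)
  grid <- kernel_truth$grid
  mids <- shell_midpoints(grid)
  # smooth near-field-dominated water profile (arbitrary batch scale)
  d_w <- norm$d_bg * 5 * (100 / (100 + mids))^2 + norm$d_bg * 0.05
  truth <- der_truth(kernel_truth, mids)
  d_au <- (truth * (d_w * norm$f1 * norm$f2_wnp + norm$d_bg) - norm$d_bg) /
    (norm$f1 * norm$f2_aunp)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sdl <- sqrt(log(1 + noise_cv^2))
    mu <- -sdl^2 / 2   # unit-mean lognormal
    d_au <- d_au * stats::rlnorm(length(d_au), mu, sdl)
    d_w <- d_w * stats::rlnorm(length(d_w), mu, sdl)
  }
  list(aunp = radial_dose_profile(grid, d_au, "AuNP", n_histories),
       wnp = radial_dose_profile(grid, d_w, "WNP", n_histories))
}

#' Generate a synthetic megavoltage particle spectrum
#'
#' Mixture emulating a 6 MV beam at depth: a lognormal megavoltage photon
#' component plus a uniform sub-100 keV component at the target rate, with
#' electron labels assigned independently at the target electron fraction.
#' The lognormal location is chosen so the overall weighted mean energy
#' converges to \code{e_mean_target} as n grows.
#'
#' @param e_mean_target target mean energy in MeV.
#' @param frac_low_target target percent of particles below 100 keV, in
#'   [0, 100).
#' @param electron_frac_target target percent of electrons, in [0, 100).
#' @param n number of records (>= 100).
#' @param seed integer seed.
#' @param sdlog log-scale spread of the megavoltage component.
#' @return An \code{\link{energy_spectrum}} with unit weights.
#' @export
gen_spectrum <- function(e_mean_target, frac_low_target = 2.5,
                         electron_frac_target = 1.2, n = 1e5, seed = 1L,
                         sdlog = 0.8) {
  stopifnot(n >= 100, e_mean_target > 0)
  if (frac_low_target < 0 || frac_low_target >= 100 ||
      electron_frac_target < 0 || electron_frac_target >= 100)
    stop("infeasible targets: fractions must lie in [0, 100)")
  p_low <- frac_low_target / 100
  mean_low <- 0.05                       # uniform(0.001, 0.099) component
  m_high <- (e_mean_target - p_low * mean_low) / (1 - p_low)
  if (m_high <= 0.1)
    stop("infeasible targets: mean too low for the sub-100 keV fraction")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  low <- stats::runif(n) < p_low
  e <- numeric(n)
  e[low] <- stats::runif(sum(low), 0.001, 0.099)
  # lognormal above 0.1 MeV with matched conditional mean
  nh <- sum(!low)
  if (nh > 0) {
    meanlog <- log(m_high) - sdlog^2 / 2
    eh <- stats::rlnorm(nh, meanlog, sdlog)
    while (any(eh < 0.1)) eh[eh < 0.1] <- stats::rlnorm(sum(eh < 0.1), meanlog, sdlog)
    e[!low] <- eh
  }
  type <- ifelse(stats::runif(n) < electron_frac_target / 100,
                 "electron", "photon")
  energy_spectrum(type, e, weight = rep(1, n),
                  cos_theta = rep(1, n))
}

#' Generate synthetic clonogenic assay records
#'
#' Per dish, the colony count is Binomial(n_seeded, pe0 * Sx(D)) under the
#' supplied LQ truth — binomial rather than Poisson so that counts can never
#' exceed the seeding number. Dose-0 control dishes are always included.
#'
#' @param lq an \code{\link{lq_parameters}} truth.
#' @param doses positive doses in Gy (default 2, 4, 6, 8).
#' @param n_seeded cells seeded per dish: a scalar, or a vector with one
#'   entry per dose level (control first). The default escalates seeding
#'   with dose — standard clonogenic practice, so that every dish retains a
#'   countable expected number of colonies at high dose.
#' @param pe0 control plating efficiency in (0, 1].
#' @param replicates dishes per dose (>= 1; default triplicate).
#' @param seed integer seed.
#' @param group label for the treatment group.
#' @return A \code{\link{clonogenic_records}} data.frame including the dose-0
#'   controls.
#' @export
gen_clonogenic <- function(lq, doses = c(2, 4, 6, 8),
                           n_seeded = 200 * 4^(0:length(doses)),
                           pe0 = 0.5, replicates = 3, seed = 1L,
                           group = "synthetic") {
  stopifnot(inherits(lq, "lq_parameters"), pe0 > 0, pe0 <= 1,
            replicates >= 1, all(n_seeded >= 1), all(doses > 0))
  all_doses <- c(0, doses)
  if (length(n_seeded) == 1L) n_seeded <- rep(n_seeded, length(all_doses))
  if (length(n_seeded) != length(all_doses))
    stop("n_seeded must be scalar or have one entry per dose level (control first)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- pe0 * exp(local_log_survival(all_doses, lq))
  df <- do.call(rbind, lapply(seq_along(all_doses), function(j) {
    data.frame(group = group, dose_Gy = all_doses[j], n_seeded = n_seeded[j],
               n_colonies = stats::rbinom(replicates, n_seeded[j], p[j]),
               replicate = seq_len(replicates))
  }))
  clonogenic_records(df)
}
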