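#' Clonogenic assay records
#'
#' Validates a data.frame of clonogenic dishes: \code{group} (treatment
#' label), \code{dose_Gy}, \code{n_seeded}, \code{n_colonies},
#' \code{replicate}. Colony counts exceeding the seeding number draw a
#' warning (miscounts happen) but are not rejected.
#'
#' @param records data.frame with the columns above.
#' @return The validated data.frame, classed \code{clonogenic_records}.
#' @export
clonogenic_records <- function(records) {
  need <- c("group", "dose_Gy", "n_seeded", "n_colonies", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(records$dose_Gy >= 0), all(records$n_seeded > 0),
            all(records$n_colonies >= 0))
  if (any(records$n_colonies > records$n_seeded))
    warning("some dishes report more colonies than cells seeded")
  class(records) <- unique(c("clonogenic_records", class(records)))
  records
}

#' Plating efficiency per treatment group
#'
#' Per dish, PE = colonies / cells seeded; per (group, dose), the mean and
#' sample standard deviation over replicate dishes.
#'
#' @param records a \code{\link{clonogenic_records}} data.frame.
#' @return data.frame with \code{group}, \code{dose_Gy}, \code{pe_mean},
#'   \code{pe_sd}, \code{n}.
#' @export
plating_efficiency <- function(records) {
  records <- clonogenic_records(records)
  if (nrow(records) == 0) stop("no records")
  pe <- records$n_colonies / records$n_seeded
  key <- interaction(records$group, records$dose_Gy, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(group = records$group[i[1]], dose_Gy = records$dose_Gy[i[1]],
               pe_mean = mean(pe[i]),
               pe_sd = if (length(i) > 1) stats::sd(pe[i]) else 0,
               n = length(i))
  }))
  rownames(agg) <- NULL
  if (any(agg$pe_mean == 0))
    warning("plating efficiency of 0 in at least one group")
  agg[order(agg$group, agg$dose_Gy), , drop = FALSE]
}

#' Dose-survival curve container
#'
#' @param doses doses in Gy, strictly increasing.
#' @param sf surviving fractions in (0, 1]; if dose 0 is present its sf must
#'   be 1.
#' @param sf_se optional standard errors.
#' @param source \code{"experiment"} or \code{"model"}.
#' @return data.frame of class \code{survival_curve} with columns
#'   \code{dose_Gy}, \code{sf}, \code{sf_se}.
#' @export
survival_curve <- function(doses, sf, sf_se = NULL,
                           source = c("experiment", "model")) {
  source <- match.arg(source)
  stopifnot(length(doses) == length(sf))
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  if (any(sf <= 0) || any(sf > 1)) stop("sf must lie in (0, 1]")
  if (any(doses == 0) && sf[doses == 0] != 1) stop("sf at dose 0 must be 1")
  df <- data.frame(dose_Gy = doses, sf = sf,
                   sf_se = if (is.null(sf_se)) NA_real_ else sf_se)
  attr(df, "source") <- source
  class(df) <- c("survival_curve", "data.frame")
  df
}

#' Survival fractions from clonogenic records
#'
#' SF(D) is the plating efficiency of the irradiated dishes divided by that
#' of the unirradiated controls; the standard error combines the two PE
#' standard errors by first-order propagation for a ratio.
#'
#' @param irradiated records at positive doses.
#' @param control records at dose 0 (same group conventions).
#' @return A \code{\link{survival_curve}} (source \code{"experiment"}).
#' @export
survival_fractions <- function(irradiated, control) {
  pe_c <- plating_efficiency(control)
  if (nrow(pe_c) != 1) pe_c <- pe_c[pe_c$dose_Gy == 0, , drop = FALSE][1, , drop = FALSE]
  if (pe_c$pe_mean <= 0) stop("control plating efficiency must be > 0")
  pe_i <- plating_efficiency(irradiated)
  pe_i <- pe_i[order(pe_i$dose_Gy), , drop = FALSE]
  sf <- pmin(pe_i$pe_mean / pe_c$pe_mean, 1)
  se_c <- pe_c$pe_sd / sqrt(pe_c$n)
  se_i <- pe_i$pe_sd / sqrt(pe_i$n)
  sf_se <- sf * sqrt((se_i / pmax(pe_i$pe_mean, .Machine$double.eps))^2 +
                     (se_c / pe_c$pe_mean)^2)
  if (any(sf <= 0)) stop("zero surviving fraction; dose range exceeds assay sensitivity")
  out <- survival_curve(pe_i$dose_Gy, sf, sf_se, source = "experiment")
  # the control PE error is shared by every dose point: record its ln-scale
  # size so downstream fits can model the induced correlation
  attr(out, "se_ln_common") <- se_c / pe_c$pe_mean
  out
}

#' Fit the linear-quadratic model to a survival curve
#'
#' Generalized least squares of ln SF on \eqn{-\alpha D - \beta D^2} over
#' the positive doses, with alpha and beta constrained non-negative (a
#' negative beta makes the mean inactivation dose divergent). When the
#' curve carries standard errors they enter as a per-point ln-scale
#' variance; a curve produced by \code{\link{survival_fractions}} also
#' carries the ln-scale error of the shared unirradiated control, which is
#' common to every dose point and is modelled as an equicorrelated
#' covariance component (ignoring it makes the fit overconfident). Without
#' standard errors the fit is ordinary least squares. The two-parameter
#' non-negative problem is solved exactly: the unconstrained fit is
#' accepted if interior, otherwise the violated coefficient is pinned to 0
#' and the other refit. 95 percent confidence intervals come from the
#' parameter covariance (residual-rescaled) with a t reference on n - 2
#' degrees of freedom; goodness of fit is reported as R^2 on the whitened
#' ln scale.
#'
#' @param curve a \code{\link{survival_curve}} with >= 3 distinct positive
#'   doses.
#' @return An \code{\link{lq_parameters}} object with attributes \code{ci95}
#'   (2 x 2 matrix, rows alpha/beta), \code{cov} (covariance of the fitted
#'   coefficients), \code{r_squared} and \code{df}.
#' @export
fit_lq <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  pos <- curve$dose_Gy > 0
  d <- curve$dose_Gy[pos]
  sf <- curve$sf[pos]
  if (length(unique(d)) < 3) stop("need at least 3 distinct positive doses")
  if (length(unique(sf)) == 1) stop("degenerate curve: all surviving fractions equal")
  n <- length(d)
  y <- log(sf)
  se <- curve$sf_se[pos]
  se_y <- if (all(is.finite(se))) se / sf else rep(1, n)
  common <- attr(curve, "se_ln_common")
  if (is.null(common) || !is.finite(common)) common <- 0
  # covariance of y: independent part + the shared control-arm component
  Sigma <- diag(pmax(se_y^2 - common^2, 1e-12), n) + common^2
  Si <- solve(Sigma)
  gls <- function(X) {
    vc0 <- solve(t(X) %*% Si %*% X)
    cf <- drop(vc0 %*% t(X) %*% Si %*% y)
    r <- y - drop(X %*% cf)
    s2 <- drop(t(r) %*% Si %*% r) / max(n - 2L, 1L)
    list(cf = cf, vc = vc0 * s2, resid = r, s2 = s2)
  }
  X <- cbind(-d, -d^2)
  f <- gls(X)
  cf <- f$cf
  vc <- f$vc
  if (any(cf < 0)) {
    # pin the violated coefficient at zero and refit the other
    j <- if (cf[2] < 0) 1L else 2L
    f1 <- gls(X[, j, drop = FALSE])
    cf <- c(0, 0); cf[j] <- max(f1$cf, 0)
    vc <- matrix(0, 2, 2); vc[j, j] <- f1$vc
    f$resid <- y - drop(X %*% cf)
    f$s2 <- f1$s2
  }
  dfree <- max(n - 2L, 1L)
  tq <- stats::qt(0.975, dfree)
  hw <- tq * sqrt(diag(vc))
  ci <- rbind(alpha = c(cf[1] - hw[1], cf[1] + hw[1]),
              beta  = c(cf[2] - hw[2], cf[2] + hw[2]))
  colnames(ci) <- c("lower", "upper")
  ybar <- sum(Si %*% y) / sum(Si)
  r2 <- 1 - drop(t(f$resid) %*% Si %*% f$resid) /
    drop(t(y - ybar) %*% Si %*% (y - ybar))
  out <- lq_parameters(alpha = cf[[1]], beta = cf[[2]])
  attr(out, "ci95") <- ci
  attr(out, "cov") <- vc
  attr(out, "r_squared") <- r2
  attr(out, "df") <- dfree
  out
}

#' Mean inactivation dose
#'
#' The area under the survival-fraction curve,
#' \eqn{MID = \int_0^\infty S_x(D)\,dD}, i.e. the mean of the
#' dose-to-inactivation distribution. Three evaluation routes:
#' \describe{
#'   \item{closed_form}{pure LQ only. For beta > 0,
#'     \eqn{\sqrt{\pi/(4\beta)}\, e^{\alpha^2/(4\beta)}\,
#'     \mathrm{erfc}(\alpha/(2\sqrt\beta))}, computed with the scaled
#'     complementary error function for numerical stability; for beta = 0,
#'     \eqn{1/\alpha}.}
#'   \item{quadrature}{adaptive integration of the (possibly thresholded)
#'     survival function to infinity.}
#'   \item{trapezoid}{trapezoidal rule over a measured curve's dose range
#'     only (a documented truncation; dose 0 with SF 1 is included when
#'     absent).}
#' }
#'
#' @param x an \code{\link{lq_parameters}} object (closed_form, quadrature)
#'   or a \code{\link{survival_curve}} (trapezoid).
#' @param method one of \code{"closed_form"}, \code{"quadrature"},
#'   \code{"trapezoid"}.
#' @param form threshold form for quadrature, see
#'   \code{\link{local_log_survival}}.
#' @return MID in Gy.
#' @examples
#' mid(lq_parameters(1, 0))                       # 1 Gy
#' mid(lq_parameters(0.4337, 0.0259))             # ~1.92 Gy
#' @export
mid <- function(x, method = c("closed_form", "quadrature", "trapezoid"),
                form = "standard") {
  method <- match.arg(method)
  if (method == "trapezoid") {
    stopifnot(inherits(x, "survival_curve"))
    d <- x$dose_Gy; s <- x$sf
    if (!any(d == 0)) { d <- c(0, d); s <- c(1, s) }
    return(sum(diff(d) * (utils::head(s, -1) + utils::tail(s, -1)) / 2))
  }
  stopifnot(inherits(x, "lq_parameters"))
  if (x$alpha == 0 && x$beta == 0) stop("divergent MID: alpha = beta = 0")
  if (method == "closed_form") {
    if (!is.null(x$dt)) stop("closed_form requires pure LQ (dt unset)")
    if (x$beta == 0) return(1 / x$alpha)
    return(sqrt(pi / (4 * x$beta)) * pracma::erfcx(x$alpha / (2 * sqrt(x$beta))))
  }
  sx <- function(d) exp(local_log_survival(d, x, form))
  if (is.null(x$dt)) {
    stats::integrate(sx, 0, Inf, rel.tol = 1e-10)$value
  } else {
    stats::integrate(sx, 0, x$dt, rel.tol = 1e-10)$value +
      stats::integrate(sx, x$dt, Inf, rel.tol = 1e-10)$value
  }
}

#' Sensitization enhancement ratio
#'
#' \eqn{SER = MID_{IR} / MID_{IR+AuNP}}: the factor by which the
#' nanoparticle treatment shrinks the mean inactivation dose. Values above 1
#' indicate radiosensitization. If fitted LQ parameter covariances are
#' supplied, a seeded parametric bootstrap propagates the fit uncertainty
#' into \code{ser_se}.
#'
#' @param mid_ir MID of the radiation-only curve, Gy.
#' @param mid_with_aunp MID of the radiation + nanoparticle curve, Gy.
#' @param fit_ir,fit_aunp optional \code{\link{fit_lq}} results for the two
#'   arms (used only for the bootstrap).
#' @param n_boot bootstrap draws (default 2000).
#' @param seed bootstrap seed.
#' @return Object of class \code{ser_result}: \code{mid_ir},
#'   \code{mid_with_aunp}, \code{ser}, and \code{ser_se} (NA without
#'   bootstrap inputs).
#' @export
ser <- function(mid_ir, mid_with_aunp, fit_ir = NULL, fit_aunp = NULL,
                n_boot = 2000, seed = 1L) {
  if (mid_ir <= 0 || mid_with_aunp <= 0) stop("MIDs must be > 0")
  ser_se <- NA_real_
  if (!is.null(fit_ir) && !is.null(fit_aunp)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    draw_mid <- function(fit) {
      th <- MASS::mvrnorm(n_boot, mu = c(fit$alpha, fit$beta),
                          Sigma = attr(fit, "cov"))
      th <- pmax(th, 1e-8)   # respect the non-negativity constraint
      vapply(seq_len(n_boot), function(i)
        mid(lq_parameters(th[i, 1], th[i, 2])), numeric(1))
    }
    ser_se <- stats::sd(draw_mid(fit_ir) / draw_mid(fit_aunp))
  }
  structure(list(mid_ir = mid_ir, mid_with_aunp = mid_with_aunp,
                 ser = mid_ir / mid_with_aunp, ser_se = ser_se),
            class = "ser_result")
}

#' @export
print.ser_result <- function(x, ...) {
  cat(sprintf("<ser_result> SER = %.3f (MID %.3f / %.3f Gy)",
              x$ser, x$mid_ir, x$mid_with_aunp))
  if (is.finite(x$ser_se)) cat(sprintf(" +/- %.3f", x$ser_se))
  cat("\n")
  invisible(x)
}

#' Mean relative difference between two SER series
#'
#' Summarises model-vs-benchmark agreement as
#' \eqn{\mathrm{mean}_i |m_i - r_i| / r_i \times 100} percent.
#'
#' @param model_sers,reference_sers equal-length numeric vectors (>= 1).
#' @return Mean relative difference in percent.
#' @export
compare_ser <- function(model_sers, reference_sers) {
  if (length(model_sers) != length(reference_sers))
    stop("SER series must have equal length")
  if (length(model_sers) < 1) stop("empty SER series")
  if (any(reference_sers <= 0)) stop("reference SERs must be > 0")
  mean(abs(model_sers - reference_sers) / reference_sers) * 100
}
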