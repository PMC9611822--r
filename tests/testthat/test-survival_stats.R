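make_records <- function(dose, colonies, n_seeded = 100, group = "g") {
  data.frame(group = group, dose_Gy = dose, n_seeded = n_seeded,
             n_colonies = colonies, replicate = seq_along(colonies))
}

test_that("plating efficiency summarises replicate dishes", {
  pe <- plating_efficiency(make_records(0, 50))
  expect_equal(pe$pe_mean, 0.5)
  expect_equal(pe$pe_sd, 0)

  pe3 <- plating_efficiency(make_records(0, c(40, 50, 60)))
  expect_equal(pe3$pe_mean, 0.5)
  expect_equal(pe3$pe_sd, 0.1)

  expect_warning(pe0 <- plating_efficiency(make_records(2, c(0, 0, 0))),
                 "plating efficiency of 0")
  expect_equal(pe0$pe_mean, 0)
  expect_error(plating_efficiency(make_records(0, 10)[0, ]), "no records")
  expect_warning(plating_efficiency(make_records(0, 150)), "more colonies")
})

test_that("survival fractions are PE ratios against the unirradiated control", {
  ctrl <- make_records(0, c(48, 50, 52))
  irr <- rbind(make_records(2, c(24, 25, 26)), make_records(4, c(12, 13, 11)))
  sc <- survival_fractions(irr, ctrl)
  expect_s3_class(sc, "survival_curve")
  expect_equal(sc$sf[1], 0.5)
  expect_equal(sc$sf[2], 0.24, tolerance = 1e-12)
  expect_true(all(is.finite(sc$sf_se)))

  same <- survival_fractions(make_records(2, c(48, 50, 52)), ctrl)
  expect_equal(same$sf, 1)

  dead_ctrl <- make_records(0, c(0, 0, 0))
  expect_error(suppressWarnings(survival_fractions(irr, dead_ctrl)),
               "control plating efficiency")
})

test_that("synthetic assays round-trip to their ground-truth survival", {
  truth <- lq_parameters(0.4337, 0.0259)
  rec <- gen_clonogenic(truth, n_seeded = 5000, replicates = 6, seed = 31)
  sc <- survival_fractions(rec[rec$dose_Gy > 0, ], rec[rec$dose_Gy == 0, ])
  sf_true <- exp(local_log_survival(sc$dose_Gy, truth))
  expect_true(all(abs(sc$sf - sf_true) < 3 * pmax(sc$sf_se, 1e-4) + 0.02))
})

test_that("LQ fitting recovers noiseless parameters exactly", {
  d <- c(2, 4, 6, 8)
  curve <- survival_curve(d, exp(-0.5 * d - 0.02 * d^2), source = "model")
  fit <- fit_lq(curve)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-10)
  expect_equal(fit$beta, 0.02, tolerance = 1e-10)
  expect_gt(attr(fit, "r_squared"), 1 - 1e-12)

  # pure exponential data pins beta at the constraint boundary
  cexp <- survival_curve(d, exp(-0.5 * d), source = "model")
  fexp <- fit_lq(cexp)
  expect_equal(fexp$beta, 0)
  expect_equal(fexp$alpha, 0.5, tolerance = 1e-10)

  expect_error(fit_lq(survival_curve(c(2, 4), exp(-c(2, 4) * 0.5),
                                     source = "model")), "3 distinct")
  expect_error(fit_lq(survival_curve(d, rep(0.5, 4), source = "model")),
               "degenerate")
})

test_that("mean inactivation dose: closed form, quadrature and trapezoid agree", {
  expect_equal(mid(lq_parameters(1, 0)), 1)
  expect_equal(mid(lq_parameters(0.4337, 0.0259)), 1.918796, tolerance = 1e-6)
  expect_equal(mid(lq_parameters(0.4337, 0.0259)),
               mid(lq_parameters(0.4337, 0.0259), "quadrature"),
               tolerance = 1e-8)
  expect_error(mid(lq_parameters(0, 0)))
  expect_error(mid(lq_parameters(1, 0.1, dt = 5)), "pure LQ")

  # trapezoid truncates at the measured range and prepends dose 0
  cv <- analytic_curve(lq_parameters(1, 0), doses = c(1, 2))
  expect_equal(mid(cv, "trapezoid"),
               0.5 * (1 + exp(-1)) + 0.5 * (exp(-1) + exp(-2)))

  # thresholded survival integrates piecewise; the linear tail decays more
  # slowly than the LQ quadratic, so the threshold model has the larger MID
  lqt <- lq_parameters(0.3, 0.02, dt = 6)
  m <- mid(lqt, "quadrature")
  expect_gt(m, mid(lq_parameters(0.3, 0.02), "quadrature"))
  expect_lt(m, 1 / 0.3)   # but never beyond the alpha-only exponential
})

test_that("closed-form MID equals quadrature across the parameter sweep", {
  set.seed(101)
  for (i in 1:100) {
    a <- runif(1, 0.05, 2)
    b <- runif(1, 1e-4, 0.1)
    lq <- lq_parameters(a, b)
    expect_equal(mid(lq, "closed_form"), mid(lq, "quadrature"),
                 tolerance = 1e-8)
  }
})

test_that("SER is the MID ratio and responds to curve ordering", {
  expect_equal(ser(2, 2)$ser, 1)
  expect_equal(ser(2.0, 1.6)$ser, 1.25)
  expect_error(ser(0, 1), "> 0")

  # a curve strictly below the reference at all doses has SER > 1
  lq_ir <- lq_parameters(0.4, 0.02)
  lq_np <- lq_parameters(0.6, 0.02)
  expect_gt(ser(mid(lq_ir), mid(lq_np))$ser, 1)

  # SER is invariant under common dose-axis rescaling (both MIDs scale)
  s <- 2.7
  lq_ir_s <- lq_parameters(0.4 / s, 0.02 / s^2)
  lq_np_s <- lq_parameters(0.6 / s, 0.02 / s^2)
  expect_equal(ser(mid(lq_ir_s), mid(lq_np_s))$ser,
               ser(mid(lq_ir), mid(lq_np))$ser, tolerance = 1e-10)
})

test_that("bootstrap SER uncertainty is reproducible and positive", {
  d <- c(2, 4, 6, 8)
  set.seed(55)
  mk <- function(a, b) {
    sf <- exp(-a * d - b * d^2) * exp(rnorm(4, 0, 0.03))
    survival_curve(d, pmin(sf, 1), sf_se = 0.03 * sf, source = "experiment")
  }
  f_ir <- fit_lq(mk(0.43, 0.026))
  f_np <- fit_lq(mk(0.58, 0.012))
  s1 <- ser(mid(f_ir), mid(f_np), f_ir, f_np, n_boot = 500, seed = 9)
  s2 <- ser(mid(f_ir), mid(f_np), f_ir, f_np, n_boot = 500, seed = 9)
  expect_identical(s1$ser_se, s2$ser_se)
  expect_gt(s1$ser_se, 0)
})

test_that("compare_ser reports the mean relative difference in percent", {
  expect_equal(compare_ser(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compare_ser(1.1 * c(1, 2), c(1, 2)), 10)
  expect_error(compare_ser(1, c(1, 2)), "equal length")
})

test_that("fit_lq bias shrinks as replication grows", {
  truth <- lq_parameters(0.4337, 0.0259)
  bias <- vapply(c(3, 10, 30), function(reps) {
    est <- vapply(1:40, function(s) {
      rec <- gen_clonogenic(truth, replicates = reps, seed = 5000 + s)
      fit_lq(survival_fractions(rec[rec$dose_Gy > 0, ],
                                rec[rec$dose_Gy == 0, ]))$alpha
    }, numeric(1))
    abs(mean(est) - truth$alpha)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.01)
  expect_lt(bias[3], 0.02)
})
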