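test_that("local dose combines kernels by additive excess or product", {
  geo <- cell_geometry()
  lq <- lq_parameters(1, 0)

  # no nanoparticles: base dose everywhere
  empty <- place_nps(geo, 0, "homogeneous", seed = 1)
  k <- step_kernel(2, 1000)
  f <- dose_field(4, empty, k)
  expect_equal(local_dose(c(0, 0), f), 4)

  # single NP close to the point: both modes give D0 * DER
  one <- place_nps(geo, 0, "homogeneous", seed = 1)
  one$positions <- matrix(c(0.5, 0), ncol = 2,
                          dimnames = list(NULL, c("x", "y")))
  fa <- dose_field(4, one, k, "additive_excess", np_diameter = 1e-9)
  fm <- dose_field(4, one, k, "multiplicative", np_diameter = 1e-9)
  expect_equal(local_dose(c(0, 0), fa), 8)
  expect_equal(local_dose(c(0, 0), fm), 8)

  # two NPs with DER 2 and 3: additive excess 4, multiplicative 6
  k23 <- der_profile(radii = c(250, 750), der = c(3, 2), support_max = 1000,
                     edges = c(0, 500, 1000))
  two <- one
  two$positions <- matrix(c(0.1, 0, 0.7, 0), ncol = 2, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y")))
  fa2 <- dose_field(1, two, k23, "additive_excess", np_diameter = 1e-9)
  fm2 <- dose_field(1, two, k23, "multiplicative", np_diameter = 1e-9)
  expect_equal(local_dose(c(0, 0), fa2), 4)
  expect_equal(local_dose(c(0, 0), fm2), 6)

  # kernels beyond support contribute exactly 1
  far <- one
  far$positions <- matrix(c(5, 0), ncol = 2,
                          dimnames = list(NULL, c("x", "y")))
  ff <- dose_field(4, far, k)
  expect_equal(local_dose(c(0, 0), ff), 4)
})

test_that("threshold log-survival is continuous and matches hand arithmetic", {
  lq <- lq_parameters(0.4, 0.03, dt = 10)
  expect_equal(lq_smax(lq), 1.0)
  expect_equal(local_log_survival(0, lq), 0)
  expect_equal(local_log_survival(11, lq), -8)   # -(4 + 3) - 1.0 * 1
  # both forms agree at the threshold
  expect_equal(local_log_survival(10, lq, "standard"),
               local_log_survival(10, lq, "as_printed"))
  expect_equal(local_log_survival(10, lq), -(0.4 * 10 + 0.03 * 100))
  # as-printed variant evaluated literally
  expect_equal(local_log_survival(11, lq, "as_printed"),
               -0.4 * 11 - 0.03 * 121 + 1.0 * (11 - 10))
  # pure LQ when dt unset
  lq0 <- lq_parameters(0.4, 0.03)
  expect_equal(local_log_survival(20, lq0), -0.4 * 20 - 0.03 * 400)
  expect_error(local_log_survival(-1, lq0), ">= 0")
  expect_error(lq_smax(lq0), "unset")
})

test_that("nbar is exact for uniform dose fields", {
  geo <- cell_geometry()
  lq <- lq_parameters(0.4337, 0.0259)
  empty <- place_nps(geo, 0, "homogeneous", seed = 1)
  for (D in c(2, 4, 6, 8)) {
    res <- nbar(dose_field(D, empty, step_kernel()), lq, n_points = 50, seed = 2)
    expect_equal(res$n_bar, 0.4337 * D + 0.0259 * D^2)
    expect_equal(res$n_bar_se, 0)
    expect_equal(res$survival, exp(-res$n_bar))
  }
  # a kernel identically 1 behaves exactly like no nanoparticles
  pl <- place_nps(geo, 200, "cytoplasm", seed = 3)
  res1 <- nbar(dose_field(4, pl, unit_kernel()), lq, n_points = 100, seed = 2)
  expect_equal(res1$n_bar, 0.4337 * 4 + 0.0259 * 16)
  expect_equal(res1$n_bar_se, 0)
})

test_that("nbar matches the closed-form area-fraction oracle for a step kernel", {
  # one NP at the nucleus centre, DER = 2 within 1 um: the enhanced disc is
  # 1/16 of the 4 um nucleus disc, so N = 2 * (15/16) + 4 * (1/16) = 2.125
  geo <- cell_geometry()
  pl <- place_nps(geo, 0, "homogeneous", seed = 1)
  pl$positions <- matrix(c(0, 0), ncol = 2,
                         dimnames = list(NULL, c("x", "y")))
  lq <- lq_parameters(1, 0)
  f <- dose_field(2, pl, step_kernel(2, 1000), np_diameter = 1e-9)
  res <- nbar(f, lq, n_points = 4e4, seed = 7)
  expect_lt(abs(res$n_bar - 2.125), 3 * res$n_bar_se)
})

test_that("nbar is monotone in dose, count and kernel strength", {
  geo <- cell_geometry()
  lq <- lq_parameters(0.4, 0.03)
  k <- gen_kernel(kernel_preset("depth2.5", grid = shell_grid(50, 4, 50, 200)))
  pl <- place_nps(geo, 400, "cytoplasm", seed = 13)

  nb_dose <- vapply(c(1, 2, 4, 8), function(D)
    nbar(dose_field(D, pl, k), lq, n_points = 400, seed = 5)$n_bar, numeric(1))
  expect_true(all(diff(nb_dose) > 0))

  nb_count <- vapply(c(50, 150, 400), function(m)
    nbar(dose_field(4, placement_prefix(pl, m), k), lq,
         n_points = 400, seed = 5)$n_bar, numeric(1))
  expect_true(all(diff(nb_count) > 0))

  nb_kern <- vapply(c(2, 5.5, 8), function(md)
    nbar(dose_field(4, pl, gen_kernel(kernel_params(md))), lq,
         n_points = 400, seed = 5)$n_bar, numeric(1))
  expect_true(all(diff(nb_kern) > 0))

  # survival is always a valid probability
  expect_true(all(exp(-nb_dose) > 0 & exp(-nb_dose) <= 1))
})

test_that("Monte Carlo integration variance halves when points double", {
  geo <- cell_geometry()
  lq <- lq_parameters(0.4, 0.03)
  k <- gen_kernel(kernel_preset("depth2.5", grid = shell_grid(50, 4, 50, 200)))
  pl <- place_nps(geo, 300, "cytoplasm", seed = 29)
  f <- dose_field(4, pl, k)
  est <- function(n) vapply(1:30, function(s)
    nbar(f, lq, n_points = n, seed = 1000 + s)$n_bar, numeric(1))
  v1 <- var(est(250))
  v2 <- var(est(500))
  expect_equal(v2 / v1, 0.5, tolerance = 0.5)  # halves, up to sampling noise
})

test_that("model survival curve reduces to the analytic LQ curve for unit kernels", {
  geo <- cell_geometry()
  lq <- lq_parameters(0.4337, 0.0259)
  cv <- model_survival_curve(geo, 100, "cytoplasm", unit_kernel(), lq,
                             replicates = 3, n_points = 200, seed = 4)
  expect_equal(cv$sf, exp(local_log_survival(c(2, 4, 6, 8), lq)))
  expect_equal(cv$sf_sd, rep(0, 4))

  # an enhancing kernel pushes survival strictly below the LQ curve
  cv2 <- model_survival_curve(geo, 100, "cytoplasm",
                              gen_kernel(kernel_preset("depth2.5")), lq,
                              replicates = 3, n_points = 200, seed = 4)
  expect_true(all(cv2$sf < cv$sf))
})

test_that("model curves are deterministic under a fixed seed", {
  geo <- cell_geometry()
  lq <- lq_parameters(0.4, 0.02)
  k <- gen_kernel(kernel_preset("depth10", grid = shell_grid(50, 4, 50, 200)))
  a <- model_survival_curve(geo, 150, "homogeneous", k, lq,
                            replicates = 4, n_points = 300, seed = 77)
  b <- model_survival_curve(geo, 150, "homogeneous", k, lq,
                            replicates = 4, n_points = 300, seed = 77)
  expect_identical(a$sf, b$sf)
})
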