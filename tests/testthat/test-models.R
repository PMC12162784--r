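test_that("energy densities vanish in the reference configuration", {
  for (p in all_model_params()) {
    for (th in c(0, pi / 2)) {
      expect_equal(energy(p, 0, theta = th), 0,
                   tolerance = 1e-12, label = p$model)
    }
  }
})

test_that("energy matches direct evaluation for the Yeoh reference set", {
  x <- (1.5^2 + 2 / 1.5) - 3
  expect_equal(energy(table1_yeoh(), 0.5),
               3.54 * x + 38.21 * x^2 - 14.6 * x^3)
})

test_that("analytic nominal stresses reproduce hand-derived values", {
  expect_equal(nominal_stress_model(neo_hookean(1), 0.5),
               2 * (1.5 - 1.5^-2))
  expect_equal(nominal_stress_model(ogden(4.3, 8), 0.2),
               4.3 * (1.2^7 - 1.2^-5))
  fm <- fiber_model(yeoh(1e-12, 0, 0, allow_nonphysical = TRUE),
                    e_f = 10, phi = 0.5, k = 1, e_f_unit = "kPa")
  expect_equal(nominal_stress_model(fm, 0.2, theta = 0),
               0.5 * 5 * exp(0.44) * 2.4, tolerance = 1e-9)
})

test_that("stress-free reference holds for all models except the fiber term", {
  for (nm in c("neo_hookean", "yeoh", "ogden", "goh")) {
    p <- all_model_params()[[nm]]
    expect_equal(nominal_stress_model(p, 0, theta = 0), 0,
                 tolerance = 1e-10, label = nm)
  }
  # fiber model as defined: d/dlambda exp(k(I4-1)) is k at lambda = 1, so a
  # residual stress remains at zero strain for theta < pi/2
  fib <- all_model_params()$fiber
  expect_gt(nominal_stress_model(fib, 0, theta = 0), 0)
  # ... but not across the fibers, where the term is dead
  expect_equal(nominal_stress_model(fib, 0, theta = pi / 2), 0,
               tolerance = 1e-10)
})

test_that("analytic stress agrees with the finite-difference oracle", {
  lam <- seq(1.01, 1.5, length.out = 50)
  for (p in all_model_params()) {
    for (th in c(0, pi / 2)) {
      a <- nominal_stress_model(p, lam - 1, theta = th)
      f <- finite_difference_stress(p, lam - 1, theta = th)
      rel <- abs(a - f) / pmax(abs(f), 1e-8)
      expect_lt(max(rel), 1e-6)
    }
  }
})

test_that("finite-difference oracle validates its step and the reference", {
  expect_error(finite_difference_stress(neo_hookean(1), 0.2, h = 0.01),
               class = "fibrelast_domain_error")
  expect_lt(abs(finite_difference_stress(table1_yeoh(), 0)), 1e-6)
})

test_that("model reduction identities hold", {
  lam <- seq(1, 1.5, by = 0.05)
  eps <- lam - 1
  # Yeoh with C2 = C3 = 0 is Neo-Hookean
  expect_equal(nominal_stress_model(yeoh(5), eps),
               nominal_stress_model(neo_hookean(5), eps))
  # fiber with phi = 0 is the plain matrix
  f0 <- fiber_model(table1_yeoh(), e_f = 100, phi = 0, k = 3,
                    e_f_unit = "kPa")
  expect_equal(nominal_stress_model(f0, eps, theta = 0),
               nominal_stress_model(table1_yeoh(), eps))
  expect_equal(energy(f0, eps, theta = 0), energy(table1_yeoh(), eps))
  # across the fibers the fiber term dies: composite = (1 - phi) * matrix
  f <- desk_fiber(phi = 0.2)
  expect_equal(nominal_stress_model(f, eps, theta = pi / 2),
               0.8 * nominal_stress_model(table1_yeoh(), eps))
  # GOH with k1 -> 0 is Neo-Hookean with C1 = C_iso
  g0 <- goh(6.91, 1e-14, 0.9, 0.3, allow_nonphysical = TRUE)
  expect_equal(nominal_stress_model(g0, eps, theta = 0),
               nominal_stress_model(neo_hookean(6.91), eps),
               tolerance = 1e-10)
})

test_that("Neo-Hookean and single-term Ogden stresses increase with stretch", {
  eps <- seq(0, 1, by = 0.02)
  expect_true(all(diff(nominal_stress_model(neo_hookean(3), eps)) > 0))
  expect_true(all(diff(nominal_stress_model(ogden(4.3, 8), eps)) > 0))
})

test_that("integrating the stress recovers the energy", {
  for (p in all_model_params()) {
    for (th in c(0, pi / 2)) {
      w_num <- stats::integrate(
        function(l) nominal_stress_model(p, l - 1, theta = th),
        lower = 1, upper = 1.4, rel.tol = 1e-10)$value
      w <- energy(p, 0.4, theta = th)
      expect_equal(w_num, w, tolerance = 1e-6, label = p$model)
    }
  }
})

test_that("printed-variant GOH is not stress-free at the reference", {
  gp <- goh(6.91, 184, 0.9, 0.3, variant = "as_printed")
  expect_gt(abs(nominal_stress_model(gp, 0, theta = 0)), 0)
  expect_gt(energy(gp, 0, theta = 0), 0)
  # and still matches its own finite-difference derivative
  lam <- seq(1.01, 1.5, length.out = 20)
  a <- nominal_stress_model(gp, lam - 1, theta = 0)
  f <- finite_difference_stress(gp, lam - 1, theta = 0)
  expect_lt(max(abs(a - f) / pmax(abs(f), 1e-8)), 1e-6)
})

test_that("tension-only GOH drops the fiber term under fiber shortening", {
  g <- goh(6.91, 184, 0.9, 0, tension_only = TRUE)
  # circumferential loading shortens axial fibers: I4 < 1 -> isotropic only
  eps <- seq(0.05, 0.5, by = 0.05)
  expect_equal(nominal_stress_model(g, eps, theta = pi / 2),
               nominal_stress_model(neo_hookean(6.91), eps))
  # along the fibers the term stays active
  expect_gt(nominal_stress_model(g, 0.3, theta = 0),
            nominal_stress_model(neo_hookean(6.91), 0.3))
})

test_that("parameter validation names the violated constraint", {
  expect_error(neo_hookean(-1), class = "fibrelast_validation_error")
  expect_error(goh(1, 10, 1, 0.5), "kappa",
               class = "fibrelast_validation_error")
  expect_error(ogden(c(1, 1), 2), class = "fibrelast_validation_error")
  expect_error(fiber_model(table1_yeoh(), 230, 1.5, 2),
               class = "fibrelast_validation_error")
  # the escape hatch admits exploratory sets
  expect_s3_class(goh(1, 10, 1, 0.5, allow_nonphysical = TRUE),
                  "fibrelast_goh")
  expect_error(energy(list(), 0.1), class = "fibrelast_validation_error")
})

test_that("fiber modulus unit conversion stores kPa internally", {
  f_mpa <- fiber_model(table1_yeoh(), e_f = 230, phi = 0.2, k = 2.02,
                       e_f_unit = "MPa")
  f_kpa <- fiber_model(table1_yeoh(), e_f = 230000, phi = 0.2, k = 2.02,
                       e_f_unit = "kPa")
  expect_equal(f_mpa$e_f_kpa, 230000)
  expect_equal(nominal_stress_model(f_mpa, 0.3, theta = 0),
               nominal_stress_model(f_kpa, 0.3, theta = 0))
})
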