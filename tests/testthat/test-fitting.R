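test_that("percent RMSE follows its definition and normalisers", {
  obs <- c(1, 2, 3, 4)
  expect_equal(rmse_percent(obs, obs), 0)
  expect_equal(rmse_percent(c(1, 1), c(2, 2)), 50)
  expect_equal(rmse_percent(c(0, 2), c(1, 1)), 100)
  expect_equal(rmse_percent(c(2, 4), c(1, 3), normalization = "range"), 50)
  expect_equal(rmse_percent(c(2, 4), c(1, 3), normalization = "max"),
               100 * 1 / 3)
})

test_that("percent RMSE is scale-invariant under joint rescaling", {
  set.seed(42)
  obs <- runif(20, 1, 10)
  pred <- obs + rnorm(20, 0, 0.5)
  for (norm in c("mean_abs", "range", "max")) {
    expect_equal(rmse_percent(pred, obs, normalization = norm),
                 rmse_percent(1e3 * pred, 1e3 * obs, normalization = norm))
  }
})

test_that("percent RMSE rejects degenerate inputs", {
  expect_error(rmse_percent(1, c(1, 2)), class = "fibrelast_domain_error")
  expect_error(rmse_percent(c(1, 2), c(0, 0)),
               class = "fibrelast_domain_error")
})

test_that("pooling averages specimens on a common grid", {
  p <- table1_yeoh()
  base <- clean_curves(p, n = 1)
  shifted <- dplyr::mutate(base, specimen_id = paste0(specimen_id, "b"),
                           stress_kpa = stress_kpa + 2)
  pooled <- pool_curves(dplyr::bind_rows(base, shifted),
                        strain_grid = seq(0, 0.5, by = 0.05))
  expect_true(all(pooled$n_specimens == 2))
  direct <- nominal_stress_model(p, pooled$strain[
    pooled$orientation == "circumferential"])
  expect_equal(pooled$stress_kpa[pooled$orientation == "circumferential"],
               direct + 1, tolerance = 1e-6)
})

test_that("matrix stage recovers generating Yeoh constants from clean data", {
  curves <- clean_curves(table1_yeoh(), n = 1)
  fit <- fit_matrix_stage(curves, seed = 1)
  expect_true(attr(fit, "converged"))
  rel <- abs(c(fit$c1 - 3.54, fit$c2 - 38.21, fit$c3 + 14.6)) /
    c(3.54, 38.21, 14.6)
  expect_lt(max(rel), 1e-3)
  # objective at optimum no worse than at truth (clean data -> ~0)
  expect_lte(attr(fit, "objective_value"), 1e-6)
})

test_that("matrix stage recovers a nested Neo-Hookean as Yeoh with C2=C3=0", {
  curves <- clean_curves(neo_hookean(5), n = 1)
  fit <- fit_matrix_stage(curves, seed = 1)
  expect_equal(fit$c1, 5, tolerance = 1e-3)
  expect_lt(abs(fit$c2), 1e-3)
  expect_lt(abs(fit$c3), 1e-3)
})

test_that("matrix stage demands circumferential data", {
  longi <- dplyr::filter(clean_curves(table1_yeoh()),
                         orientation == "longitudinal")
  expect_error(fit_matrix_stage(longi),
               class = "fibrelast_validation_error")
  expect_error(fit_matrix_stage(tibble::tibble()),
               class = "fibrelast_validation_error")
})

test_that("fiber stage recovers the stiffening exponent with frozen matrix", {
  curves <- clean_curves(desk_fiber(e_f_kpa = 100, phi = 0.2, k = 3))
  fit <- fit_fiber_stage(curves, table1_yeoh(), e_f_kpa = 100, phi = 0.2,
                         seed = 1)
  expect_lt(abs(fit$k - 3) / 3, 1e-2)
  expect_true(attr(fit, "converged"))
  expect_true(attr(fit, "identifiable"))
  # frozen constants pass through untouched
  expect_equal(fit$matrix$c1, 3.54)
  expect_equal(fit$e_f_kpa, 100)
})

test_that("a dead fiber term yields a flat-objective warning, not an estimate", {
  f0 <- fiber_model(table1_yeoh(), e_f = 100, phi = 0, k = 3,
                    e_f_unit = "kPa")
  curves <- clean_curves(f0)
  expect_warning(
    fit <- fit_fiber_stage(curves, table1_yeoh(), e_f_kpa = 100, phi = 0,
                           seed = 1, n_starts = 2),
    class = "fibrelast_flat_objective")
  expect_false(attr(fit, "identifiable"))
  # prediction equals the matrix prediction regardless of k
  eps <- seq(0, 0.5, by = 0.1)
  expect_equal(nominal_stress_model(fit, eps, theta = 0),
               nominal_stress_model(table1_yeoh(), eps))
})

test_that("bounds excluding the truth are reported as a boundary hit", {
  curves <- clean_curves(desk_fiber(k = 3))
  fit <- fit_fiber_stage(curves, table1_yeoh(), e_f_kpa = 100, phi = 0.2,
                         bounds = list(k = c(0.5, 2)), seed = 1,
                         n_starts = 2)
  expect_true(attr(fit, "converged"))
  expect_true(attr(fit, "boundary_hit"))
  expect_equal(fit$k, 2, tolerance = 1e-6)
})

test_that("single-set fiber fit reproduces its own synthetic data", {
  curves <- clean_curves(desk_fiber(), n = 1)
  fit <- fit_single_set("fiber", curves, fixed = list(phi = 0.2), seed = 1)
  expect_lt(fit$rmse_circ, 0.5)
  expect_lt(fit$rmse_long, 0.5)
})

test_that("an isotropic single set cannot match anisotropic data", {
  curves <- clean_curves(calibrate_emulation(), n = 1)
  fit_nh <- fit_single_set("neo_hookean", curves, seed = 1, n_starts = 4)
  fit_fib <- fit_single_set("fiber", curves, fixed = list(phi = 0.2),
                            seed = 1, n_starts = 4)
  expect_gt(fit_nh$rmse_long, fit_fib$rmse_long)
})

test_that("fitting is deterministic under a fixed seed", {
  curves <- clean_curves(table1_yeoh(), n = 1)
  f1 <- fit_single_set("yeoh", curves, seed = 7, n_starts = 3)
  f2 <- fit_single_set("yeoh", curves, seed = 7, n_starts = 3)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(glance(f1), glance(f2))
})

test_that("unknown model names list the supported families", {
  curves <- clean_curves(table1_yeoh(), n = 1)
  expect_error(fit_single_set("mooney", curves), "Supported models",
               class = "fibrelast_validation_error")
})

test_that("noisy Yeoh refits recover median constants within 10 percent", {
  truth <- table1_yeoh()
  grid <- seq(0, 0.5, by = 0.01)
  ests <- purrr::map_dfr(1:20, function(i) {
    spec <- synthetic_spec(truth, strain_grid = grid,
                           noise = "gaussian_additive", sigma_frac = 0.02,
                           n_specimens = 2, seed = 100 + i)
    fit <- fit_matrix_stage(generate_curves(spec), seed = 1, n_starts = 2)
    tibble::tibble(c1 = fit$c1, c2 = fit$c2, c3 = fit$c3)
  })
  med <- vapply(ests, stats::median, numeric(1))
  rel <- abs(med - c(3.54, 38.21, -14.6)) / c(3.54, 38.21, 14.6)
  expect_lt(max(rel), 0.10)
})

test_that("model comparison ranks and survives per-model failures", {
  curves <- clean_curves(table1_yeoh(), n = 1)
  cmp <- compare_models(curves, models = "yeoh", seed = 1, n_starts = 2)
  expect_equal(cmp$report$model[1], "yeoh")
  expect_lt(cmp$report$rmse_long_pct[1], 0.5)
  # a bogus model fails without aborting the others
  cmp2 <- compare_models(curves, models = c("nope", "yeoh"), seed = 1,
                         n_starts = 2)
  expect_true(cmp2$report$failed[cmp2$report$model == "nope"])
  expect_false(cmp2$report$failed[cmp2$report$model == "yeoh"])
  expect_error(compare_models(curves, models = character(0)),
               class = "fibrelast_validation_error")
})

test_that("tidy and glance expose parameters and fit metrics", {
  curves <- clean_curves(table1_yeoh(), n = 1)
  fit <- fit_single_set("yeoh", curves, seed = 1, n_starts = 2)
  td <- tidy(fit)
  expect_setequal(td$term, c("c1", "c2", "c3"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("rmse_circ_pct", "rmse_long_pct", "converged", "seed")
                  %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
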