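#' Settings for the synthetic tensile-curve generator
#'
#' Describes a simulated uniaxial tensile study: the ground-truth
#' constitutive model, the strain grid, the per-point noise model, and the
#' number of specimens per orientation. The generator exists so that every
#' stage of the calibration pipeline (pooling, two-stage fitting, model
#' comparison) can be exercised and validated against known ground truth.
#'
#' @param params Ground-truth parameter object (any [model_params] family).
#' @param strain_grid Nondecreasing grid within `[0, 0.6]` (tensile records
#'   beyond 0.6 strain are unreliable because the cross-section can no longer
#'   be tracked; the default working range is `[0, 0.5]`).
#' @param noise `"none"`, `"gaussian_additive"` (sd = `sigma_frac` of the
#'   maximum noise-free stress across both orientations) or
#'   `"gaussian_multiplicative"` (sd of the multiplicative factor =
#'   `sigma_frac`).
#' @param sigma_frac Noise scale as a fraction; default 0.02.
#' @param n_specimens Specimens per orientation.
#' @param seed Integer seed; mandatory whenever `noise != "none"`.
#' @return A `fibrelast_synthetic_spec` list.
#' @export
synthetic_spec <- function(params,
                           strain_grid = seq(0, 0.5, by = 0.01),
                           noise = c("none", "gaussian_additive",
                                     "gaussian_multiplicative"),
                           sigma_frac = 0.02,
                           n_specimens = 2,
                           seed = NULL) {
  noise <- match.arg(noise)
  if (!inherits(params, "fibrelast_params")) {
    rlang::abort("`params` must be a fibrelast parameter object.",
                 class = "fibrelast_validation_error")
  }
  if (is.unsorted(strain_grid) || any(strain_grid < 0) ||
      any(strain_grid > 0.6)) {
    rlang::abort("`strain_grid` must be nondecreasing within [0, 0.6].",
                 class = "fibrelast_validation_error")
  }
  if (sigma_frac < 0) {
    rlang::abort("`sigma_frac` must be >= 0.",
                 class = "fibrelast_validation_error")
  }
  if (noise != "none" && is.null(seed)) {
    rlang::abort("`seed` is mandatory when noise is applied.",
                 class = "fibrelast_validation_error")
  }
  structure(list(params = params, strain_grid = strain_grid, noise = noise,
                 sigma_frac = sigma_frac, n_specimens = n_specimens,
                 seed = seed),
            class = "fibrelast_synthetic_spec")
}

#' Generate synthetic tensile curves
#'
#' Evaluates the ground-truth model on the spec's strain grid for both
#' orientations (fiber angle `pi/2` circumferential, `0` longitudinal) and
#' adds per-point noise independently for each specimen. Deterministic under
#' a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A tidy curve tibble (`specimen_id`, `orientation`, `strain`,
#'   `stress_kpa`).
#' @export
generate_curves <- function(spec) {
  if (!inherits(spec, "fibrelast_synthetic_spec")) {
    rlang::abort("`spec` must come from synthetic_spec().",
                 class = "fibrelast_validation_error")
  }
  clean <- predict_curve(spec$params, strain = spec$strain_grid)
  max_stress <- max(abs(clean$stress_kpa))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  purrr::map_dfr(seq_len(spec$n_specimens), function(i) {
    clean |>
      dplyr::group_by(.data$orientation) |>
      dplyr::mutate(
        specimen_id = paste0(substr(.data$orientation, 1, 4), "_", i),
        stress_kpa = apply_noise(.data$stress_kpa, spec$noise,
                                 spec$sigma_frac, max_stress)
      ) |>
      dplyr::ungroup()
  }) |>
    dplyr::select("specimen_id", "orientation", "strain", "stress_kpa") |>
    dplyr::arrange(.data$specimen_id, .data$strain)
}

apply_noise <- function(stress, noise, sigma_frac, max_stress) {
  switch(noise,
    none = stress,
    gaussian_additive =
      stress + stats::rnorm(length(stress), 0, sigma_frac * max_stress),
    gaussian_multiplicative =
      stress * (1 + stats::rnorm(length(stress), 0, sigma_frac))
  )
}

#' Calibrate the generator to anisotropic tissue-scale anchors
#'
#' Builds a fiber-matrix parameter set whose predicted mean curves pass
#' through prescribed stress anchors, by default the tissue-scale behaviour
#' of distal urethral tissue: a circumferential mean stress of 33.01 kPa at
#' 0.5 strain, a longitudinal mean stress of 59.4 kPa at 0.5 strain, and
#' longitudinal stiffening setting in near 0.25 strain so the two
#' orientations share a similar initial slope.
#'
#' The matrix keeps a fixed Yeoh shape (the `C2/C1`, `C3/C1` ratios of
#' `matrix_shape`) and is scaled so the composite circumferential prediction
#' `(1 - phi) * sigma_yeoh` passes through the circumferential anchors in the
#' least-squares sense. The fiber stage holds `phi` and the stiffening
#' exponent `k` fixed (the value of `k` sets the stiffening onset) and solves
#' the fiber modulus from the longitudinal anchors: with one anchor the
#' solution is closed-form; with several it is the least-squares amplitude,
#' since the longitudinal fiber contribution is linear in `E_f`.
#'
#' The calibrated modulus is a curve-scale effective value in kPa, not a
#' collagen fiber modulus: its job is to give the generated curves the
#' anisotropic structure of the tissue, at tissue stress scale.
#'
#' @param targets Data frame with columns `orientation`, `strain`,
#'   `stress_kpa`; default the two anchors above.
#' @param phi Fiber volume fraction (default 0.2).
#' @param k Fiber stiffening exponent (default 3, placing the onset of
#'   longitudinal stiffening near 0.25 strain).
#' @param matrix_shape A [yeoh()] object fixing the matrix curve shape.
#' @param tolerance Maximum admissible relative miss at any anchor
#'   (default 0.02); exceeding it raises an infeasibility error.
#' @return A [fiber_model()] parameter object (with `e_f_unit = "kPa"`).
#' @export
calibrate_emulation <- function(targets = default_emulation_targets(),
                                phi = 0.2, k = 3,
                                matrix_shape = yeoh(3.54, 38.21, -14.6,
                                                    allow_nonphysical = TRUE),
                                tolerance = 0.02) {
  needed <- c("orientation", "strain", "stress_kpa")
  if (!all(needed %in% names(targets)) || nrow(targets) == 0) {
    rlang::abort("`targets` needs columns orientation, strain, stress_kpa.",
                 class = "fibrelast_validation_error")
  }
  circ <- dplyr::filter(targets, .data$orientation == "circumferential")
  longi <- dplyr::filter(targets, .data$orientation == "longitudinal")
  if (nrow(circ) == 0) {
    rlang::abort("At least one circumferential anchor is required.",
                 class = "fibrelast_validation_error")
  }

  # Matrix scale: composite circ prediction is (1 - phi) * s * sigma_shape,
  # linear in the scale s -> least-squares amplitude.
  shape_circ <- nominal_stress_model(matrix_shape, circ$strain)
  s <- sum(shape_circ * circ$stress_kpa) / ((1 - phi) * sum(shape_circ^2))
  matrix_cal <- yeoh(s * matrix_shape$c1, s * matrix_shape$c2,
                     s * matrix_shape$c3, allow_nonphysical = TRUE)

  if (nrow(longi) == 0) {
    # Single-orientation calibration: matrix only, fiber constants default.
    out <- fiber_model(matrix_cal, e_f = 1, phi = phi, k = k,
                       e_f_unit = "kPa", allow_nonphysical = TRUE)
    return(check_emulation(out, circ, tolerance))
  }

  # Fiber amplitude: longitudinal excess over the matrix contribution is
  # linear in E_f -> least-squares solution.
  lambda_l <- 1 + longi$strain
  matrix_long <- (1 - phi) * nominal_stress_model(matrix_cal, longi$strain)
  fiber_unit <- phi / 2 * k * exp(k * (lambda_l^2 - 1)) * 2 * lambda_l
  excess <- longi$stress_kpa - matrix_long
  e_f <- sum(fiber_unit * excess) / sum(fiber_unit^2)
  if (e_f <= 0) {
    rlang::abort(paste0(
      "Infeasible longitudinal anchors: the matrix already exceeds the ",
      "longitudinal targets, no positive fiber modulus fits."),
      class = "fibrelast_infeasible_error")
  }
  out <- fiber_model(matrix_cal, e_f = e_f, phi = phi, k = k,
                     e_f_unit = "kPa", allow_nonphysical = TRUE)
  check_emulation(out, targets, tolerance)
}

check_emulation <- function(params, targets, tolerance) {
  pred <- purrr::map2_dbl(targets$strain, targets$orientation, function(eps, ori) {
    nominal_stress_model(params, eps, theta = orientation_theta(ori))
  })
  rel <- abs(pred - targets$stress_kpa) / abs(targets$stress_kpa)
  if (any(rel > tolerance)) {
    worst <- which.max(rel)
    rlang::abort(paste0(
      "Emulation infeasible at tolerance ", tolerance, ": ",
      targets$orientation[worst], " anchor at strain ",
      targets$strain[worst], " missed by ",
      signif(100 * rel[worst], 3), "%."),
      class = "fibrelast_infeasible_error")
  }
  params
}

#' Default emulation anchors for distal urethral tissue
#'
#' Circumferential 33.01 kPa and longitudinal 59.4 kPa, both at 0.5 nominal
#' strain — the reported endpoint stresses of porcine distal urethral mean
#' curves.
#'
#' @return A tibble with columns `orientation`, `strain`, `stress_kpa`.
#' @export
default_emulation_targets <- function() {
  tibble::tibble(
    orientation = c("circumferential", "longitudinal"),
    strain = c(0.5, 0.5),
    stress_kpa = c(33.01, 59.4)
  )
}
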