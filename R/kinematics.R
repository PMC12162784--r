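#' Nominal (engineering) strain from current and reference length
#'
#' Strain is computed as `(L - L0) / L0`, dimensionless, the standard
#' grip-to-grip measure for uniaxial tensile tests.
#'
#' @param length_l Current specimen length (mm). Vectorised.
#' @param length_l0 Initial (reference) length (mm), must be positive.
#' @return Dimensionless nominal strain, same length as `length_l`.
#' @examples
#' nominal_strain(45, 30)   # 0.5
#' @export
nominal_strain <- function(length_l, length_l0) {
  if (any(length_l0 <= 0)) {
    rlang::abort("`length_l0` must be positive.", class = "fibrelast_domain_error")
  }
  if (any(length_l < 0)) {
    rlang::abort("`length_l` must be non-negative.", class = "fibrelast_domain_error")
  }
  (length_l - length_l0) / length_l0
}

#' Nominal (engineering) stress from force and reference cross-section
#'
#' Force over initial cross-sectional area. With force in N and area in
#' mm^2 the ratio is in MPa; the result is returned in kPa, the working
#' stress unit of the package.
#'
#' @param force_n Applied force (N). Vectorised.
#' @param area_a0 Initial cross-sectional area (mm^2), must be positive.
#' @return Nominal stress in kPa.
#' @examples
#' nominal_stress(0.264, 8)  # 33 kPa
#' @export
nominal_stress <- function(force_n, area_a0) {
  if (any(area_a0 <= 0)) {
    rlang::abort("`area_a0` must be positive.", class = "fibrelast_domain_error")
  }
  1000 * force_n / area_a0
}

#' Nominal strain rate of a displacement-controlled test
#'
#' @param speed Crosshead speed (mm/s), positive.
#' @param length_l0 Initial length (mm), positive.
#' @return Strain rate in 1/s.
#' @examples
#' strain_rate(0.83, 30)  # ~0.028 1/s
#' @export
strain_rate <- function(speed, length_l0) {
  if (any(speed <= 0) || any(length_l0 <= 0)) {
    rlang::abort("`speed` and `length_l0` must be positive.",
                 class = "fibrelast_domain_error")
  }
  speed / length_l0
}

#' Specimen geometry record
#'
#' One row per specimen with the reference dimensions used to convert raw
#' force/displacement records to nominal stress/strain. The aspect ratio
#' (initial length over width) is the usual screen for grip end effects.
#'
#' @param initial_length_l0 Grip-to-grip initial length (mm).
#' @param width Specimen width (mm).
#' @param thickness Specimen thickness (mm).
#' @return A one-row tibble with columns `initial_length_l0`, `width`,
#'   `thickness`, `cross_section_a0` (mm^2) and `aspect_ratio`.
#' @examples
#' specimen_geometry(30, 8, 1)
#' @export
specimen_geometry <- function(initial_length_l0, width, thickness) {
  vals <- c(initial_length_l0 = initial_length_l0, width = width,
            thickness = thickness)
  if (any(vals <= 0)) {
    bad <- names(vals)[vals <= 0]
    rlang::abort(paste0("Geometry fields must be positive: ",
                        paste(bad, collapse = ", ")),
                 class = "fibrelast_domain_error")
  }
  tibble::tibble(
    initial_length_l0 = initial_length_l0,
    width = width,
    thickness = thickness,
    cross_section_a0 = width * thickness,
    aspect_ratio = initial_length_l0 / width
  )
}

#' Incompressible uniaxial deformation state
#'
#' Maps nominal strain to the kinematic quantities every constitutive model
#' consumes: the loading-direction stretch `lambda = 1 + strain`, the lateral
#' stretches `lambda^(-1/2)` implied by incompressibility (det F = 1), the
#' first invariant `I1 = lambda^2 + 2/lambda`, and the fourth pseudo-invariant
#' `I4`, the squared stretch along a fiber direction at angle `theta` from the
#' loading axis.
#'
#' With `i4_mode = "fiber_vector"` (default) the fiber direction is treated as
#' a unit vector at angle `theta` in the loading plane, giving
#' `I4 = lambda^2 cos^2(theta) + lambda^(-1) sin^2(theta)` (the A.C.A
#' contraction). `i4_mode = "loading_axis"` ignores the angle in the invariant
#' and uses `I4 = lambda^2`; the two agree at `theta = 0`.
#'
#' @param strain_eps Nominal strain, must be > -1. Vectorised.
#' @param theta Fiber angle from the loading axis, radians in `[0, pi/2]`.
#' @param i4_mode `"fiber_vector"` or `"loading_axis"`.
#' @return A tibble with columns `strain`, `stretch_lambda`,
#'   `lateral_stretch`, `i1`, `i4`, `fiber_angle_theta`.
#' @examples
#' uniaxial_state(0.5, theta = 0)        # lambda 1.5, I4 = 2.25
#' uniaxial_state(0.5, theta = pi / 2)   # I4 = 1/1.5
#' @export
uniaxial_state <- function(strain_eps, theta = 0,
                           i4_mode = c("fiber_vector", "loading_axis")) {
  i4_mode <- match.arg(i4_mode)
  if (any(strain_eps <= -1)) {
    rlang::abort("`strain_eps` must be > -1 (stretch must stay positive).",
                 class = "fibrelast_domain_error")
  }
  if (any(theta < 0) || any(theta > pi / 2 + 1e-12)) {
    rlang::abort("`theta` must lie in [0, pi/2].",
                 class = "fibrelast_domain_error")
  }
  lambda <- 1 + strain_eps
  i4 <- switch(i4_mode,
    fiber_vector = lambda^2 * cos(theta)^2 + sin(theta)^2 / lambda,
    loading_axis = lambda^2 + 0 * theta
  )
  tibble::tibble(
    strain = strain_eps,
    stretch_lambda = lambda,
    lateral_stretch = lambda^(-1 / 2),
    i1 = lambda^2 + 2 / lambda,
    i4 = i4,
    fiber_angle_theta = theta + 0 * lambda
  )
}

#' Convert raw force/displacement records to a tensile curve
#'
#' Takes a raw machine export (`time_s`, `displacement_mm`, `force_n`) and a
#' specimen geometry and returns the curve in nominal strain / nominal stress
#' form, ready for fitting.
#'
#' @param raw A data frame with columns `time_s`, `displacement_mm`, `force_n`.
#' @param geometry A one-row tibble from [specimen_geometry()].
#' @param specimen_id Specimen label stored with the curve.
#' @param orientation `"circumferential"` or `"longitudinal"`.
#' @return A tidy curve tibble with columns `specimen_id`, `orientation`,
#'   `strain`, `stress_kpa`.
#' @export
raw_to_curve <- function(raw, geometry, specimen_id,
                         orientation = c("circumferential", "longitudinal")) {
  orientation <- match.arg(orientation)
  needed <- c("time_s", "displacement_mm", "force_n")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Raw record is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "fibrelast_parse_error")
  }
  l0 <- geometry$initial_length_l0
  tibble::tibble(
    specimen_id = specimen_id,
    orientation = orientation,
    strain = nominal_strain(l0 + raw$displacement_mm, l0),
    stress_kpa = nominal_stress(raw$force_n, geometry$cross_section_a0)
  ) |>
    dplyr::arrange(.data$strain)
}
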