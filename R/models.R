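#' Constitutive model parameter constructors
#'
#' Each constructor validates its material constants and returns a classed
#' list consumed by [energy()], [nominal_stress_model()] and the fitting
#' functions. All stress-like constants are in kPa. Validation is strict by
#' default; `allow_nonphysical = TRUE` disables the sign checks so that
#' exploratory or literature parameter sets can still be evaluated.
#'
#' @param c1,c2,c3 Yeoh / Neo-Hookean constants (kPa). `c2`, `c3` may be
#'   negative (soft tissues commonly fit with `c3 < 0`); `c1` must be
#'   positive unless `allow_nonphysical`.
#' @param allow_nonphysical Skip sign/range validation.
#' @return An object of class `fibrelast_params` (subclassed per family).
#' @name model_params
NULL

new_params <- function(model, fields) {
  structure(c(list(model = model), fields),
            class = c(paste0("fibrelast_", model), "fibrelast_params"))
}

check_params <- function(ok, msg) {
  if (!ok) {
    rlang::abort(paste0("Invalid parameters: ", msg),
                 class = "fibrelast_validation_error")
  }
}

#' @rdname model_params
#' @export
neo_hookean <- function(c1, allow_nonphysical = FALSE) {
  if (!allow_nonphysical) check_params(c1 > 0, "c1 must be > 0 (kPa)")
  new_params("neo_hookean", list(c1 = c1))
}

#' @rdname model_params
#' @export
yeoh <- function(c1, c2 = 0, c3 = 0, allow_nonphysical = FALSE) {
  if (!allow_nonphysical) check_params(c1 > 0, "c1 must be > 0 (kPa)")
  new_params("yeoh", list(c1 = c1, c2 = c2, c3 = c3))
}

#' @rdname model_params
#' @param mu,alpha Ogden shear-like constants (kPa) and exponents; equal
#'   lengths give the number of terms. The ground-state shear modulus
#'   `sum(mu * alpha) / 2` must be positive.
#' @export
ogden <- function(mu, alpha, allow_nonphysical = FALSE) {
  check_params(length(mu) == length(alpha) && length(mu) >= 1,
               "mu and alpha must be equal-length, length >= 1")
  if (!allow_nonphysical) {
    check_params(sum(mu * alpha) > 0,
                 "sum(mu * alpha) must be > 0 (positive ground-state modulus)")
  }
  new_params("ogden", list(mu = mu, alpha = alpha))
}

#' @rdname model_params
#' @param c_iso Isotropic (Neo-Hookean) ground-matrix constant (kPa).
#' @param k1 Fiber stress-like constant (kPa), positive.
#' @param k2 Fiber exponential constant (dimensionless), positive.
#' @param kappa Fiber dispersion in `[0, 1/3]` (0 = perfectly aligned,
#'   1/3 = isotropic dispersion).
#' @param variant `"standard"` uses the Gasser-Ogden-Holzapfel fiber argument
#'   `E = kappa (I1 - 3) + (1 - 3 kappa)(I4 - 1)`, which is stress-free at the
#'   reference configuration. `"as_printed"` subtracts an extra 1 inside the
#'   squared bracket, reproducing a variant that appears in some texts but is
#'   not stress-free at zero strain; it is kept for audit purposes only.
#' @param tension_only If `TRUE` the anisotropic term is switched off when the
#'   fibers are shortened (`I4 < 1`). Default `FALSE` (term always active).
#' @export
goh <- function(c_iso, k1, k2, kappa, theta = 0,
                variant = c("standard", "as_printed"),
                tension_only = FALSE, allow_nonphysical = FALSE) {
  variant <- match.arg(variant)
  if (!allow_nonphysical) {
    check_params(c_iso > 0, "c_iso must be > 0 (kPa)")
    check_params(k1 > 0, "k1 must be > 0 (kPa)")
    check_params(k2 > 0, "k2 must be > 0")
    check_params(kappa >= 0 && kappa <= 1 / 3, "kappa must lie in [0, 1/3]")
  }
  check_params(theta >= 0 && theta <= pi / 2, "theta must lie in [0, pi/2]")
  new_params("goh", list(c_iso = c_iso, k1 = k1, k2 = k2, kappa = kappa,
                         theta = theta, variant = variant,
                         tension_only = tension_only))
}

#' @rdname model_params
#' @param matrix A [yeoh()] parameter object for the ground matrix.
#' @param e_f Fiber modulus; interpreted in the unit given by `e_f_unit` and
#'   stored internally in kPa. Literature values for type I collagen are of
#'   order 230 MPa.
#' @param phi Fiber volume fraction in `[0, 1]`.
#' @param k Exponential fiber-stiffening constant, positive.
#' @param theta Default fiber angle from the loading axis (radians in
#'   `[0, pi/2]`); 0 for longitudinal loading along the fibers, pi/2 for
#'   circumferential loading across them. Overridable at evaluation time.
#' @param e_f_unit `"MPa"` (default, the unit moduli are usually quoted in)
#'   or `"kPa"`.
#' @export
fiber_model <- function(matrix, e_f, phi, k, theta = 0,
                        e_f_unit = c("MPa", "kPa"),
                        allow_nonphysical = FALSE) {
  e_f_unit <- match.arg(e_f_unit)
  check_params(inherits(matrix, "fibrelast_yeoh"),
               "matrix must be a yeoh() parameter object")
  e_f_kpa <- if (e_f_unit == "MPa") e_f * 1000 else e_f
  if (!allow_nonphysical) {
    check_params(e_f_kpa > 0, "e_f must be > 0")
    check_params(phi >= 0 && phi <= 1, "phi must lie in [0, 1]")
    check_params(k > 0, "k must be > 0")
  }
  check_params(theta >= 0 && theta <= pi / 2, "theta must lie in [0, pi/2]")
  new_params("fiber", list(matrix = matrix, e_f_kpa = e_f_kpa, phi = phi,
                           k = k, theta = theta))
}

#' @export
print.fibrelast_params <- function(x, ...) {
  cat("<", x$model, " hyperelastic parameters>\n", sep = "")
  flat <- flatten_params(x)
  for (nm in names(flat)) cat("  ", nm, " = ", format(flat[[nm]]), "\n", sep = "")
  invisible(x)
}

# Flatten a parameter object to a named numeric list (used by print,
# write_report and the JSON round-trip).
flatten_params <- function(params) {
  switch(params$model,
    neo_hookean = list(c1 = params$c1),
    yeoh = list(c1 = params$c1, c2 = params$c2, c3 = params$c3),
    ogden = {
      out <- list()
      for (i in seq_along(params$mu)) {
        out[[paste0("mu", i)]] <- params$mu[i]
        out[[paste0("alpha", i)]] <- params$alpha[i]
      }
      out
    },
    goh = list(c_iso = params$c_iso, k1 = params$k1, k2 = params$k2,
               kappa = params$kappa),
    fiber = list(c1 = params$matrix$c1, c2 = params$matrix$c2,
                 c3 = params$matrix$c3, e_f_kpa = params$e_f_kpa,
                 phi = params$phi, k = params$k)
  )
}

theta_or_default <- function(params, theta) {
  if (!is.null(theta)) return(theta)
  if (!is.null(params$theta)) return(params$theta)
  0
}

#' Strain-energy density under the uniaxial incompressible substitution
#'
#' Evaluates the strain-energy density W (kPa, i.e. kJ/m^3) of a model at the
#' given nominal strain, with the lateral stretches eliminated by
#' incompressibility. For the anisotropic models `theta` sets the fiber angle
#' relative to the loading axis.
#'
#' @param params A parameter object from one of the [model_params]
#'   constructors.
#' @param strain_eps Nominal strain (vectorised), > -1.
#' @param theta Fiber angle (radians); defaults to the angle stored in the
#'   parameter object (fiber model) or 0.
#' @return Numeric vector of energy densities (kPa).
#' @export
energy <- function(params, strain_eps, theta = NULL) {
  UseMethod("energy")
}

#' @export
energy.default <- function(params, strain_eps, theta = NULL) {
  rlang::abort("`params` must be a fibrelast parameter object.",
               class = "fibrelast_validation_error")
}

#' @export
energy.fibrelast_neo_hookean <- function(params, strain_eps, theta = NULL) {
  st <- uniaxial_state(strain_eps)
  params$c1 * (st$i1 - 3)
}

#' @export
energy.fibrelast_yeoh <- function(params, strain_eps, theta = NULL) {
  st <- uniaxial_state(strain_eps)
  x <- st$i1 - 3
  params$c1 * x + params$c2 * x^2 + params$c3 * x^3
}

#' @export
energy.fibrelast_ogden <- function(params, strain_eps, theta = NULL) {
  lambda <- 1 + strain_eps
  if (any(lambda <= 0)) {
    rlang::abort("strain must be > -1", class = "fibrelast_domain_error")
  }
  terms <- purrr::map2(params$mu, params$alpha, function(mu_n, a_n) {
    mu_n / a_n * (lambda^a_n + 2 * lambda^(-a_n / 2) - 3)
  })
  purrr::reduce(terms, `+`)
}

goh_fiber_argument <- function(params, st) {
  e <- params$kappa * (st$i1 - 3) + (1 - 3 * params$kappa) * (st$i4 - 1)
  if (params$variant == "as_printed") e <- e - 1
  e
}

#' @export
energy.fibrelast_goh <- function(params, strain_eps, theta = NULL) {
  theta <- theta_or_default(params, theta)
  st <- uniaxial_state(strain_eps, theta)
  e <- goh_fiber_argument(params, st)
  w_aniso <- params$k1 / (2 * params$k2) * (exp(params$k2 * e^2) - 1)
  if (isTRUE(params$tension_only)) w_aniso[st$i4 < 1] <- 0
  params$c_iso * (st$i1 - 3) + w_aniso
}

#' @export
energy.fibrelast_fiber <- function(params, strain_eps, theta = NULL) {
  theta <- theta_or_default(params, theta)
  st <- uniaxial_state(strain_eps, theta)
  w_matrix <- energy(params$matrix, strain_eps)
  w_fibers <- cos(theta) * params$e_f_kpa / 2 *
    (exp(params$k * (st$i4 - 1)) - 1)
  (1 - params$phi) * w_matrix + params$phi * w_fibers
}

#' Analytic nominal stress of a hyperelastic model
#'
#' The nominal (engineering) stress of an incompressible uniaxial extension
#' is the derivative of the substituted strain-energy density with respect to
#' the loading stretch, `sigma_n = dW/dlambda`. Closed forms are implemented
#' per model; [finite_difference_stress()] provides an independent numerical
#' check.
#'
#' @inheritParams energy
#' @return Numeric vector of nominal stresses (kPa).
#' @examples
#' nominal_stress_model(neo_hookean(1), 0.5)  # 2 (1.5 - 1.5^-2)
#' @export
nominal_stress_model <- function(params, strain_eps, theta = NULL) {
  UseMethod("nominal_stress_model")
}

#' @export
nominal_stress_model.default <- function(params, strain_eps, theta = NULL) {
  rlang::abort("`params` must be a fibrelast parameter object.",
               class = "fibrelast_validation_error")
}

#' @export
nominal_stress_model.fibrelast_neo_hookean <- function(params, strain_eps,
                                                       theta = NULL) {
  lambda <- 1 + strain_eps
  2 * params$c1 * (lambda - lambda^(-2))
}

#' @export
nominal_stress_model.fibrelast_yeoh <- function(params, strain_eps,
                                                theta = NULL) {
  st <- uniaxial_state(strain_eps)
  lambda <- st$stretch_lambda
  x <- st$i1 - 3
  2 * (lambda - lambda^(-2)) *
    (params$c1 + 2 * params$c2 * x + 3 * params$c3 * x^2)
}

#' @export
nominal_stress_model.fibrelast_ogden <- function(params, strain_eps,
                                                 theta = NULL) {
  lambda <- 1 + strain_eps
  terms <- purrr::map2(params$mu, params$alpha, function(mu_n, a_n) {
    mu_n * (lambda^(a_n - 1) - lambda^(-a_n / 2 - 1))
  })
  purrr::reduce(terms, `+`)
}

d_i1_d_lambda <- function(lambda) 2 * lambda - 2 * lambda^(-2)
d_i4_d_lambda <- function(lambda, theta) {
  2 * lambda * cos(theta)^2 - lambda^(-2) * sin(theta)^2
}

#' @export
nominal_stress_model.fibrelast_goh <- function(params, strain_eps,
                                               theta = NULL) {
  theta <- theta_or_default(params, theta)
  st <- uniaxial_state(strain_eps, theta)
  lambda <- st$stretch_lambda
  e <- goh_fiber_argument(params, st)
  de <- params$kappa * d_i1_d_lambda(lambda) +
    (1 - 3 * params$kappa) * d_i4_d_lambda(lambda, theta)
  s_aniso <- params$k1 * e * exp(params$k2 * e^2) * de
  if (isTRUE(params$tension_only)) s_aniso[st$i4 < 1] <- 0
  2 * params$c_iso * (lambda - lambda^(-2)) + s_aniso
}

#' @export
nominal_stress_model.fibrelast_fiber <- function(params, strain_eps,
                                                 theta = NULL) {
  theta <- theta_or_default(params, theta)
  st <- uniaxial_state(strain_eps, theta)
  lambda <- st$stretch_lambda
  s_matrix <- nominal_stress_model(params$matrix, strain_eps)
  s_fibers <- cos(theta) * params$e_f_kpa / 2 * params$k *
    exp(params$k * (st$i4 - 1)) * d_i4_d_lambda(lambda, theta)
  (1 - params$phi) * s_matrix + params$phi * s_fibers
}

#' Central finite-difference nominal stress
#'
#' Numerical derivative of the strain-energy density with respect to the
#' loading stretch, `[W(lambda + h) - W(lambda - h)] / (2h)`. Serves as the
#' independent oracle against which every analytic stress expression is
#' verified.
#'
#' @inheritParams energy
#' @param h Step size on the stretch, in `(0, 1e-3]`.
#' @return Numeric vector of nominal stresses (kPa).
#' @export
finite_difference_stress <- function(params, strain_eps, theta = NULL,
                                     h = 1e-6) {
  if (h <= 0 || h > 1e-3) {
    rlang::abort("`h` must lie in (0, 1e-3].", class = "fibrelast_domain_error")
  }
  (energy(params, strain_eps + h, theta) -
     energy(params, strain_eps - h, theta)) / (2 * h)
}

#' Predict a stress-strain curve from a parameter set
#'
#' Convenience wrapper returning a tidy curve tibble for one or both
#' orientations. Anisotropic models (GOH, fiber) are evaluated at
#' `theta = pi/2` for the circumferential orientation and `theta = 0` for the
#' longitudinal one; isotropic models give the same prediction for both.
#'
#' @param params A parameter object.
#' @param strain Strain grid (default 51 points on `[0, 0.5]`).
#' @param orientation Character vector of orientations to predict.
#' @return A tibble with `orientation`, `strain`, `stress_kpa`.
#' @export
predict_curve <- function(params, strain = seq(0, 0.5, length.out = 51),
                          orientation = c("circumferential", "longitudinal")) {
  orientation <- match.arg(orientation, several.ok = TRUE)
  purrr::map_dfr(orientation, function(ori) {
    tibble::tibble(
      orientation = ori,
      strain = strain,
      stress_kpa = nominal_stress_model(params, strain,
                                        theta = orientation_theta(ori))
    )
  })
}

# Operating fiber angle per loading orientation: fibers run longitudinally,
# so longitudinal loading is along the fibers (theta = 0) and circumferential
# loading is across them (theta = pi/2).
orientation_theta <- function(orientation) {
  ifelse(orientation == "longitudinal", 0, pi / 2)
}
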