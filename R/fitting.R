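#' Percent root-mean-square error between predicted and observed stress
#'
#' `100 * sqrt(mean((predicted - observed)^2)) / N`, where `N` normalises the
#' observed series: its mean absolute value (`"mean_abs"`, default), its range
#' (`"range"`), or its maximum absolute value (`"max"`). Mean-normalised RMSE
#' is the usual convention for monotone stress-strain curves; the alternatives
#' are provided because published percent-RMSE figures do not always state
#' the normaliser.
#'
#' @param predicted,observed Equal-length numeric vectors (kPa), length >= 2.
#' @param normalization One of `"mean_abs"`, `"range"`, `"max"`.
#' @return RMSE as a percentage (scalar).
#' @examples
#' rmse_percent(c(1, 1), c(2, 2))  # 50
#' @export
rmse_percent <- function(predicted, observed,
                         normalization = c("mean_abs", "range", "max")) {
  normalization <- match.arg(normalization)
  if (length(predicted) != length(observed) || length(observed) < 2) {
    rlang::abort("`predicted` and `observed` must be equal-length, length >= 2.",
                 class = "fibrelast_domain_error")
  }
  norm <- switch(normalization,
    mean_abs = mean(abs(observed)),
    range = diff(range(observed)),
    max = max(abs(observed))
  )
  if (norm <= 0) {
    rlang::abort(paste0("Observed series has zero ", normalization,
                        "; percent RMSE is undefined."),
                 class = "fibrelast_domain_error")
  }
  100 * sqrt(mean((predicted - observed)^2)) / norm
}

#' Pool specimen curves onto a common strain grid
#'
#' Resamples every specimen curve onto a shared strain grid by linear
#' interpolation and averages across specimens within each orientation,
#' giving the mean stress-strain curve each fit is run against. Grid points
#' outside a specimen's strain support are dropped from that specimen's
#' contribution.
#'
#' @param curves Tidy curve tibble (`specimen_id`, `orientation`, `strain`,
#'   `stress_kpa`).
#' @param strain_grid Common grid; default 51 points on `[0, 0.5]`.
#' @return A tibble with `orientation`, `strain`, `stress_kpa` (mean) and
#'   `n_specimens`.
#' @export
pool_curves <- function(curves, strain_grid = seq(0, 0.5, length.out = 51)) {
  check_curve_table(curves)
  curves |>
    dplyr::group_by(.data$orientation, .data$specimen_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        strain = strain_grid,
        stress_kpa = stats::approx(df$strain, df$stress_kpa,
                                   xout = strain_grid, rule = 1,
                                   ties = mean)$y
      )
    }) |>
    dplyr::ungroup() |>
    tidyr::drop_na("stress_kpa") |>
    dplyr::group_by(.data$orientation, .data$strain) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      stress_kpa = mean(.data$stress_kpa),
      .groups = "drop"
    ) |>
    dplyr::select("orientation", "strain", "stress_kpa", "n_specimens")
}

check_curve_table <- function(curves) {
  needed <- c("specimen_id", "orientation", "strain", "stress_kpa")
  missing_cols <- setdiff(needed, names(curves))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Curve table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "fibrelast_validation_error")
  }
  if (nrow(curves) == 0) {
    rlang::abort("Curve table is empty.", class = "fibrelast_validation_error")
  }
  bad <- setdiff(unique(curves$orientation),
                 c("circumferential", "longitudinal"))
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown orientation: ", paste(bad, collapse = ", ")),
                 class = "fibrelast_validation_error")
  }
  invisible(curves)
}

# Seeded multi-start bounded quasi-Newton minimisation. The first start is
# the caller's init; the rest are uniform draws inside the (finite) bounds.
# Exponential stiffening terms create local minima, hence the restarts.
# The optimizer works on log1p(SSR): same minimiser, but the compressed
# scale keeps the line search stable when a start lands in the steep
# exponential regime (raw SSR can exceed 1e20 there). The reported value is
# the raw SSR at the optimum.
multistart_optim <- function(objective, init, lower, upper,
                             n_starts = 8, seed = 1) {
  stopifnot(length(init) == length(lower), length(init) == length(upper))
  transformed <- function(p) log1p(objective(p))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  starts <- list(init)
  if (n_starts > 1) {
    # draw uniformly inside the bounds; fall back to a window around the
    # init where a bound is infinite
    lo <- ifelse(is.finite(lower), lower, init - 10 * (abs(init) + 1))
    hi <- ifelse(is.finite(upper), upper, init + 10 * (abs(init) + 1))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- stats::runif(length(init), lo, hi)
    }
  }
  fits <- purrr::map(starts, function(p0) {
    tryCatch(
      stats::optim(p0, transformed, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 1000, factr = 1e7)),
      error = function(e) list(value = Inf, par = p0, convergence = 99,
                               counts = c(`function` = 0, gradient = 0))
    )
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  best$value <- objective(best$par)
  best$boundary_hit <- any(
    abs(best$par - lower) < 1e-8 * (1 + abs(lower)) & is.finite(lower) |
    abs(best$par - upper) < 1e-8 * (1 + abs(upper)) & is.finite(upper)
  )
  best
}

# Default free-parameter tables: bounds and starting values per model.
# Stress-like constants in kPa. These are generic fitting defaults, not
# tissue-specific values.
default_param_table <- function(model) {
  switch(model,
    neo_hookean = tibble::tibble(
      term = "c1", init = 1, lower = 1e-6, upper = 1e3),
    yeoh = tibble::tibble(
      term = c("c1", "c2", "c3"),
      init = c(1, 1, 1),
      lower = c(1e-6, -1e3, -1e3),
      upper = c(1e3, 1e3, 1e3)),
    ogden = tibble::tibble(
      term = c("mu1", "alpha1"),
      init = c(5, 8),
      lower = c(1e-6, 1),
      upper = c(1e3, 20)),
    goh = tibble::tibble(
      term = c("c_iso", "k1", "k2", "kappa"),
      init = c(1, 100, 1, 0.3),
      lower = c(1e-6, 1e-6, 1e-6, 0),
      upper = c(1e3, 1e4, 1e2, 1 / 3)),
    fiber = tibble::tibble(
      term = c("c1", "c2", "c3", "e_f_kpa", "k"),
      init = c(1, 1, 1, 10, 2),
      lower = c(1e-6, -1e3, -1e3, 1e-6, 1e-6),
      upper = c(1e3, 1e3, 1e3, 1e4, 1e2)),
    rlang::abort(paste0("Unknown model `", model, "`. Supported models: ",
                        "neo_hookean, yeoh, ogden, goh, fiber."),
                 class = "fibrelast_validation_error")
  )
}

apply_overrides <- function(tab, bounds = NULL, init = NULL) {
  if (!is.null(init)) {
    for (nm in names(init)) tab$init[tab$term == nm] <- init[[nm]]
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      tab$lower[tab$term == nm] <- bounds[[nm]][1]
      tab$upper[tab$term == nm] <- bounds[[nm]][2]
    }
  }
  tab
}

# Build a parameter object of the given family from a named vector of free
# values plus fixed values.
assemble_params <- function(model, values, fixed = list()) {
  v <- as.list(values)
  f <- fixed
  get_v <- function(nm, default = NULL) {
    if (!is.null(v[[nm]])) v[[nm]] else if (!is.null(f[[nm]])) f[[nm]] else default
  }
  switch(model,
    neo_hookean = neo_hookean(get_v("c1"), allow_nonphysical = TRUE),
    yeoh = yeoh(get_v("c1"), get_v("c2", 0), get_v("c3", 0),
                allow_nonphysical = TRUE),
    ogden = {
      mus <- unlist(v[grepl("^mu", names(v))], use.names = FALSE)
      alphas <- unlist(v[grepl("^alpha", names(v))], use.names = FALSE)
      ogden(mus, alphas, allow_nonphysical = TRUE)
    },
    goh = goh(get_v("c_iso"), get_v("k1"), get_v("k2"), get_v("kappa"),
              variant = get_v("variant", "standard") ,
              tension_only = isTRUE(f$tension_only),
              allow_nonphysical = TRUE),
    fiber = fiber_model(
      yeoh(get_v("c1"), get_v("c2", 0), get_v("c3", 0),
           allow_nonphysical = TRUE),
      e_f = get_v("e_f_kpa"), phi = get_v("phi", 0.2), k = get_v("k"),
      e_f_unit = "kPa", allow_nonphysical = TRUE)
  )
}

#' Stage one of the two-stage calibration: matrix constants
#'
#' Fits the Yeoh matrix constants `C1, C2, C3` to the pooled circumferential
#' mean curve. Circumferential loading runs across the (longitudinal) fibers,
#' so the fiber energy term vanishes identically (`cos(pi/2) = 0`) and the
#' circumferential response is governed by the matrix alone. When the fit is
#' destined for the fiber-matrix composite, pass its fiber volume fraction
#' `phi` so the matrix prediction carries the composite's `(1 - phi)` weight;
#' with the default `phi = 0` the plain Yeoh prediction is fitted.
#'
#' @param curves Tidy curve tibble containing at least one circumferential
#'   specimen.
#' @param phi Fiber volume fraction of the composite the constants will be
#'   embedded in (default 0 = plain Yeoh fit).
#' @param bounds,init Named overrides, e.g. `bounds = list(c3 = c(-50, 0))`,
#'   `init = list(c1 = 2)`.
#' @param strain_grid Pooling grid.
#' @param n_starts,seed Multi-start control.
#' @return A [yeoh()] parameter object with attributes `converged`,
#'   `objective_value`, `n_iterations`, `boundary_hit`.
#' @export
fit_matrix_stage <- function(curves, phi = 0, bounds = NULL, init = NULL,
                             strain_grid = seq(0, 0.5, length.out = 51),
                             n_starts = 8, seed = 1) {
  check_curve_table(curves)
  circ <- dplyr::filter(curves, .data$orientation == "circumferential")
  if (nrow(circ) == 0) {
    rlang::abort("No circumferential curves supplied.",
                 class = "fibrelast_validation_error")
  }
  mean_curve <- pool_curves(circ, strain_grid)
  tab <- apply_overrides(default_param_table("yeoh"), bounds, init)
  obj <- function(p) {
    names(p) <- tab$term
    prm <- assemble_params("yeoh", p)
    pred <- (1 - phi) * nominal_stress_model(prm, mean_curve$strain)
    ssr <- sum((pred - mean_curve$stress_kpa)^2)
    if (!is.finite(ssr)) 1e30 else ssr
  }
  fit <- multistart_optim(obj, tab$init, tab$lower, tab$upper,
                          n_starts = n_starts, seed = seed)
  names(fit$par) <- tab$term
  out <- yeoh(fit$par[["c1"]], fit$par[["c2"]], fit$par[["c3"]],
              allow_nonphysical = TRUE)
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "objective_value") <- fit$value
  attr(out, "n_iterations") <- unname(fit$counts["function"])
  attr(out, "boundary_hit") <- fit$boundary_hit
  if (fit$convergence != 0) {
    rlang::warn("Matrix-stage optimizer did not report convergence.")
  }
  out
}

#' Stage two of the two-stage calibration: fiber constants
#'
#' With the matrix constants frozen from [fit_matrix_stage()], fits the free
#' fiber constants (by default only the stiffening exponent `k`) to the
#' pooled longitudinal mean curve, where the fibers are loaded along their
#' axis (`theta = 0`). The fiber modulus and volume fraction default to being
#' held at supplied values, mirroring a protocol in which those two constants
#' come from histology rather than from the tensile fit.
#'
#' If the fiber term cannot influence the prediction (`phi = 0`), the
#' objective is flat in `k`; the fit then warns and flags the result instead
#' of reporting a spurious estimate.
#'
#' @param curves Tidy curve tibble containing at least one longitudinal
#'   specimen.
#' @param fixed_matrix A [yeoh()] object, frozen.
#' @param e_f_kpa Fiber modulus (kPa), fixed unless listed in `free`.
#' @param phi Fiber volume fraction, fixed unless listed in `free`.
#' @param free Character vector of free constants among
#'   `c("k", "e_f_kpa", "phi")`.
#' @param theta Fiber angle during the longitudinal fit (0 = along fibers).
#' @inheritParams fit_matrix_stage
#' @return A [fiber_model()] parameter object with fit diagnostics attached
#'   as attributes (`converged`, `objective_value`, `n_iterations`,
#'   `boundary_hit`, `identifiable`).
#' @export
fit_fiber_stage <- function(curves, fixed_matrix, e_f_kpa = 100, phi = 0.2,
                            free = "k", theta = 0, bounds = NULL, init = NULL,
                            strain_grid = seq(0, 0.5, length.out = 51),
                            n_starts = 8, seed = 1) {
  check_curve_table(curves)
  if (!inherits(fixed_matrix, "fibrelast_yeoh")) {
    rlang::abort("`fixed_matrix` must be a yeoh() parameter object.",
                 class = "fibrelast_validation_error")
  }
  longi <- dplyr::filter(curves, .data$orientation == "longitudinal")
  if (nrow(longi) == 0) {
    rlang::abort("No longitudinal curves supplied.",
                 class = "fibrelast_validation_error")
  }
  free <- match.arg(free, c("k", "e_f_kpa", "phi"), several.ok = TRUE)
  mean_curve <- pool_curves(longi, strain_grid)
  tab <- default_param_table("fiber")
  tab <- tab[tab$term %in% free, , drop = FALSE]
  if ("phi" %in% free) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(term = "phi", init = phi,
                                                lower = 0, upper = 1))
  }
  tab <- apply_overrides(tab, bounds, init)
  fixed <- list(c1 = fixed_matrix$c1, c2 = fixed_matrix$c2,
                c3 = fixed_matrix$c3, e_f_kpa = e_f_kpa, phi = phi)
  obj <- function(p) {
    names(p) <- tab$term
    prm <- assemble_params("fiber", p, fixed = fixed)
    pred <- nominal_stress_model(prm, mean_curve$strain, theta = theta)
    ssr <- sum((pred - mean_curve$stress_kpa)^2)
    if (!is.finite(ssr)) 1e30 else ssr
  }
  fit <- multistart_optim(obj, tab$init, tab$lower, tab$upper,
                          n_starts = n_starts, seed = seed)
  names(fit$par) <- tab$term

  # Identifiability probe: perturb each free constant around the optimum;
  # a flat objective (e.g. k with phi = 0) means the data do not constrain it.
  identifiable <- TRUE
  for (i in seq_along(fit$par)) {
    p_lo <- p_hi <- fit$par
    span <- tab$upper[i] - tab$lower[i]
    p_lo[i] <- max(tab$lower[i], fit$par[i] - 0.25 * span)
    p_hi[i] <- min(tab$upper[i], fit$par[i] + 0.25 * span)
    spread <- max(obj(p_lo), obj(p_hi)) - fit$value
    if (spread <= 1e-10 * (1 + abs(fit$value))) identifiable <- FALSE
  }
  if (!identifiable) {
    rlang::warn(paste0(
      "Flat objective: one or more fiber constants (",
      paste(tab$term, collapse = ", "),
      ") are not identifiable from these data (e.g. phi = 0 removes the ",
      "fiber term); their reported values are not estimates."),
      class = "fibrelast_flat_objective")
  }

  values <- as.list(fit$par)
  out <- assemble_params("fiber", values, fixed = fixed)
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "objective_value") <- fit$value
  attr(out, "n_iterations") <- unname(fit$counts["function"])
  attr(out, "boundary_hit") <- fit$boundary_hit
  attr(out, "identifiable") <- identifiable
  out
}

#' Fit one parameter set to both orientations simultaneously
#'
#' Minimises the pooled sum of squared residuals over the circumferential and
#' longitudinal mean curves with a single parameter vector. Isotropic models
#' (Neo-Hookean, Yeoh, Ogden) necessarily predict the same curve for both
#' orientations, which is exactly the limitation this protocol exposes;
#' anisotropic models (GOH, fiber) switch the fiber angle per orientation
#' (`pi/2` circumferential, `0` longitudinal, fibers longitudinal).
#'
#' @param model_name One of `"neo_hookean"`, `"yeoh"`, `"ogden"`, `"goh"`,
#'   `"fiber"`.
#' @param curves Tidy curve tibble with at least one curve per orientation.
#' @param fixed Named list of constants held fixed (fiber: `phi` defaults to
#'   0.2; GOH: `variant`, `tension_only`).
#' @param normalization Percent-RMSE normaliser, see [rmse_percent()].
#' @inheritParams fit_matrix_stage
#' @return A `fibrelast_fit` object; see [tidy.fibrelast_fit()] and
#'   [glance.fibrelast_fit()].
#' @export
fit_single_set <- function(model_name, curves, fixed = list(),
                           bounds = NULL, init = NULL,
                           strain_grid = seq(0, 0.5, length.out = 51),
                           n_starts = 8, seed = 1,
                           normalization = "mean_abs") {
  check_curve_table(curves)
  tab <- apply_overrides(default_param_table(model_name), bounds, init)
  mean_curves <- pool_curves(curves, strain_grid)
  orientations <- unique(mean_curves$orientation)
  if (length(orientations) < 2) {
    rlang::abort("Curves for both orientations are required.",
                 class = "fibrelast_validation_error")
  }
  if (model_name == "fiber" && is.null(init)) {
    phi_fixed <- fixed$phi %||% 0.2
    warm <- fiber_varpro_init(mean_curves, phi_fixed, tab)
    tab <- apply_overrides(tab, init = warm)
  }
  strain_v <- mean_curves$strain
  theta_v <- orientation_theta(mean_curves$orientation)
  obs_v <- mean_curves$stress_kpa
  obj <- function(p) {
    names(p) <- tab$term
    prm <- assemble_params(model_name, p, fixed = fixed)
    pred <- nominal_stress_model(prm, strain_v, theta = theta_v)
    ssr <- sum((pred - obs_v)^2)
    if (!is.finite(ssr)) 1e30 else ssr
  }
  fit <- multistart_optim(obj, tab$init, tab$lower, tab$upper,
                          n_starts = n_starts, seed = seed)
  names(fit$par) <- tab$term
  params <- assemble_params(model_name, as.list(fit$par), fixed = fixed)
  finish_fit(model_name, params, fit, mean_curves, tab, seed, normalization,
             protocol = "single_set")
}

# Warm start for the fiber composite via variable projection: for fixed k
# the prediction is linear in (C1, C2, C3, E_f), so a 1-D search over k with
# a linear least-squares solve per k locates the valley the quasi-Newton
# polish then refines. Coefficients are clipped into the bounds.
fiber_varpro_init <- function(mean_curves, phi, tab) {
  lam <- 1 + mean_curves$strain
  th <- orientation_theta(mean_curves$orientation)
  x <- (lam^2 + 2 / lam) - 3
  base <- 2 * (lam - lam^-2) * (1 - phi)
  i4 <- lam^2 * cos(th)^2 + sin(th)^2 / lam
  di4 <- 2 * lam * cos(th)^2 - lam^-2 * sin(th)^2
  obs <- mean_curves$stress_kpa
  profile <- function(k) {
    X <- cbind(base, base * 2 * x, base * 3 * x^2,
               phi * cos(th) * (k / 2) * exp(k * (i4 - 1)) * di4)
    cf <- tryCatch(qr.solve(X, obs), error = function(e) rep(NA_real_, 4))
    if (anyNA(cf)) return(list(ssr = Inf, coef = cf))
    list(ssr = sum((X %*% cf - obs)^2), coef = cf)
  }
  k_lo <- max(tab$lower[tab$term == "k"], 1e-2)
  k_hi <- tab$upper[tab$term == "k"]
  ks <- exp(seq(log(k_lo), log(k_hi), length.out = 40))
  ssrs <- vapply(ks, function(k) profile(k)$ssr, numeric(1))
  k0 <- ks[which.min(ssrs)]
  k_ref <- stats::optimize(function(k) profile(k)$ssr,
                           c(max(k_lo, k0 / 2), min(k_hi, k0 * 2)))$minimum
  cf <- profile(k_ref)$coef
  clip <- function(term, v) {
    min(max(v, tab$lower[tab$term == term]), tab$upper[tab$term == term])
  }
  list(c1 = clip("c1", cf[1]), c2 = clip("c2", cf[2]),
       c3 = clip("c3", cf[3]), e_f_kpa = clip("e_f_kpa", cf[4]),
       k = clip("k", k_ref))
}

# Shared assembly of a fibrelast_fit object from an optimizer result.
finish_fit <- function(model_name, params, fit, mean_curves, tab, seed,
                       normalization, protocol) {
  preds <- mean_curves |>
    dplyr::mutate(pred = nominal_stress_model(
      params, .data$strain, theta = orientation_theta(.data$orientation)))
  rmse_by <- preds |>
    dplyr::group_by(.data$orientation) |>
    dplyr::summarise(rmse = rmse_percent(.data$pred, .data$stress_kpa,
                                         normalization = normalization),
                     .groups = "drop")
  pick <- function(ori) {
    v <- rmse_by$rmse[rmse_by$orientation == ori]
    if (length(v) == 1) v else NA_real_
  }
  structure(list(
    model_name = model_name,
    params = params,
    rmse_circ = pick("circumferential"),
    rmse_long = pick("longitudinal"),
    n_iterations = unname(fit$counts["function"]),
    converged = fit$convergence == 0,
    objective_value = fit$value,
    bounds_used = tab,
    boundary_hit = isTRUE(fit$boundary_hit),
    seed = seed,
    normalization = normalization,
    protocol = protocol,
    mean_curves = preds
  ), class = "fibrelast_fit")
}

#' Fit and rank several constitutive models on one data set
#'
#' Runs the per-model calibration protocol — the two-stage matrix/fiber
#' procedure for the fiber-matrix composite, a single pooled parameter set
#' for every other model (`protocol = "staged_fiber"`, default), or the
#' single-set protocol for all models (`protocol = "single_set"`) — and
#' returns the fits together with a report ranked by longitudinal percent
#' RMSE. A model whose fit fails is reported as failed without aborting the
#' remaining models.
#'
#' @param curves Tidy curve tibble with both orientations.
#' @param models Character vector of model names.
#' @param protocol `"staged_fiber"` or `"single_set"`.
#' @param fiber_fixed Named list passed to the fiber stage
#'   (`e_f_kpa`, `phi`, `free`).
#' @inheritParams fit_single_set
#' @return A `fibrelast_comparison`: list with `fits` (named list) and
#'   `report` (ranked tibble).
#' @export
compare_models <- function(curves,
                           models = c("yeoh", "ogden", "goh", "fiber"),
                           protocol = c("staged_fiber", "single_set"),
                           fiber_fixed = list(e_f_kpa = 100, phi = 0.2,
                                              free = "k"),
                           strain_grid = seq(0, 0.5, length.out = 51),
                           n_starts = 8, seed = 1,
                           normalization = "mean_abs") {
  protocol <- match.arg(protocol)
  if (length(models) == 0) {
    rlang::abort("`models` must be non-empty.",
                 class = "fibrelast_validation_error")
  }
  check_curve_table(curves)
  fits <- purrr::map(models, function(m) {
    tryCatch({
      if (m == "fiber" && protocol == "staged_fiber") {
        fit_two_stage(curves, e_f_kpa = fiber_fixed$e_f_kpa %||% 100,
                      phi = fiber_fixed$phi %||% 0.2,
                      free = fiber_fixed$free %||% "k",
                      strain_grid = strain_grid, n_starts = n_starts,
                      seed = seed, normalization = normalization)
      } else {
        fit_single_set(m, curves, strain_grid = strain_grid,
                       n_starts = n_starts, seed = seed,
                       normalization = normalization)
      }
    }, error = function(e) {
      structure(list(model_name = m, error = conditionMessage(e)),
                class = "fibrelast_fit_failure")
    })
  })
  names(fits) <- models
  report <- purrr::map_dfr(fits, function(f) {
    if (inherits(f, "fibrelast_fit_failure")) {
      tibble::tibble(model = f$model_name, rmse_circ_pct = NA_real_,
                     rmse_long_pct = NA_real_, converged = FALSE,
                     failed = TRUE)
    } else {
      tibble::tibble(model = f$model_name, rmse_circ_pct = f$rmse_circ,
                     rmse_long_pct = f$rmse_long, converged = f$converged,
                     failed = FALSE)
    }
  }) |>
    dplyr::arrange(.data$failed, .data$rmse_long_pct)
  structure(list(fits = fits, report = report, protocol = protocol,
                 seed = seed, normalization = normalization),
            class = "fibrelast_comparison")
}

#' Two-stage calibration of the fiber-matrix composite
#'
#' Convenience wrapper chaining [fit_matrix_stage()] (circumferential,
#' matrix constants, composite weight `1 - phi`) and [fit_fiber_stage()]
#' (longitudinal, matrix frozen) and packaging the result as a
#' `fibrelast_fit` with per-orientation percent RMSE.
#'
#' @inheritParams fit_fiber_stage
#' @inheritParams fit_single_set
#' @export
fit_two_stage <- function(curves, e_f_kpa = 100, phi = 0.2, free = "k",
                          strain_grid = seq(0, 0.5, length.out = 51),
                          n_starts = 8, seed = 1,
                          normalization = "mean_abs") {
  matrix_fit <- fit_matrix_stage(curves, phi = phi, strain_grid = strain_grid,
                                 n_starts = n_starts, seed = seed)
  fiber_fit <- fit_fiber_stage(curves, matrix_fit, e_f_kpa = e_f_kpa,
                               phi = phi, free = free,
                               strain_grid = strain_grid,
                               n_starts = n_starts, seed = seed)
  mean_curves <- pool_curves(curves, strain_grid)
  pseudo <- list(
    par = stats::setNames(numeric(0), character(0)),
    value = attr(fiber_fit, "objective_value"),
    convergence = if (isTRUE(attr(matrix_fit, "converged")) &&
                      isTRUE(attr(fiber_fit, "converged"))) 0 else 1,
    counts = c(`function` = attr(matrix_fit, "n_iterations") +
                 attr(fiber_fit, "n_iterations")),
    boundary_hit = isTRUE(attr(matrix_fit, "boundary_hit")) ||
      isTRUE(attr(fiber_fit, "boundary_hit"))
  )
  finish_fit("fiber", fiber_fit, pseudo, mean_curves,
             default_param_table("fiber"), seed, normalization,
             protocol = "staged_fiber")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
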