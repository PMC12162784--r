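#' Read tensile curves from CSV
#'
#' Expects the package's standard curve table: header
#' `specimen_id,orientation,strain,stress_kpa`, comma-separated, `.` decimal,
#' optional `#` comment lines (provenance) before the header. Validation is
#' strict and errors name the offending file line: unknown orientation
#' tokens, non-monotone strain within a specimen, ragged rows, and
#' non-numeric values are all rejected.
#'
#' @param path CSV file path.
#' @return A tidy curve tibble (`specimen_id`, `orientation`, `strain`,
#'   `stress_kpa`), grouped implicitly by specimen.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "fibrelast_parse_error")
  }
  raw_lines <- readLines(path, warn = FALSE)
  n_comment <- 0
  while (n_comment < length(raw_lines) &&
         grepl("^\\s*#", raw_lines[n_comment + 1])) {
    n_comment <- n_comment + 1
  }
  header_line <- n_comment + 1
  # strain/stress are read as text and converted with as.numeric (strtod):
  # correctly rounded to the nearest double, so write/read round-trips exactly
  tbl <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      specimen_id = readr::col_character(),
      orientation = readr::col_character(),
      strain = readr::col_character(),
      stress_kpa = readr::col_character()
    )
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    # readr's problem rows count file lines net of the skipped comments
    rlang::abort(paste0("Malformed row at line ",
                        probs$row[1] + n_comment, " of ", path, ": ",
                        probs$expected[1], ", got ", probs$actual[1]),
                 class = "fibrelast_parse_error")
  }
  expected <- c("specimen_id", "orientation", "strain", "stress_kpa")
  if (!identical(names(tbl), expected)) {
    rlang::abort(paste0("Header must be `", paste(expected, collapse = ","),
                        "`, got `", paste(names(tbl), collapse = ","), "`."),
                 class = "fibrelast_parse_error")
  }
  tbl$strain <- suppressWarnings(as.numeric(tbl$strain))
  tbl$stress_kpa <- suppressWarnings(as.numeric(tbl$stress_kpa))
  line_no <- seq_len(nrow(tbl)) + header_line
  bad_ori <- !tbl$orientation %in% c("circumferential", "longitudinal")
  if (any(bad_ori)) {
    i <- which(bad_ori)[1]
    rlang::abort(paste0("Unknown orientation `", tbl$orientation[i],
                        "` at line ", line_no[i], " of ", path, "."),
                 class = "fibrelast_parse_error")
  }
  if (any(is.na(tbl$strain)) || any(is.na(tbl$stress_kpa))) {
    i <- which(is.na(tbl$strain) | is.na(tbl$stress_kpa))[1]
    rlang::abort(paste0("Non-numeric strain/stress at line ", line_no[i],
                        " of ", path, "."),
                 class = "fibrelast_parse_error")
  }
  if (any(tbl$strain < 0)) {
    i <- which(tbl$strain < 0)[1]
    rlang::abort(paste0("Negative strain at line ", line_no[i], " of ",
                        path, "."),
                 class = "fibrelast_parse_error")
  }
  # Strain must be nondecreasing within each specimen (file sorted by
  # specimen, then strain).
  for (sid in unique(tbl$specimen_id)) {
    idx <- which(tbl$specimen_id == sid)
    d <- diff(tbl$strain[idx])
    if (any(d < 0)) {
      bad <- idx[which(d < 0)[1] + 1]
      rlang::abort(paste0("Non-monotone strain within specimen `", sid,
                          "` at line ", line_no[bad], " of ", path, "."),
                   class = "fibrelast_parse_error")
    }
  }
  tbl
}

provenance_header <- function(seed = NULL, config = NULL) {
  version <- as.character(utils::packageVersion("fibrelast"))
  c(
    paste0("# fibrelast ", version),
    paste0("# seed: ", if (is.null(seed)) "none" else seed),
    paste0("# config_hash: ",
           rlang::hash(list(version = version, seed = seed, config = config)))
  )
}

#' Write tensile curves to CSV
#'
#' Writes the standard curve table with a provenance header (tool version,
#' seed, config hash) as `#` comment lines. [read_curves()] skips those
#' lines, so write/read round-trips to full double precision.
#'
#' @param curves Tidy curve tibble.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header, if any.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, seed = NULL) {
  check_curve_table(curves)
  curves <- dplyr::arrange(curves, .data$specimen_id, .data$strain)
  body <- c(
    "specimen_id,orientation,strain,stress_kpa",
    sprintf("%s,%s,%.17g,%.17g", curves$specimen_id, curves$orientation,
            curves$strain, curves$stress_kpa)
  )
  writeLines(c(provenance_header(seed = seed, config = "curves"), body), path)
  invisible(path)
}

report_columns <- c(
  "model", "c1", "c2", "c3", "mu1", "alpha1", "c_iso", "k1", "k2", "kappa",
  "e_f_kpa", "phi", "k", "rmse_circ_pct", "rmse_long_pct", "converged",
  "seed"
)

#' Write a model-comparison report to CSV
#'
#' One row per fitted model with its flattened parameters, per-orientation
#' percent RMSE, convergence flag and seed. Column order is fixed
#' (`model, c1, c2, c3, mu1, alpha1, c_iso, k1, k2, kappa, e_f_kpa, phi, k,
#' rmse_circ_pct, rmse_long_pct, converged, seed`); parameters a model does
#' not have are left empty. Reruns with the same inputs and seed are
#' byte-identical.
#'
#' @param results A `fibrelast_comparison`, a list of `fibrelast_fit`
#'   objects, or a single fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "fibrelast_comparison")) results <- results$fits
  if (inherits(results, "fibrelast_fit")) results <- list(results)
  results <- purrr::discard(results, inherits, "fibrelast_fit_failure")
  if (length(results) == 0) {
    rlang::abort("`results` must contain at least one successful fit.",
                 class = "fibrelast_validation_error")
  }
  rows <- purrr::map_dfr(results, function(f) {
    flat <- flatten_params(f$params)
    row <- stats::setNames(
      as.list(rep(NA_real_, length(report_columns))), report_columns)
    row$model <- f$model_name
    for (nm in names(flat)) if (nm %in% report_columns) row[[nm]] <- flat[[nm]]
    row$rmse_circ_pct <- f$rmse_circ
    row$rmse_long_pct <- f$rmse_long
    row$converged <- f$converged
    row$seed <- f$seed
    tibble::as_tibble(row)
  })
  seed <- results[[1]]$seed
  fmt <- function(x) {
    ifelse(is.na(x), "",
           vapply(x, function(v) format(v, digits = 15, trim = TRUE),
                  character(1)))
  }
  body <- c(
    paste(report_columns, collapse = ","),
    do.call(paste, c(lapply(report_columns, function(cn) fmt(rows[[cn]])),
                     sep = ","))
  )
  writeLines(c(provenance_header(seed = seed, config = "report"), body), path)
  invisible(path)
}

#' Serialise / restore model parameters as JSON
#'
#' Flat key-value representation, one object per model family, keys named as
#' in the constructors. The round-trip preserves every constant to full
#' double precision.
#'
#' @param params A [model_params] object.
#' @param path JSON path.
#' @return `write_params()`: `path` invisibly; `read_params()`: the restored
#'   parameter object.
#' @export
write_params <- function(params, path) {
  if (!inherits(params, "fibrelast_params")) {
    rlang::abort("`params` must be a fibrelast parameter object.",
                 class = "fibrelast_validation_error")
  }
  payload <- switch(params$model,
    neo_hookean = list(model = "neo_hookean", c1 = params$c1),
    yeoh = list(model = "yeoh", c1 = params$c1, c2 = params$c2,
                c3 = params$c3),
    ogden = list(model = "ogden", mu = as.list(params$mu),
                 alpha = as.list(params$alpha)),
    goh = list(model = "goh", c_iso = params$c_iso, k1 = params$k1,
               k2 = params$k2, kappa = params$kappa, theta = params$theta,
               variant = params$variant,
               tension_only = params$tension_only),
    fiber = list(model = "fiber", c1 = params$matrix$c1,
                 c2 = params$matrix$c2, c3 = params$matrix$c3,
                 e_f_kpa = params$e_f_kpa, phi = params$phi, k = params$k,
                 theta = params$theta)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # accept a serialized fit result too: constants live under $params there
  if (!is.null(p$params)) p <- c(list(model = p$model), p$params)
  switch(p$model,
    neo_hookean = neo_hookean(p$c1, allow_nonphysical = TRUE),
    yeoh = yeoh(p$c1, p$c2, p$c3, allow_nonphysical = TRUE),
    ogden = ogden(unlist(p$mu), unlist(p$alpha), allow_nonphysical = TRUE),
    goh = goh(p$c_iso, p$k1, p$k2, p$kappa, theta = p$theta %||% 0,
              variant = p$variant %||% "standard",
              tension_only = isTRUE(p$tension_only),
              allow_nonphysical = TRUE),
    fiber = fiber_model(yeoh(p$c1, p$c2, p$c3, allow_nonphysical = TRUE),
                        e_f = p$e_f_kpa, phi = p$phi, k = p$k,
                        theta = p$theta %||% 0, e_f_unit = "kPa",
                        allow_nonphysical = TRUE),
    rlang::abort(paste0("Unknown model in ", path, ": ", p$model),
                 class = "fibrelast_parse_error")
  )
}

#' Serialise a fit result as JSON with full provenance
#'
#' Stores the model name, calibrated constants, per-orientation percent
#' RMSE, optimizer diagnostics, bounds, seed, normaliser and tool version.
#'
#' @param fit A `fibrelast_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  if (!inherits(fit, "fibrelast_fit")) {
    rlang::abort("`fit` must be a fibrelast_fit object.",
                 class = "fibrelast_validation_error")
  }
  payload <- list(
    tool = "fibrelast",
    version = as.character(utils::packageVersion("fibrelast")),
    model = fit$model_name,
    protocol = fit$protocol,
    params = flatten_params(fit$params),
    rmse_circ_pct = fit$rmse_circ,
    rmse_long_pct = fit$rmse_long,
    converged = fit$converged,
    boundary_hit = fit$boundary_hit,
    n_iterations = fit$n_iterations,
    objective_value = fit$objective_value,
    bounds = list(term = fit$bounds_used$term,
                  lower = fit$bounds_used$lower,
                  upper = fit$bounds_used$upper,
                  init = fit$bounds_used$init),
    seed = fit$seed,
    normalization = fit$normalization
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
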