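#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibrated fit into one row per parameter
#'
#' @param x A `fibrelast_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `term`, `estimate`.
#' @export
tidy.fibrelast_fit <- function(x, ...) {
  flat <- flatten_params(x$params)
  tibble::tibble(
    model = x$model_name,
    term = names(flat),
    estimate = unlist(flat, use.names = FALSE)
  )
}

#' One-row fit summary
#'
#' @param x A `fibrelast_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, per-orientation percent RMSE, optimizer
#'   diagnostics, protocol, seed.
#' @export
glance.fibrelast_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    rmse_circ_pct = x$rmse_circ,
    rmse_long_pct = x$rmse_long,
    converged = x$converged,
    boundary_hit = x$boundary_hit,
    objective_value = x$objective_value,
    n_iterations = x$n_iterations,
    protocol = x$protocol,
    normalization = x$normalization,
    seed = x$seed
  )
}

#' @export
print.fibrelast_fit <- function(x, ...) {
  cat("<fibrelast fit: ", x$model_name, " (", x$protocol, ")>\n", sep = "")
  cat(sprintf("  RMSE circumferential: %.2f%%  longitudinal: %.2f%% (%s)\n",
              x$rmse_circ, x$rmse_long, x$normalization))
  cat("  converged:", x$converged,
      if (isTRUE(x$boundary_hit)) " [parameter at bound]" else "", "\n")
  print(x$params)
  invisible(x)
}

#' @export
print.fibrelast_comparison <- function(x, ...) {
  cat("<fibrelast model comparison (", x$protocol, ", seed ", x$seed,
      ")>\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @rdname tidy.fibrelast_fit
#' @export
tidy.fibrelast_comparison <- function(x, ...) {
  purrr::map_dfr(purrr::discard(x$fits, inherits, "fibrelast_fit_failure"),
                 tidy)
}

#' @rdname glance.fibrelast_fit
#' @export
glance.fibrelast_comparison <- function(x, ...) {
  purrr::map_dfr(purrr::discard(x$fits, inherits, "fibrelast_fit_failure"),
                 glance)
}
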