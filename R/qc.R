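#' Specimen retention bookkeeping
#'
#' Tensile tests on clamped soft-tissue strips are routinely discarded when
#' failure or slippage occurs near the clamping region, or when the usable
#' strain range falls short of the analysis window. `qc_specimens()` flags
#' each tested specimen as retained or excluded; `retention_summary()` counts
#' extracted versus retained specimens per orientation.
#'
#' @param specimens Tibble with one row per tested specimen: `specimen_id`,
#'   `orientation`, `failure_mode` (`"none"`, `"clamp_failure"`,
#'   `"slippage"`), and optionally `max_strain` (largest strain reached).
#' @param min_max_strain Minimum usable strain range for retention
#'   (default 0.5, the conservative analysis window within which the
#'   cross-section can still be tracked).
#' @return `qc_specimens()`: the input with a logical `retained` column;
#'   `retention_summary()`: a tibble with per-orientation and total
#'   `n_extracted` / `n_retained`.
#' @export
qc_specimens <- function(specimens, min_max_strain = 0.5) {
  needed <- c("specimen_id", "orientation", "failure_mode")
  missing_cols <- setdiff(needed, names(specimens))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Specimen table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "fibrelast_validation_error")
  }
  known <- c("none", "clamp_failure", "slippage")
  bad <- setdiff(unique(specimens$failure_mode), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown failure_mode: ", paste(bad, collapse = ", ")),
                 class = "fibrelast_validation_error")
  }
  specimens |>
    dplyr::mutate(
      retained = .data$failure_mode == "none" &
        (if ("max_strain" %in% names(specimens)) {
          .data$max_strain >= min_max_strain
        } else TRUE)
    )
}

#' @rdname qc_specimens
#' @export
retention_summary <- function(specimens, min_max_strain = 0.5) {
  flagged <- if ("retained" %in% names(specimens)) {
    specimens
  } else {
    qc_specimens(specimens, min_max_strain)
  }
  per_orientation <- flagged |>
    dplyr::group_by(.data$orientation) |>
    dplyr::summarise(n_extracted = dplyr::n(),
                     n_retained = sum(.data$retained), .groups = "drop")
  dplyr::bind_rows(
    per_orientation,
    tibble::tibble(orientation = "total",
                   n_extracted = nrow(flagged),
                   n_retained = sum(flagged$retained))
  )
}
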