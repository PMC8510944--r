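#' Read and write pressure-trace CSV files
#'
#' Traces are stored as plain CSV with columns `time_s`,
#' `overpressure_pa` and optionally `probe`. Write-then-read is the
#' identity on values to better than 1e-12 relative (full-precision
#' serialisation).
#'
#' @param file Path to a CSV file.
#' @return `read_trace()` returns a trace tibble.
#' @export
read_trace <- function(file) {
  d <- readr::read_csv(file, show_col_types = FALSE)
  if (!all(c("time_s", "overpressure_pa") %in% names(d))) {
    stop("trace file needs columns time_s and overpressure_pa: ", file)
  }
  if (is.null(d$probe)) d$probe <- "trace"
  tibble::as_tibble(d[, c("time_s", "overpressure_pa", "probe")])
}

#' @rdname read_trace
#' @param trace A trace tibble.
#' @export
write_trace <- function(trace, file) {
  stopifnot(all(c("time_s", "overpressure_pa") %in% names(trace)))
  readr::write_csv(trace, file)
  invisible(file)
}

#' Write a cohort back to CSV
#'
#' Serialises a cohort tibble to the same schema [read_cohort()] parses,
#' so the round trip reproduces the cohort (flags are re-derived from the
#' remark text when present, otherwise from the flag columns).
#'
#' @param cohort A cohort tibble.
#' @param file Output path.
#' @export
write_cohort <- function(cohort, file) {
  remark <- cohort$organ_damage
  if (is.null(remark) || all(is.na(remark))) {
    flag_names <- c(LH = "LH", hemothorax = "Hemothorax",
                    splenic = "Splenic injury", liver = "Liver injury",
                    IAH = "IAH", BR = "BR")
    remark <- vapply(seq_len(nrow(cohort)), function(i) {
      on <- names(flag_names)[vapply(names(flag_names),
                                     function(f) isTRUE(cohort[[f]][i]),
                                     logical(1))]
      paste(flag_names[on], collapse = ", ")
    }, character(1))
  }
  out <- tibble::tibble(
    id = cohort$id,
    body_weight_kg = cohort$body_weight_kg,
    body_armor = ifelse(cohort$armor, "Yes", "No"),
    organ_damage = remark,
    respiratory_arrest = ifelse(cohort$respiratory_arrest, "Yes", "No"),
    outcome = as.character(cohort$outcome)
  )
  readr::write_csv(out, file)
  invisible(file)
}

#' Write an arrival report as JSON
#'
#' @param arrivals Arrival tibble from [simulate_scenario()] (columns
#'   `event`, `time_s`, `offset_from_t0_ms`).
#' @param file Output path.
#' @param threshold Detection threshold recorded alongside, Pa.
#' @export
write_arrivals_json <- function(arrivals, file, threshold = 5e3) {
  x <- list(
    threshold_pa = threshold,
    events = stats::setNames(
      lapply(seq_len(nrow(arrivals)), function(i) list(
        time_s = arrivals$time_s[i],
        offset_from_t0_ms = arrivals$offset_from_t0_ms[i]
      )),
      arrivals$event
    )
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Write a pressure snapshot as CSV
#'
#' Long-format serialisation of a pressure field snapshot (one row per
#' fluid cell: `z_m`, `r_m`, `pressure_pa`).
#'
#' @param snapshot A `(time, pressure)` snapshot from the solver.
#' @param grid The [axi_grid()] of the run.
#' @param file Output path.
#' @export
write_snapshot <- function(snapshot, grid, file) {
  p <- snapshot$pressure
  d <- tibble::tibble(
    z_m = rep(grid$z_centers, times = grid$nr),
    r_m = rep(grid$r_centers, each = grid$nz),
    pressure_pa = as.vector(p)
  )
  d <- d[!is.na(d$pressure_pa), ]
  readr::write_csv(d, file)
  invisible(file)
}
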