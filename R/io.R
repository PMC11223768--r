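#' Write a simulated trajectory to tidy CSV
#'
#' Emits the per-cycle columns `(cycle, phase, clamp_deg, state_deg,
#' x_hat_deg, extent_deg)`; all angles in degrees.
#'
#' @param trajectory a `"pea_trajectory"` from one of the simulators.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pea_trajectory"))
  cols <- c("cycle", "phase", "clamp_deg", "state_deg", "x_hat_deg",
            "extent_deg")
  utils::write.csv(as.data.frame(trajectory)[cols], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to CSV with a sidecar truth file
#'
#' The trial table goes to `<stem>.csv` and the embedded
#' truth-parameter record (plus experiment tag and seed) to
#' `<stem>_truth.json`.
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param stem output path without extension.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dataset_csv <- function(dataset, stem) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, "_truth.json")
  utils::write.csv(dataset$data, csv, row.names = FALSE)
  jsonlite::write_json(list(experiment = dataset$experiment,
                            seed = dataset$seed,
                            truth = dataset$truth),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(data = csv, truth = json))
}

#' Read an adaptation trial table from CSV
#'
#' Expects the tidy schema produced by [gen_adaptation()] (or real data
#' arranged the same way): `subject` (optional), `clamp_deg`, `cycle`,
#' `mode`, `hand_deg`, with hand angles on the positive-adaptation
#' convention.
#'
#' @param path CSV file.
#' @return A data.frame ready for [multistart_fit()].
#' @export
read_adaptation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clamp_deg", "cycle", "mode", "hand_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("adaptation CSV lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Read a 2AFC trial table from CSV
#'
#' Expects the schema of [gen_2afc()]: `subject`, `clamp_deg` (signed),
#' `reference_offset_deg`, `response_ccw` (plus any bookkeeping
#' columns).
#'
#' @param path CSV file.
#' @return A data.frame ready for [estimate_sigma_v()].
#' @export
read_2afc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "clamp_deg", "reference_offset_deg", "response_ccw")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("2AFC CSV lacks columns: ", paste(missing, collapse = ", "))
  df
}
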