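# CSV I/O for the analysis input tables (the counterpart of write_cohort).

#' Read a cohort's input tables from a directory of CSVs
#'
#' Reads whatever tables are present among those written by
#' [write_cohort()] (animals, body weights, bottle readings, operant
#' manifest and events, NOR/EPM trajectories and geometry, behavior
#' events) plus the `config.txt` key-value file, and returns them in the
#' same `cohort_dataset` layout [run_pipeline()] consumes. Latent
#' simulation traits are never read back: the analysis only sees the
#' observable tables.
#'
#' @param dir Directory containing the CSVs.
#' @return A `cohort_dataset` list (without `traits`).
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) {
      readr::read_csv(p, show_col_types = FALSE)
    } else {
      NULL
    }
  }
  ds <- list(
    animals = rd("animals.csv"),
    bodyweights = rd("bodyweights.csv"),
    bottle_readings = rd("bottle_readings.csv"),
    operant_manifest = rd("operant_sessions.csv"),
    operant_events = rd("operant_events.csv"),
    nor_trajectories = rd("nor_trajectories.csv"),
    nor_objects = rd("nor_objects.csv"),
    epm_trajectories = rd("epm_trajectories.csv"),
    epm_geometry = rd("epm_geometry.csv"),
    behavior_events = rd("behavior_events.csv")
  )
  cfg_path <- file.path(dir, "config.txt")
  if (file.exists(cfg_path)) {
    lines <- readLines(cfg_path)
    kv <- strsplit(lines, ": ", fixed = TRUE)
    cfg <- stats::setNames(
      lapply(kv, function(x) {
        v <- paste(x[-1], collapse = ": ")
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
      }),
      vapply(kv, `[[`, character(1), 1)
    )
    ds$config <- cfg
  }
  ds <- ds[!vapply(ds, is.null, logical(1))]
  structure(ds, class = "cohort_dataset")
}
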