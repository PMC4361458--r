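# Readers/writers: spike-train and stimulus CSV interchange, and the session
# archive (a directory of CSV tables plus a JSON metadata sidecar carrying
# the config snapshot, seed and package version).

SCHEMA_VERSION <- "1"

#' Read / write spike trains as CSV
#'
#' Two-column interchange format: `source_id`, `time_s`. Writing uses full
#' double precision, so a write/read round trip is lossless.
#'
#' @param train A [spike_train()].
#' @param path CSV file path.
#' @return `write_spike_csv()` returns `path` invisibly; `read_spike_csv()`
#'   returns a [spike_train()].
#' @export
write_spike_csv <- function(train, path) {
  stopifnot(is.data.frame(train), all(c("time_s", "source_id") %in% names(train)))
  readr::write_csv(tibble(source_id = train$source_id, time_s = train$time_s),
                   path)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("source_id", "time_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("spike CSV %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "prcclamp_error_io")
  }
  spike_train(df$time_s, df$source_id)
}

#' Read / write stimulus (pulse) logs as CSV
#'
#' Columns: `t_pulse_s`, `amplitude_pA`, `duration_s` (any extra columns,
#' e.g. `scheduled_delay`, are preserved).
#'
#' @param pulses A [perturbations()] tibble.
#' @param path CSV file path.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns a [perturbations()] tibble.
#' @export
write_stimulus_csv <- function(pulses, path) {
  readr::write_csv(pulses, path)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t_pulse_s", "amplitude_pA", "duration_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("stimulus CSV %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "prcclamp_error_io")
  }
  out <- perturbations(df$t_pulse_s, df$amplitude_pA, df$duration_s)
  extra <- setdiff(names(df), need)
  for (cl in extra) out[[cl]] <- df[[cl]]
  out
}

#' Write / read a closed-loop session archive
#'
#' A session archive is a directory with `spikes.csv`, `pulses.csv`,
#' `log.csv` and `meta.json` (config snapshot, seed, schema and package
#' version — full provenance). The round trip preserves times to full double
#' precision.
#'
#' @param session A `clamp_session`.
#' @param dir Directory path (created if absent).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns the `clamp_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "clamp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spike_csv(session$train, file.path(dir, "spikes.csv"))
  write_stimulus_csv(session$pulses, file.path(dir, "pulses.csv"))
  readr::write_csv(session$log, file.path(dir, "log.csv"))
  meta <- list(
    schema_version = SCHEMA_VERSION,
    package = "prcclamp",
    package_version = as.character(utils::packageVersion("prcclamp")),
    config = session$config
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  files <- file.path(dir, c("spikes.csv", "pulses.csv", "log.csv", "meta.json"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(sprintf("session archive incomplete, missing: %s",
                  paste(basename(missing), collapse = ", ")),
          class = "prcclamp_error_io")
  }
  meta <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  structure(
    list(train = read_spike_csv(files[1]),
         pulses = read_stimulus_csv(files[2]),
         log = readr::read_csv(files[3], show_col_types = FALSE),
         config = meta$config),
    class = "clamp_session"
  )
}

#' Export a smoothed PRC as CSV
#'
#' Grid, curve and (when present) confidence band, with the bandwidth and
#' provenance recorded as a JSON sidecar.
#'
#' @param curve A `smoothed_prc`.
#' @param path CSV path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_prc_csv <- function(curve, path) {
  readr::write_csv(as_tibble(curve), path)
  meta <- list(
    schema_version = SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("prcclamp")),
    bandwidth = attr(curve, "bandwidth"),
    n_samples = attr(curve, "n_samples"),
    mean_isi_s = attr(curve, "mean_isi_s"),
    rate_hz = attr(curve, "rate_hz"),
    charge_pC = attr(curve, "charge_pC")
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
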