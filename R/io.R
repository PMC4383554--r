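# File formats, configuration and reproducibility plumbing: schema-checked
# CSV readers, self-describing outputs (config hash + seed in every header),
# and the YAML run configuration.

#' Run configuration
#'
#' Assembles the full parameter set of a run: seed, acoustic defaults, gas
#' (dissolution) parameters, simulation parameters and the synthetic
#' protocol kind. Every output file written by the pipeline carries this
#' configuration's hash and seed in its header.
#'
#' @param seed Integer seed.
#' @param config_file Optional YAML file whose top-level keys (`acoustics`,
#'   `gas`, `sim`, `protocol_kind`, `tree`) override the defaults.
#' @param ... Named overrides applied after the file (e.g.
#'   `sim = list(ensemble_size = 5)`).
#' @return A list of class `run_config` with elements `seed`, `acoustics`,
#'   `gas`, `sim`, `tree`, `protocol_kind` and `hash`.
#' @export
run_config <- function(seed = 1L, config_file = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    acoustics = list(transmit_frequency = 2e6, doppler_angle = 30,
                     sample_length = 10, reference_haematocrit = 0.30,
                     detection_threshold = 7),
    gas = unclass(gas_params()),
    sim = list(stiction_coefficient = 10, time_step = 0.1,
               ensemble_size = 30, radius_noise_rel_sd = 0.40,
               clearance_window = 60),
    tree = list(generations = 19, length_to_diameter = 20,
                viscosity = 3.5e-3, input_pressure = 100,
                outlet_pressure = 0),
    protocol_kind = "CABG"
  )
  merge_in <- function(base, upd) {
    for (k in names(upd)) {
      if (is.list(upd[[k]]) && is.list(base[[k]])) {
        base[[k]] <- merge_in(base[[k]], upd[[k]])
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  if (!is.null(config_file)) {
    cfg <- merge_in(cfg, yaml::read_yaml(config_file))
  }
  dots <- list(...)
  if (length(dots) > 0) cfg <- merge_in(cfg, dots)
  cfg$seed <- as.integer(cfg$seed)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialisation (hash field excluded), so that
#' identical configurations always map to the same hash.
#'
#' @param cfg A [run_config()] or plain list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), tmp)
  unname(tools::md5sum(tmp))
}

# header stamped into every output file
.file_header <- function(cfg) {
  c(sprintf("# mcaemboli %s",
            as.character(utils::packageVersion("mcaemboli"))),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# config_hash: %s", cfg$hash))
}

#' Write a self-describing CSV
#'
#' Writes `df` with a comment header carrying the package version, seed and
#' configuration hash; readable back with [read_stamped_csv()].
#'
#' @param df Data frame.
#' @param path Output path.
#' @param cfg A [run_config()].
#' @return Invisibly, `path`.
#' @export
write_stamped_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(cfg), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a self-describing CSV written by [write_stamped_csv()]
#'
#' @param path File path.
#' @return The data frame (header comments skipped).
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a raw embolic-event CSV
#'
#' Expects columns `time_s`, `side` and either `mebr_db` or the linear
#' intensity pair `i_eb`, `i_b` (from which MEBR is computed on read); an
#' optional `phase` column passes through. Rows must be time-sorted; schema
#' and parse failures report the offending column or row.
#'
#' @param path CSV path (comment lines starting with `#` are ignored).
#' @return Time-sorted event data frame with `time_s`, `side`, `mebr_db`
#'   (plus any extra columns).
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("time_s", "side")) {
    if (!col %in% names(df)) {
      stop(sprintf("events file %s is missing required column '%s'",
                   path, col), call. = FALSE)
    }
  }
  if (!"mebr_db" %in% names(df)) {
    if (all(c("i_eb", "i_b") %in% names(df))) {
      df$mebr_db <- mebr_from_intensities(df$i_eb, df$i_b)
    } else {
      stop(sprintf(
        "events file %s needs either 'mebr_db' or both 'i_eb' and 'i_b'",
        path), call. = FALSE)
    }
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$mebr_db) |
                 !(df$side %in% c("left", "right")))
  if (length(bad) > 0) {
    stop(sprintf("events file %s: unparseable or invalid row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (is.unsorted(df$time_s)) {
    stop(sprintf("events file %s: times are not sorted (first offence row %d)",
                 path, which(diff(df$time_s) < 0)[1] + 1), call. = FALSE)
  }
  df
}

#' Write the standard pipeline outputs
#'
#' Writes whichever results are supplied: the sized-event stream
#' (`sized_events.csv`), per-side obstruction series
#' (`obstruction_<side>.csv`), a cohort summary table (`cohort_summary.csv`)
#' and a cohort report (`cohort_report.json`). Every file carries the
#' configuration hash and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [run_config()].
#' @param sized_events Optional sized-event data frame.
#' @param obstruction Optional named list of obstruction series (names used
#'   in filenames, e.g. `left`, `right`).
#' @param cohort Optional cohort data frame (one row per patient).
#' @param report Optional [cohort_report()] result.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(out_dir, cfg, sized_events = NULL,
                          obstruction = NULL, cohort = NULL, report = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(sized_events)) {
    p <- file.path(out_dir, "sized_events.csv")
    write_stamped_csv(sized_events, p, cfg)
    written <- c(written, p)
  }
  for (nm in names(obstruction)) {
    p <- file.path(out_dir, sprintf("obstruction_%s.csv", nm))
    write_stamped_csv(as.data.frame(obstruction[[nm]]), p, cfg)
    written <- c(written, p)
  }
  if (!is.null(cohort)) {
    p <- file.path(out_dir, "cohort_summary.csv")
    write_stamped_csv(cohort, p, cfg)
    written <- c(written, p)
  }
  if (!is.null(report)) {
    p <- file.path(out_dir, "cohort_report.json")
    payload <- list(seed = cfg$seed, config_hash = cfg$hash,
                    report = unclass(report))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, force = TRUE), p)
    written <- c(written, p)
  }
  invisible(written)
}

# patient context YAML round trip
.write_patient_yaml <- function(patient, path) {
  yaml::write_yaml(list(
    id = patient$id,
    procedure = patient$procedure,
    mca_diameter_left = patient$mca_diameter_left,
    mca_diameter_right = patient$mca_diameter_right,
    monitoring_duration = patient$monitoring_duration,
    haematocrit_samples = list(
      time_s = patient$haematocrit_samples$time_s,
      fraction = patient$haematocrit_samples$fraction)
  ), path)
  invisible(path)
}

.read_patient_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  patient_record(
    id = y$id,
    mca_diameter_left = y$mca_diameter_left,
    mca_diameter_right = y$mca_diameter_right,
    procedure = y$procedure,
    haematocrit_samples = data.frame(
      time_s = unlist(y$haematocrit_samples$time_s),
      fraction = unlist(y$haematocrit_samples$fraction)),
    monitoring_duration = y$monitoring_duration
  )
}
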