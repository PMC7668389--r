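# Configuration, end-to-end synthesis, and CSV + JSON-sidecar serialization.
#
# The canonical on-disk form of a record is a two-column CSV (time_s, ppg)
# plus a JSON sidecar <stem>.annotations.json holding onsets, beat labels and
# the full configuration + seed, so the sidecar alone suffices to regenerate
# the record. A thin command-line wrapper lives in exec/ppgsynth.

#' Synthesis configuration
#'
#' Collects every knob of the synthesis pipeline. Defaults give a 10-s
#' regular recording at 125 Hz and 60 bpm with no beat-to-beat RR
#' variability and no noise.
#'
#' @param signal_type `"regular"`, `"compensation"`, `"reset"` or
#'   `"interpolation"`.
#' @param fs Sampling frequency in Hz (>= 30).
#' @param length_s Signal length in seconds (> 0).
#' @param mean_hr Mean (regular) or basic (irregular) heart rate in bpm,
#'   `[50, 180]`.
#' @param rr_sd RR-interval standard deviation in ms (regular signals).
#' @param irregular_times Number of premature groups (irregular signals).
#' @param snr_db Optional white-noise SNR in dB.
#' @param noise_amplitude,noise_frequency Optional equal-length vectors of
#'   sinusoidal noise components.
#' @param seed Integer seed controlling every random draw of the run.
#' @return A `synthesis_config` object (validated list).
#' @export
synthesis_config <- function(signal_type = "regular", fs = 125,
                             length_s = 10, mean_hr = 60, rr_sd = 0,
                             irregular_times = 0, snr_db = NULL,
                             noise_amplitude = NULL, noise_frequency = NULL,
                             seed = 1L) {
  signal_type <- match.arg(signal_type, c("regular", "compensation",
                                          "reset", "interpolation"))
  cfg <- structure(
    list(signal_type = signal_type, fs = fs, length_s = length_s,
         mean_hr = mean_hr, rr_sd = rr_sd,
         irregular_times = as.integer(irregular_times),
         snr_db = snr_db, noise_amplitude = noise_amplitude,
         noise_frequency = noise_frequency, seed = as.integer(seed)),
    class = "synthesis_config")
  # fail fast on structurally impossible noise lists; range rules are left
  # to validate_config so they can be reported together
  if (length(noise_amplitude) != length(noise_frequency))
    stop("'noise_amplitude' and 'noise_frequency' must have the same ",
         "number of values", call. = FALSE)
  cfg
}

#' Run the full synthesis pipeline
#'
#' Validates the configuration, seeds the RNG, then runs schedule ->
#' premature-group insertion -> assembly -> junction smoothing -> noise, in
#' that fixed order (a single RNG stream, so seeds are stable across feature
#' toggles that are off). Identical (config, seed) pairs give bit-identical
#' records. If `out` is given the record is also written via
#' [write_record()].
#'
#' @param config A [synthesis_config()].
#' @param out Optional output path for the CSV (+ sidecar).
#' @return The synthesized `ppg_record`, invisibly when written to disk.
#' @examples
#' rec <- run_synthesis(synthesis_config(length_s = 5, seed = 42))
#' length(rec$samples) # 625
#' @export
run_synthesis <- function(config, out = NULL) {
  stopifnot(inherits(config, "synthesis_config"))
  msgs <- validate_config(config)
  soft <- grepl("irregular_times is 0", msgs)
  if (any(soft)) warning(msgs[soft], call. = FALSE)
  if (any(!soft))
    stop("invalid configuration:\n  ", paste(msgs[!soft], collapse = "\n  "),
         call. = FALSE)

  set.seed(config$seed)
  sched <- regular_schedule(config$mean_hr, config$rr_sd, config$length_s)
  tpl <- template_set(config$signal_type)
  if (config$signal_type != "regular" && config$irregular_times > 0)
    sched <- insert_premature_groups(sched, config$signal_type,
                                     count = config$irregular_times,
                                     ratios = tpl$ratios)
  rec <- assemble_signal(sched, tpl, config$fs, config$length_s)
  rec <- spline_smooth(rec)
  spec <- noise_spec(config$snr_db, config$noise_amplitude,
                     config$noise_frequency)
  if (!is.null(spec$snr_db) || length(spec$amplitude))
    rec <- add_noise(rec, spec)
  rec$meta$config <- unclass(config)
  rec$meta$version <- as.character(utils::packageVersion("ppgsim"))
  if (!is.null(out)) {
    write_record(rec, out)
    return(invisible(rec))
  }
  rec
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a PPG record to CSV with a JSON annotation sidecar
#'
#' The CSV has header `time_s,ppg`, one row per sample, '.' decimal
#' separator, LF line endings and 15-significant-digit numbers (so a
#' round-trip through [read_record()] reproduces the samples to better than
#' 1e-12). The sidecar `<stem>.annotations.json` carries sampling rate,
#' onsets (0-based sample indices), per-beat labels and the full
#' configuration + seed; see `inst/extdata/record.schema.json` for its
#' schema.
#'
#' @param record A `ppg_record`.
#' @param path Output CSV path.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = "csv") {
  stopifnot(inherits(record, "ppg_record"))
  format <- match.arg(format, "csv")
  t <- (seq_along(record$samples) - 1) / record$fs
  lines <- c("time_s,ppg",
             paste(fmt_num(t), fmt_num(record$samples), sep = ","))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop("cannot write to ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")

  side <- list(
    fs = record$fs,
    n_samples = length(record$samples),
    onsets = record$onsets,
    beats = if (!is.null(record$beats) && nrow(record$beats))
      record$beats[, c("duration_ms", "role", "group_type")]
    else data.frame(duration_ms = numeric(0), role = character(0),
                    group_type = character(0)),
    meta = record$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".annotations.json")
}

#' Read a PPG record written by [write_record()]
#'
#' Inverse of [write_record()] for the CSV + sidecar pair. A malformed CSV
#' cell is a parse error naming the offending line; a missing sidecar gives
#' a record with empty annotations and a warning.
#'
#' @param path Path to the CSV file.
#' @return A `ppg_record`.
#' @export
read_record <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "time_s,ppg")
    stop("not a PPG record CSV (expected header 'time_s,ppg'): ", path,
         call. = FALSE)
  body <- lines[-1]
  cells <- strsplit(body, ",", fixed = TRUE)
  bad_shape <- which(lengths(cells) != 2L)
  if (length(bad_shape))
    stop("parse error in ", path, " at line ", bad_shape[1] + 1L,
         ": expected two comma-separated values", call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
              ncol = 2, byrow = TRUE)
  bad <- which(apply(is.na(m), 1, any))
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1] + 1L,
         ": non-numeric value", call. = FALSE)
  samples <- m[, 2]

  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    warning("annotation sidecar not found (", sp,
            "); returning record with empty annotations", call. = FALSE)
    dt <- diff(m[, 1])
    fs <- if (length(dt)) 1 / stats::median(dt) else 1
    return(new_ppg_record(samples, fs, integer(0),
                          data.frame(duration_ms = numeric(0),
                                     role = character(0),
                                     group_type = character(0)),
                          meta = list()))
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  beats <- as.data.frame(side$beats)
  new_ppg_record(samples, side$fs, as.integer(side$onsets), beats,
                 meta = as.list(side$meta))
}

#' Structurally validate an annotation sidecar
#'
#' Checks a parsed sidecar (or a path to one) against the shipped schema's
#' structural requirements: required fields present, correct types, onsets
#' sorted starting at 0 and consistent with `n_samples`.
#'
#' @param x A path to an `.annotations.json` file or an already-parsed list.
#' @return Character vector of problems (empty if valid).
#' @export
validate_sidecar <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  probs <- character(0)
  need <- c("fs", "n_samples", "onsets", "beats", "meta")
  miss <- setdiff(need, names(x))
  if (length(miss))
    return(paste("missing field:", miss))
  if (!is.numeric(x$fs) || x$fs <= 0) probs <- c(probs, "fs must be > 0")
  if (!is.numeric(x$n_samples) || x$n_samples < 1)
    probs <- c(probs, "n_samples must be >= 1")
  ons <- x$onsets
  if (length(ons)) {
    if (!is.numeric(ons) || ons[1] != 0 ||
        is.unsorted(ons, strictly = TRUE) || any(ons >= x$n_samples))
      probs <- c(probs, "onsets must start at 0, increase strictly and stay below n_samples")
  }
  b <- x$beats
  if (!all(c("duration_ms", "role", "group_type") %in% names(b)))
    probs <- c(probs, "beats must have duration_ms, role, group_type")
  else {
    if (!all(b$role %in% c("reference", "first", "second")))
      probs <- c(probs, "invalid beat role")
    if (!all(b$group_type %in% c("none", "compensation", "reset",
                                 "interpolation")))
      probs <- c(probs, "invalid group_type")
  }
  probs
}
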