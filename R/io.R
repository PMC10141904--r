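## Readers and writers for recordings, ground truths, manifests and latency
## artifacts. Recordings travel as HDF5 (dataset /signal, attributes
## sampling_rate and start_time) or long-format CSV (time_s, channel, value).

#' Write a recording to HDF5
#'
#' Layout: dataset `/signal` (n_samples x n_sensors), attributes
#' `sampling_rate`, `start_time`, `case_id`, `night_index`.
#'
#' @param rec an `smrr_recording`.
#' @param path output file path.
#' @param start_time recording start, seconds since epoch (metadata only).
#' @return `path`, invisibly.
#' @export
write_recording_h5 <- function(rec, path, start_time = 0) {
  stopifnot(inherits(rec, "smrr_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$signal, path, "signal")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "signal")
  rhdf5::h5writeAttribute(rec$sampling_rate, did, "sampling_rate")
  rhdf5::h5writeAttribute(start_time, did, "start_time")
  rhdf5::h5writeAttribute(rec$case_id, did, "case_id")
  rhdf5::h5writeAttribute(rec$night_index, did, "night_index")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Write a recording as long-format CSV (`time_s`, `channel`, `value`)
#' @inheritParams write_recording_h5
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "smrr_recording"))
  n <- nrow(rec$signal); nc <- ncol(rec$signal)
  df <- data.frame(time_s = rep((seq_len(n) - 1) / rec$sampling_rate, nc),
                   channel = rep(seq_len(nc), each = n),
                   value = as.vector(rec$signal))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from HDF5, CSV or EDF
#'
#' CSV input is re-gridded to a uniform 54 Hz series by linear interpolation
#' when timestamps are irregular or gappy (the device reports an *average*
#' rate); gaps are repaired, and the repair is reported via a message. EDF is
#' not supported in this build (no EDF reader in the supported dependency
#' set) and raises an error.
#'
#' @param path input file.
#' @param format `"hdf5"`, `"csv"` or `"edf"`; default guessed from the
#'   extension.
#' @param sampling_rate target rate for CSV re-gridding.
#' @return an `smrr_recording`.
#' @export
read_recording <- function(path, format = c("auto", "hdf5", "csv", "edf"),
                           sampling_rate = 54) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     h5 = , hdf5 = "hdf5", csv = "csv", edf = "edf",
                     stop("read_recording: cannot guess format of ", path))
  }
  if (format == "edf")
    stop("read_recording: EDF input is not supported in this build; ",
         "convert to HDF5 or CSV")
  if (format == "hdf5") {
    sig <- rhdf5::h5read(path, "signal")
    at <- rhdf5::h5readAttributes(path, "signal")
    if (is.null(at$sampling_rate))
      stop("read_recording: sampling_rate attribute missing (never guessed)")
    return(structure(list(signal = as.matrix(sig),
                          sampling_rate = as.numeric(at$sampling_rate),
                          case_id = if (!is.null(at$case_id)) as.character(at$case_id) else "unknown",
                          night_index = if (!is.null(at$night_index)) as.integer(at$night_index) else 1L),
                     class = "smrr_recording"))
  }
  ## CSV
  df <- utils::read.csv(path)
  need <- c("time_s", "channel", "value")
  if (!all(need %in% names(df)))
    stop("read_recording: CSV must have columns time_s, channel, value")
  chans <- sort(unique(df$channel))
  t_max <- max(df$time_s)
  tt <- seq(0, t_max, by = 1 / sampling_rate)
  sig <- matrix(NA_real_, length(tt), length(chans))
  gap_repaired <- FALSE
  for (j in seq_along(chans)) {
    d <- df[df$channel == chans[j], ]
    d <- d[order(d$time_s), ]
    if (any(diff(d$time_s) > 1.5 / sampling_rate)) gap_repaired <- TRUE
    sig[, j] <- stats::approx(d$time_s, d$value, xout = tt, rule = 2)$y
  }
  if (gap_repaired)
    message("read_recording: irregular/gappy timestamps linearly interpolated to ",
            sampling_rate, " Hz")
  structure(list(signal = sig, sampling_rate = sampling_rate,
                 case_id = "unknown", night_index = 1L),
            class = "smrr_recording")
}

#' Write/read a ground-truth table as CSV
#' @param truth ground-truth data frame (see [generate_night()]).
#' @param path file path.
#' @param night night index column value.
#' @export
write_truth_csv <- function(truth, path, night = 1L) {
  out <- cbind(night = as.integer(night), truth)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) utils::read.csv(path)

#' Write a cohort manifest as CSV
#' @param manifest manifest data frame.
#' @param path file path.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.csv(path)
}

#' Write a case latency profile to JSON
#' @param profile an `smrr_profile`.
#' @param path file path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(case_id = profile$case_id, maxima_ms = profile$maxima_ms,
         breaks_ms = profile$breaks_ms, density = profile$density,
         n_usable_windows = profile$n_usable_windows,
         low_coverage = profile$low_coverage),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(case_id = j$case_id, maxima_ms = as.numeric(j$maxima_ms),
                 breaks_ms = as.numeric(j$breaks_ms),
                 density = as.numeric(j$density),
                 n_usable_windows = as.integer(j$n_usable_windows),
                 low_coverage = isTRUE(j$low_coverage)),
            class = "smrr_profile")
}
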