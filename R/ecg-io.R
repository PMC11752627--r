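# Record container and dataset loading for the PhysioNet/CinC 2017 layout:
# per-record `<id>.mat` (int16 row vector `val`) + `<id>.hea`, labels in
# `REFERENCE.csv` (record_id,label with classes N, A, O, ~).

#' Construct a single-lead ECG record
#'
#' @param record_id record identifier.
#' @param signal numeric vector of samples in millivolts.
#' @param fs sampling rate in Hz (> 0).
#' @param label one of `"N"`, `"A"`, `"O"`, `"~"` or `"unknown"`.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs, label = "unknown") {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar")
  }
  if (length(signal) < 1L) stop("signal must hold at least one sample")
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  if (!label %in% c(ecg_classes(), "unknown")) {
    stop("label must be one of N, A, O, ~, unknown")
  }
  structure(
    list(record_id = record_id, signal = as.double(signal),
         fs = as.double(fs), label = label),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.1f s), label %s>\n",
              x$record_id, length(x$signal), x$fs,
              length(x$signal) / x$fs, x$label))
  invisible(x)
}

#' Duration of a record or segment in seconds
#' @param x an `ecg_record` or `ecg_segment`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) {
  n <- if (!is.null(x$signal)) length(x$signal) else length(x$samples)
  n / x$fs
}

#' Read one CinC 2017-style record
#'
#' Reads the MAT sample container and its WFDB-style header, converting ADC
#' units to millivolts with the header's gain. When the header is absent the
#' CinC 2017 conventions apply (300 Hz, 1000 ADC units/mV). Amplitudes are
#' reported in millivolts by convention; the source format does not state
#' units and the gain line is trusted as units-per-mV.
#'
#' @param record_path path to the `.mat` container.
#' @param header_path path to the `.hea` header; defaults to the `.mat` path
#'   with its extension replaced.
#' @param label class label to attach.
#' @return an [ecg_record()].
#' @export
read_record <- function(record_path, header_path = NULL, label = "unknown") {
  if (is.null(header_path)) {
    header_path <- sub("\\.mat$", ".hea", record_path)
  }
  raw_samples <- read_mat_val(record_path)
  if (length(raw_samples) == 0L) stop("empty record container: ", record_path)
  fs <- 300
  gain <- 1000
  record_id <- sub("\\.mat$", "", basename(record_path))
  if (file.exists(header_path)) {
    hdr <- read_wfdb_header(header_path)
    fs <- hdr$fs
    gain <- hdr$gain
    record_id <- hdr$record_id
  }
  ecg_record(record_id, raw_samples / gain, fs, label)
}

#' Write a record in the CinC 2017 layout
#'
#' Emits `<id>.mat` (int16 `val` vector, millivolts times gain) plus
#' `<id>.hea`. Inverse of [read_record()] up to int16 quantisation; with the
#' default gain of 1000 a signal already quantised to 1e-3 mV round-trips
#' bitwise.
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param gain ADC units per millivolt.
#' @return the `.mat` path, invisibly.
#' @export
write_record <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  mat_path <- file.path(dir, paste0(record$record_id, ".mat"))
  write_mat_val(round(record$signal * gain), mat_path, int16 = TRUE)
  write_wfdb_header(record$record_id, length(record$signal),
                    file.path(dir, paste0(record$record_id, ".hea")),
                    fs = record$fs, gain = gain)
  invisible(mat_path)
}

#' Read a class-label table (REFERENCE.csv layout)
#'
#' Two comma-separated columns, `record_id,label`, no header row. Labels are
#' restricted to the closed set N, A, O, `~`; duplicates and unknown symbols
#' are format errors.
#'
#' @param csv_path path to the labels file.
#' @return data.frame with columns `record_id`, `label`.
#' @export
read_labels <- function(csv_path) {
  tab <- utils::read.csv(csv_path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("record_id", "label"),
                         colClasses = "character", strip.white = TRUE)
  if (anyDuplicated(tab$record_id)) {
    stop("duplicate record_id in labels file: ",
         paste(unique(tab$record_id[duplicated(tab$record_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(tab$label), ecg_classes())
  if (length(bad) > 0L) {
    stop("labels outside {N, A, O, ~}: ", paste(bad, collapse = ", "))
  }
  tab
}

#' Load a directory of records with labels attached
#'
#' Reads every `.mat`/`.hea` pair, attaches labels from a REFERENCE.csv-style
#' table (records without a table entry get label `"unknown"`), and returns
#' the records ordered by record id. Records that fail to parse are skipped
#' with a warning and counted in the `skipped` attribute unless
#' `strict = TRUE`.
#'
#' @param records_dir directory of record/header pairs.
#' @param labels_path optional path to the labels csv.
#' @param strict abort on the first unreadable record instead of skipping.
#' @return list of [ecg_record()]s, ordered by id, with attribute `skipped`.
#' @export
load_dataset <- function(records_dir, labels_path = NULL, strict = FALSE) {
  if (!dir.exists(records_dir)) stop("records directory not found: ", records_dir)
  mats <- sort(list.files(records_dir, pattern = "\\.mat$", full.names = TRUE))
  labels <- NULL
  if (!is.null(labels_path)) labels <- read_labels(labels_path)
  records <- list()
  skipped <- 0L
  for (p in mats) {
    rec <- tryCatch(read_record(p), error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) stop("failed to read ", p, ": ", conditionMessage(rec))
      warning("skipping unreadable record ", basename(p), ": ",
              conditionMessage(rec), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    if (!is.null(labels)) {
      hit <- match(rec$record_id, labels$record_id)
      rec$label <- if (is.na(hit)) "unknown" else labels$label[[hit]]
    }
    records[[length(records) + 1L]] <- rec
  }
  ord <- order(vapply(records, function(r) r$record_id, character(1)))
  records <- records[ord]
  attr(records, "skipped") <- skipped
  records
}
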