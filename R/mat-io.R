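# Minimal MATLAB v5 MAT container support for single-variable numeric row
# vectors (the PhysioNet/CinC 2017 record layout: one int16 vector named
# `val`). Little-endian files only; the small-data-element encoding used by
# MATLAB for short variable names is understood on read.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L
MX_DOUBLE <- 6L; MX_INT16 <- 10L

pad8 <- function(n) (8L - (n %% 8L)) %% 8L

#' Write a one-variable MAT v5 container
#'
#' Writes a numeric vector as a 1 x n row vector named `val`, int16 by
#' default (the CinC 2017 convention). Used by the synthetic-data writer and
#' the test fixtures; round-trips through [read_mat_val()].
#'
#' @param x numeric vector of samples (integer ADC units for int16 storage).
#' @param path output file path.
#' @param int16 store as 16-bit integers (default) or doubles.
#' @return `path`, invisibly.
#' @export
write_mat_val <- function(x, path, int16 = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by afwave")
  hdr <- charToRaw(desc)
  hdr <- c(hdr, raw(116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(c(as.raw(0x00), as.raw(0x01)), con) # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)               # endian indicator

  n <- length(x)
  data_type <- if (int16) MI_INT16 else MI_DOUBLE
  elt_size <- if (int16) 2L else 8L
  data_bytes <- n * elt_size
  body_bytes <- 8L + 8L +                      # array flags
    8L + 8L +                                  # dims (2 int32 + pad)
    8L + 8L +                                  # name "val" padded
    8L + data_bytes + pad8(data_bytes)

  writeBin(c(MI_MATRIX, body_bytes), con, size = 4L, endian = "little")
  writeBin(c(MI_UINT32, 8L), con, size = 4L, endian = "little")
  writeBin(c(if (int16) MX_INT16 else MX_DOUBLE, 0L), con,
           size = 4L, endian = "little")
  writeBin(c(MI_INT32, 8L), con, size = 4L, endian = "little")
  writeBin(c(1L, n), con, size = 4L, endian = "little")
  writeBin(c(MI_INT8, 3L), con, size = 4L, endian = "little")
  writeBin(c(charToRaw("val"), raw(5L)), con)
  writeBin(c(data_type, data_bytes), con, size = 4L, endian = "little")
  if (int16) {
    stopifnot(all(abs(x) <= 32767))
    writeBin(as.integer(round(x)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 8L, endian = "little")
  }
  if (pad8(data_bytes) > 0L) writeBin(raw(pad8(data_bytes)), con)
  invisible(path)
}

read_tag <- function(con) {
  word <- readBin(con, "raw", n = 4L)
  if (length(word) < 4L) return(NULL)
  # small data element: upper 16 bits of the first word hold the byte count
  small_bytes <- as.integer(word[3]) + 256L * as.integer(word[4])
  type <- as.integer(word[1]) + 256L * as.integer(word[2])
  if (small_bytes > 0L) {
    list(type = type, bytes = small_bytes, small = TRUE)
  } else {
    bytes <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    list(type = type, bytes = bytes, small = FALSE)
  }
}

read_element_data <- function(con, tag) {
  reader <- switch(as.character(tag$type),
    "1" = function(n) readBin(con, "integer", n, size = 1L, endian = "little"),
    "2" = function(n) readBin(con, "integer", n, size = 1L, signed = FALSE, endian = "little"),
    "3" = function(n) readBin(con, "integer", n, size = 2L, endian = "little"),
    "4" = function(n) readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little"),
    "5" = function(n) readBin(con, "integer", n, size = 4L, endian = "little"),
    "6" = function(n) readBin(con, "integer", n, size = 4L, endian = "little"),
    "7" = function(n) readBin(con, "double", n, size = 4L, endian = "little"),
    "9" = function(n) readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported MAT data element type ", tag$type)
  )
  elt_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
                `7` = 4L, `9` = 8L)[[as.character(tag$type)]]
  vals <- reader(tag$bytes %/% elt_size)
  pad <- if (tag$small) (4L - tag$bytes %% 4L) %% 4L else pad8(tag$bytes)
  if (pad > 0L) readBin(con, "raw", n = pad)
  vals
}

#' Read the sample vector from a MAT v5 container
#'
#' Reads the first numeric array variable (named `val` in CinC 2017 records)
#' from a little-endian MATLAB v5 file. Only real int8/16/32, single and
#' double arrays are supported.
#'
#' @param path path to the `.mat` file.
#' @return numeric vector of raw (ADC-unit) samples.
#' @export
read_mat_val <- function(path) {
  if (!file.exists(path)) stop("MAT file not found: ", path)
  if (file.size(path) <= 128) stop("empty MAT container: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 128L)
  endian <- rawToChar(hdr[127:128])
  if (endian != "IM") stop("not a little-endian MAT v5 file: ", path)
  tag <- read_tag(con)
  if (is.null(tag) || tag$type != MI_MATRIX) {
    stop("no matrix variable found in ", path)
  }
  flags_tag <- read_tag(con)
  flags <- read_element_data(con, flags_tag)
  dims_tag <- read_tag(con)
  dims <- read_element_data(con, dims_tag)
  name_tag <- read_tag(con)
  name_raw <- read_element_data(con, name_tag)
  data_tag <- read_tag(con)
  if (!data_tag$type %in% c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 9L)) {
    stop("non-numeric sample data in ", path)
  }
  vals <- read_element_data(con, data_tag)
  if (length(vals) != prod(dims)) {
    stop("truncated sample data in ", path)
  }
  as.double(vals)
}

#' Write a WFDB-style header for a single-signal record
#'
#' @param record_id record name (also used for the `.mat` file reference).
#' @param n_samples number of samples.
#' @param path output `.hea` path.
#' @param fs sampling rate in Hz.
#' @param gain ADC units per millivolt.
#' @return `path`, invisibly.
#' @export
write_wfdb_header <- function(record_id, n_samples, path, fs = 300, gain = 1000) {
  lines <- c(
    sprintf("%s 1 %g %d", record_id, fs, n_samples),
    sprintf("%s.mat 16 %g/mV 16 0 0 0 0 ECG", record_id, gain)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a WFDB-style header
#'
#' Extracts sampling rate and ADC gain from a two-line `.hea` file. Missing
#' fields fall back to the CinC 2017 conventions: 300 Hz and 1000 ADC units
#' per millivolt.
#'
#' @param path path to the `.hea` file.
#' @return list with `record_id`, `fs`, `n_samples`, `gain`.
#' @export
read_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty header: ", path)
  top <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  fs <- if (length(top) >= 3L) suppressWarnings(as.numeric(top[[3L]])) else NA_real_
  if (is.na(fs) || fs <= 0) fs <- 300
  n_samples <- if (length(top) >= 4L) suppressWarnings(as.integer(top[[4L]])) else NA_integer_
  gain <- 1000
  if (length(lines) >= 2L) {
    sig <- strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]
    if (length(sig) >= 3L) {
      g <- suppressWarnings(as.numeric(sub("/.*$", "", sig[[3L]])))
      if (!is.na(g) && g > 0) gain <- g
    }
  }
  list(record_id = top[[1L]], fs = fs, n_samples = n_samples, gain = gain)
}
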