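# Duration-based preprocessing: keep a fixed-length cut from each record
# (default the first 30 s), exclude records that fall short, and resample
# kept cuts to the analysis rate (default 128 Hz).

#' Construct an ECG segment
#'
#' @param record_id source record id.
#' @param samples numeric vector in millivolts.
#' @param fs sampling rate in Hz.
#' @param label class symbol.
#' @param source_start 0-based index of the first sample in the source record.
#' @return object of class `ecg_segment`.
#' @export
ecg_segment <- function(record_id, samples, fs, label = "unknown",
                        source_start = 0L) {
  stopifnot(fs > 0, source_start >= 0)
  structure(
    list(record_id = record_id, samples = as.double(samples),
         fs = as.double(fs), label = label,
         source_start = as.integer(source_start)),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment %s: %d samples @ %g Hz, label %s, start %d>\n",
              x$record_id, length(x$samples), x$fs, x$label, x$source_start))
  invisible(x)
}

is_excluded <- function(x) inherits(x, "afw_excluded")

#' Cut a fixed-duration segment from a record
#'
#' Records whose duration is at least `target_duration_s` contribute one cut
#' of `round(target_duration_s * fs)` samples starting at `offset_s` (default
#' the beginning of the record); shorter records are excluded. The cut window
#' is half-open in sample indices, `[start, start + n)`.
#'
#' @param record an [ecg_record()].
#' @param target_duration_s target cut duration in seconds (> 0).
#' @param offset_s start of the cut within the record, seconds.
#' @return an [ecg_segment()], or an exclusion marker (class `afw_excluded`)
#'   when the record is too short. Test with [is_excluded] via
#'   `inherits(x, "afw_excluded")`.
#' @export
segment_record <- function(record, target_duration_s = 30, offset_s = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(target_duration_s) || target_duration_s <= 0) {
    stop("target_duration_s must be positive")
  }
  n_target <- round(target_duration_s * record$fs)
  start <- round(offset_s * record$fs)
  if (length(record$signal) < n_target + start) {
    return(structure(list(record_id = record$record_id, label = record$label),
                     class = "afw_excluded"))
  }
  ecg_segment(record$record_id,
              record$signal[(start + 1L):(start + n_target)],
              record$fs, record$label, source_start = start)
}

#' Apply the duration filter to a dataset
#'
#' @param records list of [ecg_record()]s.
#' @param target_duration_s cut duration in seconds.
#' @param offset_s cut offset in seconds.
#' @return list with `segments` (kept [ecg_segment()]s, input order) and
#'   `summary`: `kept`, `excluded` counts plus `per_class_kept`.
#' @export
filter_dataset <- function(records, target_duration_s = 30, offset_s = 0) {
  out <- lapply(records, segment_record,
                target_duration_s = target_duration_s, offset_s = offset_s)
  keep <- !vapply(out, is_excluded, logical(1))
  segments <- out[keep]
  labels <- vapply(segments, function(s) s$label, character(1))
  per_class <- as.list(table(factor(labels, levels = c(ecg_classes(), "unknown"))))
  per_class <- per_class[vapply(per_class, function(v) v > 0, logical(1))]
  summary <- structure(
    list(kept = sum(keep), excluded = sum(!keep),
         per_class_kept = lapply(per_class, as.integer)),
    class = "filter_summary"
  )
  list(segments = segments, summary = summary)
}

#' @export
print.filter_summary <- function(x, ...) {
  cat(sprintf("<filter_summary: kept %d, excluded %d>\n", x$kept, x$excluded))
  if (length(x$per_class_kept)) {
    cat("  per class:",
        paste(sprintf("%s=%d", names(x$per_class_kept),
                      unlist(x$per_class_kept)), collapse = ", "), "\n")
  }
  invisible(x)
}

# Fourier-domain resampling of a real vector to n_out samples. Exact for
# content band-limited below both Nyquist rates; chosen over the installed
# polyphase resampler, whose uncompensated group delay and passband ripple
# break the band-limited round-trip guarantee documented in the vignette.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  keep <- min(n, n_out)
  half <- keep %/% 2L
  # positive frequencies (incl. DC)
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  # negative frequencies
  if (half >= 1L) {
    Y[(n_out - half + 1L):n_out] <- X[(n - half + 1L):n]
  }
  if (keep %% 2L == 0L) {
    # shared Nyquist bin: split to keep the result real and energy balanced
    nyq <- X[half + 1L]
    if (n_out > n) {
      Y[half + 1L] <- nyq / 2
      Y[n_out - half + 1L] <- Conj(nyq) / 2
    } else {
      Y[half + 1L] <- Re(nyq)
    }
  }
  # unnormalised inverse FFT: /n_out for the transform, * n_out/n for
  # amplitude preservation, net /n
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a segment to the analysis rate
#'
#' Fourier-domain rate conversion (spectral content below the lower Nyquist
#' frequency is preserved exactly). Output length is
#' `round(duration * fs_target)`; the identity when `fs_target == fs`.
#'
#' @param segment an [ecg_segment()].
#' @param fs_target target sampling rate in Hz (> 0), default 128.
#' @return resampled [ecg_segment()].
#' @export
resample_segment <- function(segment, fs_target = 128) {
  stopifnot(inherits(segment, "ecg_segment"))
  if (!is.numeric(fs_target) || length(fs_target) != 1L || fs_target <= 0) {
    stop("fs_target must be a positive scalar")
  }
  if (fs_target == segment$fs) return(segment)
  n_out <- round(length(segment$samples) / segment$fs * fs_target)
  y <- resample_fft(segment$samples, n_out)
  ecg_segment(segment$record_id, y, fs_target, segment$label,
              segment$source_start)
}
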