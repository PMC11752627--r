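# Short-time Fourier transform with a symmetric Hamming window and one-sided
# spectrum, the spectrogram branch of the time-frequency stage.

#' Symmetric Hamming window
#'
#' `w[n] = 0.54 - 0.46 * cos(2*pi*n / (L-1))`, `n = 0..L-1`; length 1 returns
#' 1 by convention.
#'
#' @param length window length (>= 1).
#' @return numeric weight vector.
#' @export
hamming_window <- function(length) {
  if (!is.numeric(length) || length < 1) stop("window length must be >= 1")
  length <- as.integer(length)
  if (length == 1L) return(1)
  n <- 0:(length - 1L)
  0.54 - 0.46 * cos(2 * pi * n / (length - 1L))
}

#' Short-time Fourier transform
#'
#' Frames the signal with a hop of `window_length - overlap`, applies the
#' Hamming window, and keeps the one-sided spectrum (`window_length/2 + 1`
#' bins). Frame count is `floor((N - window_length) / hop) + 1`; no
#' zero-padding beyond the window.
#'
#' @param signal numeric vector (length >= `window_length`).
#' @param fs sampling rate in Hz.
#' @param window_length Hamming window length in samples.
#' @param overlap overlap between consecutive frames, `0 <= overlap <
#'   window_length`.
#' @return object of class `spectrogram`: complex `values`
#'   (bins x frames), `frame_times` (frame centers, s), `bin_freqs` (Hz).
#' @export
stft <- function(signal, fs, window_length = 256, overlap = 128) {
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= window_length) {
    stop("overlap must satisfy 0 <= overlap < window_length")
  }
  n <- length(signal)
  if (n < window_length) stop("signal shorter than the analysis window")
  hop <- window_length - overlap
  n_frames <- (n - window_length) %/% hop + 1L
  n_bins <- window_length %/% 2L + 1L
  w <- hamming_window(window_length)
  values <- matrix(complex(real = 0), nrow = n_bins, ncol = n_frames)
  starts <- (seq_len(n_frames) - 1L) * hop         # 0-based frame starts
  for (j in seq_len(n_frames)) {
    frame <- signal[(starts[j] + 1L):(starts[j] + window_length)] * w
    values[, j] <- stats::fft(frame)[1:n_bins]
  }
  structure(
    list(values = values,
         frame_times = (starts + (window_length - 1) / 2) / fs,
         bin_freqs = (0:(n_bins - 1L)) * fs / window_length,
         fs = fs, window_length = window_length, overlap = overlap),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d bins x %d frames, 0-%g Hz>\n",
              nrow(x$values), ncol(x$values), max(x$bin_freqs)))
  invisible(x)
}
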