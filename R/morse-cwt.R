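# Generalized Morse continuous wavelet transform. The analytic Morse wavelet
# is defined in the frequency domain as a power law times a stretched
# exponential,
#
#   Psi(w) = U(w) * c * w^beta * exp(-w^gamma),
#
# parameterised by the shape exponent gamma and the time-bandwidth product
# P^2 = beta * gamma (the "(gamma, P^2)" convention, so Morse (3, 60) means
# gamma = 3, beta = 20). The peak angular frequency is
# w_p = (beta/gamma)^(1/gamma). The transform is computed per scale by
# frequency-domain multiplication of the signal spectrum with the scaled
# wavelet response followed by an inverse FFT.

#' Generalized Morse wavelet parameters
#'
#' @param gamma shape exponent (> 0); 3 gives the symmetric "Airy" family.
#' @param time_bandwidth time-bandwidth product P^2 (> 0); `beta =
#'   time_bandwidth / gamma`.
#' @param voices_per_octave number of scales per frequency octave (>= 1).
#' @param normalization `"L1"` (unit-amplitude response for a unit sinusoid;
#'   rendering convention) or `"L2"` (the 1/sqrt(a) integral-transform
#'   convention).
#' @return object of class `morse_params` with derived `beta` and peak
#'   angular frequency `omega_p`.
#' @export
morse_params <- function(gamma = 3, time_bandwidth = 60,
                         voices_per_octave = 10,
                         normalization = c("L1", "L2")) {
  normalization <- match.arg(normalization)
  if (gamma <= 0) stop("gamma must be positive")
  if (time_bandwidth <= 0) stop("time_bandwidth must be positive")
  voices_per_octave <- as.integer(voices_per_octave)
  if (voices_per_octave < 1L) stop("voices_per_octave must be >= 1")
  beta <- time_bandwidth / gamma
  omega_p <- (beta / gamma)^(1 / gamma)
  if (!is.finite(omega_p) || omega_p <= 0) stop("degenerate Morse parameters")
  structure(
    list(gamma = gamma, beta = beta, time_bandwidth = time_bandwidth,
         voices_per_octave = voices_per_octave,
         normalization = normalization, omega_p = omega_p),
    class = "morse_params"
  )
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf(
    "<morse_params: gamma %g, P^2 %g (beta %g), %d voices/octave, %s norm>\n",
    x$gamma, x$time_bandwidth, x$beta, x$voices_per_octave, x$normalization))
  invisible(x)
}

#' Morse wavelet frequency response
#'
#' Evaluates the analytic Morse wavelet in the frequency domain,
#' peak-normalised so the response at the peak angular frequency
#' `omega_p = (beta/gamma)^(1/gamma)` equals 2 at every scale (the analytic
#' one-sided convention: a unit real sinusoid then transforms to unit
#' magnitude under L1 normalisation). Zero for `omega <= 0` (admissibility:
#' no DC or negative-frequency content).
#'
#' @param omega angular frequency (rad/sample or rad/s, the wavelet is
#'   dimensionless), vectorised.
#' @param params a [morse_params()].
#' @return response values, same length as `omega`.
#' @export
morse_wavelet_freq <- function(omega, params) {
  stopifnot(inherits(params, "morse_params"))
  out <- numeric(length(omega))
  pos <- which(omega > 0)
  if (length(pos)) {
    w <- omega[pos]
    log_peak <- params$beta * log(params$omega_p) - params$omega_p^params$gamma
    out[pos] <- 2 * exp(params$beta * log(w) - w^params$gamma - log_peak)
  }
  out
}

# Time-domain standard deviation (in samples at unit scale) of the Morse
# envelope, approximated by the time-bandwidth relation sigma ~ P / omega_p.
morse_sigma_t <- function(params) {
  sqrt(params$time_bandwidth) / params$omega_p
}

#' Design a Morse CWT filter bank
#'
#' Scales are geometric with ratio `2^(1/voices_per_octave)`. The smallest
#' scale places the wavelet peak at the Nyquist frequency; the largest is
#' bounded so two time-domain standard deviations of the wavelet fit inside
#' the signal. Filters are sampled on the length-`n_samples` FFT grid and
#' vanish at frequency zero.
#'
#' @param n_samples FFT grid length (>= 4).
#' @param fs sampling rate in Hz.
#' @param params a [morse_params()].
#' @return object of class `filter_bank`: `scales` (ascending),
#'   `center_freqs` (Hz, descending), `filters` (scales x n_samples real
#'   matrix), `params`, `fs`, `n_samples`.
#' @export
design_filter_bank <- function(n_samples, fs, params = morse_params()) {
  stopifnot(inherits(params, "morse_params"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (fs <= 0) stop("fs must be positive")
  a_min <- params$omega_p / pi
  a_max <- n_samples / (2 * morse_sigma_t(params))
  if (a_max < a_min * 2) {
    stop("signal too short to fit one octave of Morse scales")
  }
  n_scales <- floor(params$voices_per_octave * log2(a_max / a_min)) + 1L
  scales <- a_min * 2^((seq_len(n_scales) - 1L) / params$voices_per_octave)
  center_freqs <- params$omega_p * fs / (2 * pi * scales)
  omega_k <- 2 * pi * (0:(n_samples - 1L)) / n_samples   # rad/sample
  # only the one-sided grid carries support (analytic wavelet)
  omega_k[omega_k > pi] <- -1                            # negative freqs -> 0
  filters <- matrix(0, nrow = n_scales, ncol = n_samples)
  for (j in seq_len(n_scales)) {
    filters[j, ] <- morse_wavelet_freq(scales[j] * omega_k, params)
  }
  structure(
    list(params = params, scales = scales, center_freqs = center_freqs,
         filters = filters, fs = fs, n_samples = n_samples),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank: %d scales, %g-%g Hz, %d voices/octave>\n",
              length(x$scales), min(x$center_freqs), max(x$center_freqs),
              x$params$voices_per_octave))
  invisible(x)
}

#' Continuous wavelet transform with a Morse filter bank
#'
#' Computes coefficients `Z(a, b)` per scale by frequency-domain
#' multiplication of the signal spectrum with the scaled wavelet response and
#' an inverse FFT. The signal is extended by reflection to twice its length
#' before transforming, to suppress circular wrap-around; only the original
#' support is returned. Under `"L1"` normalisation a unit sinusoid at a
#' center frequency has unit scalogram magnitude; `"L2"` multiplies each row
#' by `sqrt(a)`, the literal `1/sqrt(a)` integral convention.
#'
#' The cone of influence (`coi`) reports, per time sample, the boundary
#' frequency in Hz below which coefficients are within one e-folding of an
#' edge and should not be trusted.
#'
#' @param signal finite numeric vector, length >= 4.
#' @param fs sampling rate in Hz.
#' @param params a [morse_params()].
#' @param bank optional pre-built [design_filter_bank()] for `2 *
#'   length(signal)` samples (built internally when `NULL`).
#' @return object of class `cwt_coeffs`: complex `values` (scales x time),
#'   `scales`, `center_freqs` (Hz), `times` (s), `coi` (Hz), `fs`, `params`.
#' @export
cwt <- function(signal, fs, params = morse_params(), bank = NULL) {
  if (length(signal) < 4L) stop("signal must hold at least 4 samples")
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  n <- length(signal)
  np <- 2L * n
  if (is.null(bank)) {
    bank <- design_filter_bank(np, fs, params)
  } else {
    stopifnot(inherits(bank, "filter_bank"))
    if (bank$n_samples != np) stop("bank was designed for a different length")
    params <- bank$params
  }
  x_ext <- c(signal, rev(signal))        # reflection extension
  X <- stats::fft(x_ext)
  n_scales <- length(bank$scales)
  values <- matrix(complex(real = 0), nrow = n_scales, ncol = n)
  for (j in seq_len(n_scales)) {
    row <- stats::fft(X * bank$filters[j, ], inverse = TRUE) / np
    if (params$normalization == "L2") row <- row * sqrt(bank$scales[j])
    values[j, ] <- row[1:n]
  }
  sigma <- morse_sigma_t(params)
  dist_edge <- pmin(seq_len(n) - 0.5, n - seq_len(n) + 0.5)
  coi <- pmin(params$omega_p * fs / (2 * pi) * sqrt(2) * sigma / dist_edge,
              fs / 2)
  structure(
    list(values = values, scales = bank$scales,
         center_freqs = bank$center_freqs,
         times = (seq_len(n) - 1L) / fs, coi = coi, fs = fs, params = params),
    class = "cwt_coeffs"
  )
}

#' @export
print.cwt_coeffs <- function(x, ...) {
  cat(sprintf("<cwt_coeffs: %d scales x %d times, %g-%g Hz, %s norm>\n",
              nrow(x$values), ncol(x$values), min(x$center_freqs),
              max(x$center_freqs), x$params$normalization))
  invisible(x)
}

#' Scalogram: elementwise modulus of CWT coefficients
#'
#' @param coeffs a `cwt_coeffs` object or a complex/numeric matrix.
#' @return nonnegative real matrix of the same shape.
#' @export
scalogram <- function(coeffs) {
  if (inherits(coeffs, "cwt_coeffs")) return(Mod(coeffs$values))
  Mod(coeffs)
}

#' Ridge frequency of a coefficient matrix
#'
#' Center frequency of the scale maximising the time-averaged scalogram,
#' restricted to times where the requested fraction of the signal is outside
#' the cone of influence.
#'
#' @param coeffs a `cwt_coeffs` object.
#' @param trim fraction of samples dropped at each edge before averaging.
#' @return frequency in Hz.
#' @export
ridge_frequency <- function(coeffs, trim = 0.1) {
  n <- ncol(coeffs$values)
  keep <- seq.int(max(1L, floor(n * trim)), min(n, ceiling(n * (1 - trim))))
  prof <- rowMeans(Mod(coeffs$values[, keep, drop = FALSE]))
  coeffs$center_freqs[which.max(prof)]
}
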