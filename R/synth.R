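# Synthetic single-lead ECG generator covering the four rhythm classes:
# normal sinus (regular RR, full PQRST morphology), AF-like (irregularly
# irregular RR, absent P waves, 4-10 Hz fibrillatory baseline), other-rhythm
# (interspersed premature ectopic beats with wide, tall morphology), and
# noise (broadband noise plus baseline wander dominating the waveform).
# Morphology is intentionally stylised — Gaussian bumps at fixed offsets —
# which is sufficient to exercise the transforms and the classifier; no
# claim of clinical realism is made.

# P, Q, R, S, T bump parameters: offset from the R peak (s), width (s),
# amplitude (mV).
beat_bumps <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    offset = c(-0.17, -0.035, 0, 0.035, 0.25),
    width = c(0.025, 0.010, 0.012, 0.012, 0.045),
    amp = c(0.15, -0.10, 1.0, -0.25, 0.35)
  )
}

#' Single-beat PQRST template
#'
#' Sum of five Gaussian bumps (P, Q, R, S, T) at fixed offsets relative to
#' the R peak, amplitudes (0.15, -0.10, 1.0, -0.25, 0.35) mV; the R bump is
#' the global maximum. Support spans -0.25 s to +0.45 s around R.
#'
#' @param fs sampling rate in Hz.
#' @param p_wave include the P bump (absent in the AF-like preset).
#' @param qrs_scale width multiplier for the QRS bumps (> 1 gives the wide
#'   ectopic morphology).
#' @param amp overall amplitude multiplier.
#' @return numeric waveform with attribute `r_index` (1-based R-peak sample).
#' @export
synth_beat_template <- function(fs, p_wave = TRUE, qrs_scale = 1,
                                amp = 1) {
  stopifnot(fs > 0)
  t <- seq(-0.25, 0.45, by = 1 / fs)
  bumps <- beat_bumps()
  if (!p_wave) bumps <- bumps[bumps$wave != "P", ]
  y <- numeric(length(t))
  for (i in seq_len(nrow(bumps))) {
    width <- bumps$width[i] * if (bumps$wave[i] %in% c("Q", "R", "S"))
      qrs_scale else 1
    y <- y + bumps$amp[i] * exp(-0.5 * ((t - bumps$offset[i]) / width)^2)
  }
  y <- y * amp
  structure(y, r_index = which.min(abs(t)))
}

# Band-limited noise in [f_lo, f_hi] Hz with unit standard deviation.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  spec <- stats::fft(stats::rnorm(n))
  freqs <- (0:(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)           # two-sided axis
  mask <- freqs >= f_lo & freqs <= f_hi
  spec[!mask] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Synthetic ECG configuration
#'
#' `label` selects a preset; any field can then be overridden. Presets:
#' `"N"` regular sinus (RR CV 0.02, P waves on); `"A"` AF-like (RR CV 0.25,
#' P waves off, 0.15 mV fibrillatory 4-10 Hz baseline); `"O"` other rhythm
#' (15% premature ectopic beats with wide tall morphology); `"~"` noise
#' (0.4 mV broadband noise and 0.8 mV baseline wander over a faint beat
#' train).
#'
#' @param label class symbol: `"N"`, `"A"`, `"O"` or `"~"`.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz (default 300, the CinC 2017 rate).
#' @param heart_rate_bpm mean heart rate.
#' @param rr_cv coefficient of variation of RR intervals.
#' @param p_wave whether beats carry a P wave.
#' @param fib_wave_amp fibrillatory baseline amplitude, mV (sd).
#' @param fib_wave_band fibrillatory frequency band, Hz.
#' @param ectopic_rate per-beat probability of a premature ectopic.
#' @param noise_sd broadband noise level, mV.
#' @param wander_amp baseline wander amplitude, mV.
#' @param beat_amp beat amplitude multiplier.
#' @param seed integer seed; the same config is bit-reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(label, duration_s = 30, fs = 300,
                         heart_rate_bpm = 70, rr_cv = NULL, p_wave = NULL,
                         fib_wave_amp = NULL, fib_wave_band = c(4, 10),
                         ectopic_rate = NULL, noise_sd = NULL,
                         wander_amp = NULL, beat_amp = NULL, seed = 1L) {
  if (!label %in% ecg_classes()) {
    stop("label must be one of N, A, O, ~")
  }
  preset <- switch(label,
    "N" = list(rr_cv = 0.02, p_wave = TRUE, fib_wave_amp = 0,
               ectopic_rate = 0, noise_sd = 0.02, wander_amp = 0.05,
               beat_amp = 1),
    "A" = list(rr_cv = 0.25, p_wave = FALSE, fib_wave_amp = 0.15,
               ectopic_rate = 0, noise_sd = 0.02, wander_amp = 0.05,
               beat_amp = 1),
    "O" = list(rr_cv = 0.05, p_wave = TRUE, fib_wave_amp = 0,
               ectopic_rate = 0.15, noise_sd = 0.02, wander_amp = 0.05,
               beat_amp = 1),
    "~" = list(rr_cv = 0.1, p_wave = TRUE, fib_wave_amp = 0,
               ectopic_rate = 0, noise_sd = 0.4, wander_amp = 0.8,
               beat_amp = 0.25)
  )
  take <- function(user, from_preset) if (is.null(user)) from_preset else user
  stopifnot(duration_s > 0, fs > 0, heart_rate_bpm > 0)
  cfg <- list(label = label, duration_s = duration_s, fs = fs,
              heart_rate_bpm = heart_rate_bpm,
              rr_cv = take(rr_cv, preset$rr_cv),
              p_wave = take(p_wave, preset$p_wave),
              fib_wave_amp = take(fib_wave_amp, preset$fib_wave_amp),
              fib_wave_band = fib_wave_band,
              ectopic_rate = take(ectopic_rate, preset$ectopic_rate),
              noise_sd = take(noise_sd, preset$noise_sd),
              wander_amp = take(wander_amp, preset$wander_amp),
              beat_amp = take(beat_amp, preset$beat_amp),
              seed = as.integer(seed))
  stopifnot(cfg$rr_cv >= 0, cfg$ectopic_rate >= 0, cfg$ectopic_rate <= 1)
  structure(cfg, class = "synth_config")
}

#' Generate one synthetic ECG record
#'
#' Beats are placed at cumulative RR intervals drawn from a gamma
#' distribution with mean `60 / heart_rate_bpm` and the configured
#' coefficient of variation (gamma keeps intervals positive); ectopic beats
#' arrive prematurely (the preceding RR is shortened to 60%) with wide,
#' tall QRS morphology and no P wave. Class presets are documented at
#' [synth_config()]. Deterministic given the config seed.
#'
#' @param config a [synth_config()] (or a class symbol, which selects the
#'   preset with defaults).
#' @return an [ecg_record()] with the config's label.
#' @export
synth_ecg <- function(config) {
  if (is.character(config)) config <- synth_config(config)
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  with_seed(config$seed, {
    x <- numeric(n)
    mu <- 60 / config$heart_rate_bpm
    cv <- config$rr_cv
    draw_rr <- function() {
      if (cv < 1e-6) return(mu)
      shape <- 1 / cv^2
      stats::rgamma(1, shape = shape, scale = mu / shape)
    }
    t_beat <- draw_rr() / 2
    while (t_beat < config$duration_s) {
      ectopic <- stats::runif(1) < config$ectopic_rate
      if (ectopic) t_beat <- t_beat - 0.4 * mu    # premature arrival
      if (t_beat < 0.1) t_beat <- 0.1
      tmpl <- if (ectopic) {
        synth_beat_template(fs, p_wave = FALSE, qrs_scale = 2.5, amp = 1.3)
      } else {
        synth_beat_template(fs, p_wave = config$p_wave)
      }
      tmpl <- tmpl * config$beat_amp
      r_at <- round(t_beat * fs)
      start <- r_at - attr(tmpl, "r_index") + 1L
      idx <- seq_along(tmpl) + start - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
      t_beat <- t_beat + draw_rr()
    }
    if (config$fib_wave_amp > 0) {
      x <- x + config$fib_wave_amp *
        bandlimited_noise(n, fs, config$fib_wave_band[1],
                          config$fib_wave_band[2])
    }
    if (config$wander_amp > 0) {
      x <- x + config$wander_amp * bandlimited_noise(n, fs, 0.15, 0.6)
    }
    if (config$noise_sd > 0) {
      x <- x + stats::rnorm(n, sd = config$noise_sd)
    }
    # quantise to the int16 container grid so records round-trip bitwise
    x <- round(x * 1000) / 1000
    ecg_record(sprintf("S%06d", config$seed %% 1000000L), x, fs, config$label)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces the requested number of records per class with per-record seeds
#' derived from `base_seed`; durations are drawn uniformly in
#' `duration_range` (default 9-60 s, so the duration filter has work to do).
#'
#' @param per_class_counts named counts, e.g. `c(A = 50, N = 50, O = 50,
#'   "~" = 50)`.
#' @param base_seed integer base seed.
#' @param duration_range duration bounds in seconds.
#' @param fs sampling rate in Hz.
#' @return list of [ecg_record()]s with unique ids.
#' @export
synth_dataset <- function(per_class_counts, base_seed = 1L,
                          duration_range = c(9, 60), fs = 300) {
  stopifnot(!is.null(names(per_class_counts)),
            all(per_class_counts >= 0))
  records <- list()
  idx <- 0L
  for (cls in names(per_class_counts)) {
    for (k in seq_len(per_class_counts[[cls]])) {
      idx <- idx + 1L
      seed_k <- derive_seed(base_seed, idx)
      dur <- with_seed(seed_k,
                       stats::runif(1, duration_range[1], duration_range[2]))
      cfg <- synth_config(cls, duration_s = dur, fs = fs,
                          seed = derive_seed(seed_k, 1L))
      rec <- synth_ecg(cfg)
      rec$record_id <- sprintf("S%05d", idx)
      records[[idx]] <- rec
    }
  }
  records
}

#' Write a synthetic dataset in the CinC 2017 layout
#'
#' One `.mat`/`.hea` pair per record plus `REFERENCE.csv`; the layout
#' round-trips through [load_dataset()].
#'
#' @param records list of [ecg_record()]s.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in records) write_record(rec, dir)
  ref <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    label = vapply(records, function(r) r$label, character(1)))
  utils::write.table(ref, file.path(dir, "REFERENCE.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
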