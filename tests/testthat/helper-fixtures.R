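# Shared fixtures and independent oracles, all built in code at test time.

# Write a record directory with n sinusoid-ish records named R00001..
write_fixture_records <- function(dir, n = 3, n_samples = 9000, fs = 300,
                                  gain = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("R%05d", seq_len(n))
  for (i in seq_len(n)) {
    t <- (seq_len(n_samples) - 1) / fs
    x <- round(sin(2 * pi * i * t) * 1000) / 1000
    rec <- ecg_record(ids[i], x, fs, "N")
    write_record(rec, dir, gain = gain)
  }
  ids
}

# Independent CWT oracle: time-domain Morse wavelet via trapezoid inverse
# Fourier integral, then a direct correlation sum against the reflection-
# extended signal tiled once to either side (the transform's documented
# boundary policy). Never touches the FFT convolution path.
cwt_direct_oracle <- function(x, fs, params, scales, b_idx) {
  n <- length(x)
  np <- 2L * n
  xt <- rep(c(x, rev(x)), 3L)           # tiles at offsets -np, 0, +np
  w <- seq(1e-6, 10, length.out = 20000)
  dw <- w[2] - w[1]
  resp <- morse_wavelet_freq(w, params)
  sigma <- sqrt(params$time_bandwidth) / params$omega_p
  out <- matrix(complex(real = NA_real_), length(scales), length(b_idx))
  for (j in seq_along(scales)) {
    a <- scales[j]
    half <- min(ceiling(10 * sigma * a), 3L * np - 1L)
    lags <- (-half):half
    psi <- vapply(lags / a, function(tt) sum(resp * exp(1i * w * tt)) *
                    dw / (2 * pi), complex(1))
    for (bi in seq_along(b_idx)) {
      b <- b_idx[bi]
      m <- (np + b - 1L) + lags          # 0-based positions in the tiling
      ok <- m >= 0L & m < 3L * np
      z <- sum(xt[m[ok] + 1L] * Conj(psi[ok]))
      if (params$normalization == "L2") z <- z / sqrt(a)
      if (params$normalization == "L1") z <- z / a
      out[j, bi] <- z
    }
  }
  out
}

# Simple R-peak detector for synthetic waveforms: threshold + refractory.
detect_r_peaks <- function(x, fs, threshold = 0.5, refractory_s = 0.25) {
  above <- which(x > threshold)
  if (!length(above)) return(integer(0))
  peaks <- integer(0)
  i <- 1L
  while (i <= length(above)) {
    win_end <- above[i] + round(refractory_s * fs)
    seg <- above[above >= above[i] & above <= win_end]
    peaks <- c(peaks, seg[which.max(x[seg])])
    i <- which(above > win_end)[1]
    if (is.na(i)) break
  }
  peaks
}

# Tiny separable image set: class 1 bright top band, class 2 bright bottom
# band, plus noise.
make_band_images <- function(n_per_class, size = 16, seed = 1) {
  afwave:::with_seed(seed, {
    n <- 2 * n_per_class
    imgs <- array(0, dim = c(size, size, 3, n))
    labels <- character(n)
    for (i in seq_len(n)) {
      cls <- if (i <= n_per_class) 1L else 2L
      im <- array(stats::runif(size * size * 3, 0, 0.3), c(size, size, 3))
      rows <- if (cls == 1L) 1:(size / 2) else (size / 2 + 1):size
      im[rows, , ] <- im[rows, , ] + 0.6
      imgs[, , , i] <- pmin(im, 1)
      labels[i] <- c("hi", "lo")[cls]
    }
    list(images = imgs, labels = labels)
  })
}

expect_partition <- function(split, items) {
  got <- c(split$train, split$validation, split$test)
  expect_setequal(got, items)
  expect_length(got, length(items))
  expect_length(intersect(split$train, split$validation), 0)
  expect_length(intersect(split$train, split$test), 0)
  expect_length(intersect(split$validation, split$test), 0)
}
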