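test_that("Hamming window matches the closed form and its symmetry", {
  expect_equal(hamming_window(3), c(0.08, 1.0, 0.08))
  expect_equal(hamming_window(1), 1.0)
  expect_error(hamming_window(0), ">= 1")
  for (len in c(2, 5, 64, 257)) {
    w <- hamming_window(len)
    expect_equal(w, rev(w))
    expect_equal(w[1], 0.08)
  }
})

test_that("STFT framing, linearity, and per-frame peak location", {
  fs <- 128
  n <- 3840
  sp0 <- stft(numeric(n), fs)
  expect_equal(ncol(sp0$values), 29)           # floor((3840-256)/128)+1
  expect_equal(nrow(sp0$values), 129)          # one-sided bins
  expect_true(all(Mod(sp0$values) == 0))
  expect_error(stft(numeric(100), fs), "shorter")

  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  sp <- stft(x, fs)
  peak_bins <- apply(Mod(sp$values), 2, which.max)
  expect_true(all(abs(sp$bin_freqs[peak_bins] - 10) <= fs / 256))

  # oracle: one frame computed as a direct windowed DFT
  w <- hamming_window(256)
  frame <- x[129:384] * w
  k <- 0:128
  direct <- vapply(k, function(kk) sum(frame * exp(-2i * pi * kk * (0:255) / 256)),
                   complex(1))
  expect_equal(sp$values[, 2], direct, tolerance = 1e-9)
})

test_that("one-sided STFT satisfies Parseval per frame", {
  set.seed(3)
  x <- rnorm(1000)
  sp <- stft(x, 128, window_length = 256, overlap = 128)
  w <- hamming_window(256)
  for (j in seq_len(ncol(sp$values))) {
    frame <- x[((j - 1) * 128 + 1):((j - 1) * 128 + 256)] * w
    mags2 <- Mod(sp$values[, j])^2
    # double the interior bins (one-sided spectrum), not DC/Nyquist
    total <- (mags2[1] + mags2[129] + 2 * sum(mags2[2:128])) / 256
    expect_equal(total, sum(frame^2), tolerance = 1e-6 * sum(frame^2))
  }
})

test_that("Morse wavelet response is analytic with the expected peak", {
  p <- morse_params()                          # gamma 3, P^2 60 -> beta 20
  expect_equal(p$beta, 20)
  expect_equal(morse_wavelet_freq(0, p), 0)
  expect_equal(morse_wavelet_freq(-1, p), 0)
  expect_true(all(morse_wavelet_freq(c(0.1, 1, 3), p) > 0))

  grid <- seq(0.5, 4, by = 1e-4)
  peak <- grid[which.max(morse_wavelet_freq(grid, p))]
  expect_equal(peak, (20 / 3)^(1 / 3), tolerance = 1e-4)
  # the peak value is the same fixed constant at every scale
  wide <- seq(0.01, 4, by = 1e-4)
  for (a in c(0.7, 2, 13)) {
    expect_equal(max(morse_wavelet_freq(a * wide, p)), 2, tolerance = 1e-6)
  }
})

test_that("filter bank geometry: geometric scales, Nyquist peak, admissibility", {
  p <- morse_params(voices_per_octave = 10)
  bank <- design_filter_bank(3840, 128, p)
  ratios <- bank$center_freqs[-1] / bank$center_freqs[-length(bank$center_freqs)]
  expect_equal(ratios, rep(2^(-1 / 10), length(ratios)), tolerance = 1e-12)
  expect_lte(abs(log2(max(bank$center_freqs) / 64)), 1 / 10)
  expect_true(all(bank$filters[, 1] == 0))
  expect_true(all(diff(bank$scales) > 0))
  expect_error(design_filter_bank(8, 128, p), "octave")
})

test_that("CWT is linear with a unit-magnitude L1 response at center frequencies", {
  fs <- 128
  n <- 512
  t <- (0:(n - 1)) / fs
  p <- morse_params()
  z0 <- cwt(numeric(n) + 0, fs, p)
  expect_true(all(Mod(z0$values) == 0))
  expect_error(cwt(c(1, NA, 3, 4), fs, p), "non-finite")

  bank <- design_filter_bank(2 * n, fs, p)
  f0 <- bank$center_freqs[which.min(abs(bank$center_freqs - 10))]
  x <- sin(2 * pi * f0 * t)
  co <- cwt(x, fs, p)
  prof <- rowMeans(Mod(co$values[, 150:350]))
  expect_equal(co$center_freqs[which.max(prof)], f0)
  expect_gt(Mod(co$values[which.max(prof), n / 2]), 0.9)
  expect_lt(Mod(co$values[which.max(prof), n / 2]), 1.1)

  co3 <- cwt(3 * x, fs, p)
  expect_equal(co3$values, 3 * co$values, tolerance = 1e-12)

  sc <- scalogram(co)
  expect_true(all(sc >= 0))
  expect_equal(sc, Mod(co$values))
  expect_equal(scalogram(matrix(3 + 4i)), matrix(5))
})

test_that("FFT-based CWT matches direct integration on short signals", {
  fs <- 128
  n <- 160
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 12 * t) + 0.4 * cos(2 * pi * 25 * t)
  for (norm in c("L1", "L2")) {
    p <- morse_params(normalization = norm)
    co <- cwt(x, fs, p)
    jj <- seq(6, length(co$scales) - 10, by = 12)
    bb <- seq(40, n - 40, by = 30)
    direct <- cwt_direct_oracle(x, fs, p, co$scales[jj], bb)
    zmax <- max(Mod(co$values))
    for (ji in seq_along(jj)) {
      for (bi in seq_along(bb)) {
        if (co$center_freqs[jj[ji]] <= co$coi[bb[bi]]) next
        expect_lt(Mod(direct[ji, bi] - co$values[jj[ji], bb[bi]]) / zmax,
                  1e-3)
      }
    }
  }
})

test_that("sinusoid ridges are recovered within one voice across the band", {
  fs <- 128
  n <- 1024
  t <- (0:(n - 1)) / fs
  p <- morse_params(voices_per_octave = 10)
  for (f in c(1, 5, 10, 20, 40)) {
    co <- cwt(sin(2 * pi * f * t), fs, p)
    expect_lte(abs(log2(ridge_frequency(co) / f)), 1 / 10 + 1e-9)
  }
})

test_that("more voices per octave never hurts ridge accuracy", {
  fs <- 128
  n <- 1024
  t <- (0:(n - 1)) / fs
  freqs <- c(1, 5, 10, 20, 40)
  worst <- sapply(c(4, 10, 16), function(v) {
    p <- morse_params(voices_per_octave = v)
    max(sapply(freqs, function(f) {
      abs(log2(ridge_frequency(cwt(sin(2 * pi * f * t), fs, p)) / f))
    }))
  })
  expect_true(all(diff(worst) <= 1e-9))
})
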