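# afwave

Time-frequency analysis and CNN classification of short single-lead ECG
recordings, aimed at atrial-fibrillation screening. `afwave` is for signal-
processing and ML researchers working with the PhysioNet/CinC 2017-style
single-lead format (300 Hz, 9–60 s records, classes N / A / O / ~) who want
the full pipeline — duration-based segmentation, generalized Morse
continuous wavelet transform (or STFT) scalogram images, a transfer-
learning-style convolutional classifier, and a six-metric / ROC / PR
evaluation battery — as reusable, tested R functions that also run at desk
scale on fully synthetic data.

## The method

Each record at least 30 s long contributes its first 30 s, resampled to
128 Hz; shorter records are excluded. The cut is analysed with an analytic
**generalized Morse wavelet** filter bank, defined in the frequency domain
as

Ψ(ω) = U(ω) · c · ω^β · e^(−ω^γ),   ω_p = (β/γ)^(1/γ),

with the "(3, 60)" parameterisation (γ = 3, time-bandwidth P² = βγ = 60,
so β = 20, peak at ω_p ≈ 1.8821). Scales are geometric at 10 voices per
octave, from the Nyquist-peaked wavelet down to the longest wavelet that
fits the record. The scalogram |Z(a, b)| is log-compressed, min-max
normalised, and rendered as a fixed-size RGB image (yellow = high energy);
a small bundled CNN — or any frozen pretrained feature extractor with a
freshly replaced fully-connected/softmax/decision head — is trained with
rmsprop and validation-accuracy early stopping on a stratified 64:16:20
split, and evaluated per class (one-vs-rest) with accuracy, sensitivity,
specificity, precision, F1 and Matthews correlation plus ROC/AUC and
precision-recall curves. An STFT branch (256-point Hamming window,
128-point overlap) provides the spectrogram alternative.

A built-in generator synthesises all four rhythm classes (regular sinus;
AF-like with irregular RR, no P waves and a 4–10 Hz fibrillatory baseline;
premature ectopics; noise) so every stage is testable without downloading
anything. See `vignettes/afwave-methods.Rmd` for the full methods account.

## Worked example

```r
library(afwave)

rec <- synth_ecg(synth_config("A", duration_s = 60, seed = 7))
rec
#> <ecg_record S000007: 18000 samples @ 300 Hz (60.0 s), label A>

seg <- resample_segment(segment_record(rec), 128)   # first 30 s, 128 Hz
co  <- cwt(seg$samples, seg$fs, morse_params())     # Morse (3, 60), 10 voices
co
#> <cwt_coeffs: 107 scales x 3840 times, 0.0412346-64 Hz, L1 norm>
ridge_frequency(co)
#> [1] 7.464
```

The dominant ridge of this AF-like record sits at 7.5 Hz — inside the
4–10 Hz fibrillatory band, exactly the cue the classifier learns. The
end-to-end pipeline on a 200-record synthetic study (50 per class; records
shorter than 30 s are excluded by design):

```r
cfg <- pipeline_config(synth_counts = c(A = 50, N = 50, O = 50, "~" = 50),
                       seed = 1)
res <- run_pipeline(cfg)
#> [afwave] load         200 records
#> [afwave] filter       116 kept, 84 excluded
#> [afwave] render       116 images at 64x64
#> [afwave] split        74/19/23
#> [afwave] train        13 epochs (early_stop), best val acc 1
#> [afwave] evaluate     23 test items, macro F1 0.9141
print(res$report)
#>  class    acc     se     sp    pre     f1    mcc auc_roc auc_pr
#>      ~ 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000  1.0000 1.0000
#>      A 0.9565 1.0000 0.9412 0.8571 0.9231 0.8982  1.0000 1.0000
#>      N 0.9565 1.0000 0.9375 0.8750 0.9333 0.9057  1.0000 1.0000
#>      O 0.9130 0.6667 1.0000 1.0000 0.8000 0.7723  0.9902 0.9742
#>  macro 0.9565 0.9167 0.9697 0.9330 0.9141 0.8941  0.9975 0.9936
```

Rows are one-vs-rest records per class; `acc` is one-vs-rest accuracy,
`se` sensitivity (recall), `mcc` the Matthews correlation; the `macro` row
is the unweighted mean. On held-out synthetic data the pipeline reaches
macro-F1 ≈ 0.91 in a few minutes on one CPU.

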