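# Rendering of time-frequency magnitude matrices as fixed-size RGB images
# for the classifier. Magnitudes are normalised to peak 1, log-compressed,
# min-max scaled, resized, and mapped through a yellow-high perceptual
# colormap. Only the data panel is rendered: no axes, ticks or colorbars.

# Yellow-high perceptual colormap anchors (parula-like: dark blue -> cyan ->
# green -> yellow).
afw_colormap_anchors <- function() {
  rbind(
    c(0.2422, 0.1504, 0.6603),
    c(0.2803, 0.2782, 0.9221),
    c(0.2081, 0.4445, 0.9867),
    c(0.0870, 0.5902, 0.9012),
    c(0.0704, 0.7457, 0.7258),
    c(0.2906, 0.7964, 0.5123),
    c(0.6720, 0.7793, 0.2227),
    c(0.9439, 0.7822, 0.2095),
    c(0.9769, 0.9839, 0.0805)
  )
}

# Map values in [0, 1] to an n x 3 matrix of [0, 255] integers; monotone in
# the input by construction (piecewise-linear interpolation of the anchors).
afw_colormap <- function(v) {
  ramp <- grDevices::colorRamp(grDevices::rgb(afw_colormap_anchors()),
                               space = "rgb")
  rgb <- ramp(pmin(pmax(v, 0), 1))
  matrix(as.integer(round(rgb)), ncol = 3L)
}

#' Render a time-frequency matrix as a fixed-size RGB image
#'
#' The magnitude matrix (rows = frequency bins ordered by the `freq_axis`,
#' columns = time) is normalised to peak 1, log-compressed as
#' `log(1 + m / 1e-8)`, min-max scaled to `[0, 1]`, bilinearly resized to the
#' target panel, and mapped through a yellow-high perceptual colormap. Rows
#' are ordered so the highest frequency is the top image row. For the CWT the
#' geometric center-frequency grid makes the vertical axis log-frequency; for
#' the STFT it is linear — no re-gridding is applied. Rendering is exactly
#' invariant to positive rescaling of the input matrix.
#'
#' @param matrix nonnegative real matrix (e.g. a [scalogram()]).
#' @param freq_axis frequency of each row in Hz; used only to orient rows
#'   (descending from the top). Defaults to rows already ordered
#'   top = highest.
#' @param mode `"cwt"` or `"stft"` (recorded in the result).
#' @param size target `c(height, width)` in pixels.
#' @param source_id,label metadata carried on the image.
#' @return object of class `scalogram_image` with integer `pixels`
#'   (height x width x 3, values 0-255).
#' @export
render_tf_image <- function(matrix, freq_axis = NULL, mode = c("cwt", "stft"),
                            size = c(224, 224), source_id = "",
                            label = "unknown") {
  mode <- match.arg(mode)
  if (any(matrix < 0)) stop("magnitude matrix must be nonnegative")
  if (any(size < 1)) stop("size must be positive")
  if (!is.null(freq_axis)) {
    if (length(freq_axis) != nrow(matrix)) {
      stop("freq_axis length must match the row count")
    }
    matrix <- matrix[order(freq_axis, decreasing = TRUE), , drop = FALSE]
  }
  peak <- max(matrix)
  if (peak > 0) {
    v <- log1p((matrix / peak) / 1e-8)
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  } else {
    v <- matrix * 0
  }
  # EBImage grayscale frames are x (width) by y (height); rows of v are
  # frequencies (image y), columns time (image x)
  img <- EBImage::Image(t(v))
  resized <- EBImage::resize(img, w = size[2], h = size[1])
  v2 <- t(EBImage::imageData(resized))
  v2 <- pmin(pmax(v2, 0), 1)
  rgb <- afw_colormap(as.vector(v2))
  pixels <- array(0L, dim = c(size[1], size[2], 3L))
  for (ch in 1:3) pixels[, , ch] <- matrix(rgb[, ch], nrow = size[1])
  structure(
    list(pixels = pixels, source_id = source_id, label = label, mode = mode),
    class = "scalogram_image"
  )
}

#' @export
print.scalogram_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scalogram_image %s: %d x %d x %d, label %s (%s)>\n",
              x$source_id, d[1], d[2], d[3], x$label, x$mode))
  invisible(x)
}

#' Write a scalogram image to a PNG file
#' @param image a `scalogram_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Transform and render a batch of segments to image files
#'
#' Applies the configured time-frequency transform to each segment, renders
#' the magnitude image, and writes one PNG per segment named
#' `<label>_<record_id>.png`. Deterministic: identical inputs give
#' byte-identical files.
#'
#' @param segments list of [ecg_segment()]s.
#' @param transform_config list with `mode` (`"cwt"` or `"stft"`), `params`
#'   (a [morse_params()], cwt mode), `window_length`/`overlap` (stft mode),
#'   and `size` (`c(height, width)`).
#' @param out_dir writable output directory.
#' @return data.frame manifest (`path`, `label`, `record_id`), also written
#'   as `manifest.csv` in `out_dir`.
#' @export
batch_render <- function(segments, transform_config = list(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  cfg <- utils::modifyList(
    list(mode = "cwt", params = morse_params(), window_length = 256,
         overlap = 128, size = c(224, 224)),
    transform_config)
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    img <- render_segment(seg, cfg)
    path <- file.path(out_dir, paste0(seg$label, "_", seg$record_id, ".png"))
    write_image_png(img, path)
    rows[[i]] <- data.frame(path = path, label = seg$label,
                            record_id = seg$record_id,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(manifest)) {
    manifest <- data.frame(path = character(), label = character(),
                           record_id = character())
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# Transform one segment and render it under a batch config.
render_segment <- function(seg, cfg) {
  if (cfg$mode == "cwt") {
    co <- cwt(seg$samples, seg$fs, cfg$params, bank = cfg$bank)
    render_tf_image(scalogram(co), freq_axis = co$center_freqs, mode = "cwt",
                    size = cfg$size, source_id = seg$record_id,
                    label = seg$label)
  } else {
    sp <- stft(seg$samples, seg$fs, cfg$window_length, cfg$overlap)
    render_tf_image(Mod(sp$values), freq_axis = sp$bin_freqs, mode = "stft",
                    size = cfg$size, source_id = seg$record_id,
                    label = seg$label)
  }
}
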