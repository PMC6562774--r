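## Time-frequency front end: Morlet continuous wavelet transform, scalogram
## energy density, and bicubic resize to the network input size.
##
## The CWT computed here is
##   W(s, tau) = (1/sqrt(s)) * sum_t x(t) * Conj(psi((t - tau)/s)) * dt
## with the analytic Morlet mother wavelet
##   psi(u) = pi^(-1/4) * exp(i * omega0 * u) * exp(-u^2 / 2),
## evaluated for every configured scale s by zero-padded linear convolution in
## the frequency domain. Scales are expressed in seconds; the Morlet
## scale/pseudo-frequency correspondence is f = omega0 / (2 * pi * s).

#' Scalogram configuration
#'
#' @param omega0 Morlet center-frequency parameter (dimensionless, default 6,
#'   the standard admissible choice).
#' @param scales strictly increasing positive numeric vector of scales in
#'   seconds, or `NULL` to build the default grid with [morlet_scale_grid()]
#'   at transform time (64 log-spaced scales spanning 0.5-40 Hz, matching the
#'   bandpass of the reference recordings).
#' @param n_scales,freq_range grid parameters used when `scales` is `NULL`.
#' @param render_size optional intermediate raster size `c(height, width)` in
#'   pixels for the "faithful" path (the original workflow plotted 662 x 536
#'   figures before shrinking them); `NULL` (default) resizes the scalogram
#'   matrix directly.
#' @param input_size network input size `c(height, width)`, default `c(32, 32)`;
#'   components must be >= 8.
#' @param interpolation `"cubic"` (Keys cubic convolution, the default and the
#'   method used by the original workflow) or `"bilinear"`.
#' @param value_mode `"energy"` (squared modulus, the scalogram energy
#'   density; default) or `"magnitude"`.
#' @param channels 1 (grayscale, default) or 3 (colormap rendering).
#' @param colormap palette name passed to [grDevices::hcl.colors()] when
#'   `channels = 3`.
#' @return An object of class `"scalogram_config"`.
#' @export
scalogram_config <- function(omega0 = 6, scales = NULL, n_scales = 64,
                             freq_range = c(0.5, 40), render_size = NULL,
                             input_size = c(32, 32),
                             interpolation = c("cubic", "bilinear"),
                             value_mode = c("energy", "magnitude"),
                             channels = 1, colormap = "Viridis") {
  interpolation <- match.arg(interpolation)
  value_mode <- match.arg(value_mode)
  if (!is.null(scales)) {
    if (any(scales <= 0) || any(diff(scales) <= 0)) {
      stop_validation("scales must be strictly positive and strictly increasing")
    }
  }
  if (length(input_size) != 2L || any(input_size < 8)) {
    stop_validation("input_size must be two values >= 8")
  }
  if (!channels %in% c(1, 3)) stop_validation("channels must be 1 or 3")
  structure(list(omega0 = omega0, scales = scales, n_scales = n_scales,
                 freq_range = freq_range, render_size = render_size,
                 input_size = as.integer(input_size),
                 interpolation = interpolation, value_mode = value_mode,
                 channels = as.integer(channels), colormap = colormap),
            class = "scalogram_config")
}

#' Morlet scale/pseudo-frequency correspondence
#'
#' For the Morlet wavelet with center parameter `omega0`, a scale `s` (in
#' seconds) corresponds to the pseudo-frequency `f = omega0 / (2 * pi * s)` Hz.
#'
#' @param scale scale(s) in seconds.
#' @param freq frequency(ies) in Hz.
#' @param omega0 Morlet center-frequency parameter.
#' @return The corresponding frequency (Hz) or scale (seconds).
#' @export
morlet_frequency <- function(scale, omega0 = 6) omega0 / (2 * pi * scale)

#' @rdname morlet_frequency
#' @export
morlet_scale <- function(freq, omega0 = 6) omega0 / (2 * pi * freq)

#' Default logarithmic scale grid
#'
#' `n` scales, log-spaced so their Morlet pseudo-frequencies span
#' `freq_range` (default 0.5-40 Hz). Returned in increasing scale order
#' (decreasing frequency), so row 1 of the scalogram is the highest frequency.
#'
#' @param n number of scales.
#' @param freq_range frequency span in Hz, `c(low, high)`.
#' @param omega0 Morlet center-frequency parameter.
#' @return Numeric vector of scales in seconds.
#' @export
morlet_scale_grid <- function(n = 64, freq_range = c(0.5, 40), omega0 = 6) {
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]), length.out = n))
  morlet_scale(freqs, omega0)
}

.config_scales <- function(config) {
  if (!is.null(config$scales)) config$scales
  else morlet_scale_grid(config$n_scales, config$freq_range, config$omega0)
}

#' Continuous wavelet transform of an EEG segment
#'
#' Computes the Morlet CWT with 1/sqrt(s) normalization for every configured
#' scale, by zero-padded linear convolution (evaluated in the frequency
#' domain; the two are identical to floating precision). The transform is
#' fully deterministic. When the segment is shorter than the support of the
#' widest wavelet, a warning-level log line is emitted and the result carries
#' `edge_effect = TRUE`; coefficients near the borders are then dominated by
#' the zero-padding.
#'
#' @param segment an [eeg_segment()].
#' @param config a [scalogram_config()].
#' @return An object of class `"cwt_result"`: complex `coefficients` matrix
#'   indexed `[scale, time]`, the `scales` (seconds), `times` (seconds),
#'   `omega0`, and the `edge_effect` flag.
#' @examples
#' seg <- generate_segment("A", synthesis_config(seed = 1))
#' w <- cwt(seg, scalogram_config(n_scales = 16))
#' dim(w$coefficients)
#' @export
cwt <- function(segment, config = scalogram_config()) {
  stopifnot(inherits(segment, "eeg_segment"),
            inherits(config, "scalogram_config"))
  x <- segment$samples
  n <- length(x)
  fs <- segment$fs
  dt <- 1 / fs
  scales <- .config_scales(config)
  omega0 <- config$omega0

  # wavelet support: |u| <= 4 standard deviations of the Gaussian envelope
  half_len <- ceiling(4 * scales * fs)
  widest <- 2L * max(half_len) + 1L
  edge <- widest > n
  if (edge) {
    log_warn(sprintf(
      "cwt: segment '%s' (%d samples) is shorter than the widest wavelet support (%d samples); border coefficients are edge-affected",
      segment$segment_id, n, widest))
  }

  nfft <- stats::nextn(n + widest - 1L, 2L)
  fx <- stats::fft(c(x, numeric(nfft - n)))
  coef <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  norm0 <- pi^(-0.25)
  for (k in seq_along(scales)) {
    s <- scales[k]
    hl <- half_len[k]
    u <- (seq(-hl, hl) * dt) / s
    # g(u) = Conj(psi(-u/s)) / sqrt(s) * dt ; for the analytic Morlet this is
    # pi^(-1/4) exp(-u^2/2) exp(i*omega0*u) / sqrt(s) * dt
    g <- norm0 * exp(-u^2 / 2) * exp(1i * omega0 * u) * dt / sqrt(s)
    fg <- stats::fft(c(g, complex(real = numeric(nfft - length(g)))))
    conv <- stats::fft(fx * fg, inverse = TRUE) / nfft
    # full linear convolution index: tau_i sits at position i + hl
    coef[k, ] <- conv[seq_len(n) + hl]
  }
  structure(list(coefficients = coef, scales = scales,
                 times = (seq_len(n) - 1L) * dt, omega0 = omega0,
                 edge_effect = edge, source_id = segment$segment_id,
                 class_label = segment$class_label, fs = fs),
            class = "cwt_result")
}

#' Scalogram of a CWT result
#'
#' The scalogram is the local time-frequency energy density of the transform:
#' `|W|^2` in `"energy"` mode (default) or `|W|` in `"magnitude"` mode.
#'
#' @param result a [cwt()] result.
#' @param config a [scalogram_config()].
#' @return Non-negative real matrix indexed `[scale, time]`.
#' @export
to_scalogram <- function(result, config = scalogram_config()) {
  stopifnot(inherits(result, "cwt_result"))
  m <- Mod(result$coefficients)
  if (config$value_mode == "energy") m <- m^2
  m
}

# Keys cubic-convolution kernel, a = -0.5 (the classic "bicubic" of MATLAB
# imresize / OpenCV INTER_CUBIC).
.cubic_kernel <- function(d, a = -0.5) {
  d <- abs(d)
  ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
         ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
}

# 1-D resampling weight matrix (n_out x n_in), center-aligned coordinate
# mapping with edge clamping. method "cubic" or "bilinear".
.resample_weights <- function(n_in, n_out, method = "cubic") {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  support <- if (method == "cubic") 2L else 1L
  for (j in seq_len(n_out)) {
    src <- (j - 0.5) * scale + 0.5
    i0 <- floor(src)
    idx <- (i0 - support + 1L):(i0 + support)
    d <- src - idx
    w <- if (method == "cubic") .cubic_kernel(d) else pmax(0, 1 - abs(d))
    idx <- pmin(pmax(idx, 1L), n_in) # clamp: edge pixels replicated
    for (k in seq_along(idx)) W[j, idx[k]] <- W[j, idx[k]] + w[k]
  }
  sweep(W, 1, rowSums(W), "/")
}

#' Resize a matrix by separable cubic (or bilinear) interpolation
#'
#' @param m numeric matrix.
#' @param size target `c(height, width)`.
#' @param method `"cubic"` (Keys cubic convolution, a = -0.5) or `"bilinear"`.
#' @return Resized matrix. Cubic interpolation can overshoot the input range;
#'   no clipping is applied here.
#' @export
resize_matrix <- function(m, size, method = c("cubic", "bilinear")) {
  method <- match.arg(method)
  Wr <- .resample_weights(nrow(m), size[1], method)
  Wc <- .resample_weights(ncol(m), size[2], method)
  Wr %*% m %*% t(Wc)
}

#' Render a scalogram matrix as a normalized network input image
#'
#' Per-image min-max normalization to `[0, 1]` (a constant input maps to
#' all-zeros, by convention), optional rasterization at
#' `config$render_size`, then interpolation to `config$input_size`. Cubic
#' interpolation can overshoot, so the result is clipped back to the
#' normalized input range `[0, 1]` (the resize is therefore contractive in
#' range). Row 1 of the image corresponds to the smallest scale, i.e. the
#' highest frequency; the bottom rows are the lowest frequencies.
#'
#' @param scalogram non-negative real matrix `[scale, time]`.
#' @param config a [scalogram_config()].
#' @param source_id,class_label identification carried through to the image.
#' @return An object of class `"scalogram_image"`: `pixels` is a
#'   `height x width` matrix in `[0, 1]` (`channels = 1`) or a
#'   `height x width x 3` array (`channels = 3`).
#' @export
render_and_resize <- function(scalogram, config = scalogram_config(),
                              source_id = "scalogram",
                              class_label = NA_character_) {
  if (length(scalogram) == 0L) stop_validation("empty scalogram")
  if (anyNA(scalogram)) stop_validation("NaN/NA in scalogram input")
  rng <- range(scalogram)
  norm <- if (rng[2] > rng[1]) (scalogram - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(scalogram), ncol(scalogram))
  if (!is.null(config$render_size) &&
      !identical(dim(norm), as.integer(config$render_size))) {
    norm <- clamp01(resize_matrix(norm, config$render_size,
                                  config$interpolation))
  }
  out <- if (identical(dim(norm), as.integer(config$input_size))) norm
         else clamp01(resize_matrix(norm, config$input_size,
                                    config$interpolation))
  pixels <- if (config$channels == 3L) .apply_colormap(out, config$colormap)
            else out
  structure(list(pixels = pixels, source_id = source_id,
                 class_label = class_label),
            class = "scalogram_image")
}

# grayscale [0,1] -> RGB array through an hcl.colors palette
.apply_colormap <- function(m, palette = "Viridis", n = 256L) {
  cols <- grDevices::col2rgb(grDevices::hcl.colors(n, palette)) / 255
  idx <- pmin(pmax(floor(m * n) + 1L, 1L), n)
  array(c(cols[1, idx], cols[2, idx], cols[3, idx]), dim = c(dim(m), 3L))
}

#' @export
print.scalogram_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scalogram_image> %s  label=%s  %s\n", x$source_id,
              x$class_label, paste(d, collapse = "x")))
  invisible(x)
}

#' Full front end: segment to network input image
#'
#' Composition of [cwt()], [to_scalogram()] and [render_and_resize()];
#' carries the segment's identifier and class label through.
#'
#' @param segment an [eeg_segment()].
#' @param config a [scalogram_config()].
#' @return A [render_and_resize()] image.
#' @examples
#' img <- segment_to_input(generate_segment("E", synthesis_config(seed = 2)))
#' dim(img$pixels)
#' @export
segment_to_input <- function(segment, config = scalogram_config()) {
  w <- cwt(segment, config)
  render_and_resize(to_scalogram(w, config), config,
                    source_id = segment$segment_id,
                    class_label = segment$class_label)
}

#' Convert every segment of a dataset to input images
#'
#' @param dataset an [eeg_dataset()].
#' @param config a [scalogram_config()].
#' @return List of [render_and_resize()] images in dataset order.
#' @export
dataset_to_inputs <- function(dataset, config = scalogram_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  log_info(sprintf("stage=scalogram converting %d segments",
                   length(dataset$segments)))
  lapply(dataset$segments, segment_to_input, config = config)
}

#' Export a scalogram image as PNG
#'
#' Requires the `png` package. Grayscale images are written as 8-bit
#' single-channel PNG, colormapped images as RGB.
#'
#' @param image a [render_and_resize()] image.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  png::writePNG(image$pixels, path)
  invisible(path)
}
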