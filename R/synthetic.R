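## Synthetic EEG generator. Five recipes emulate the recording conditions of
## the public five-set epilepsy corpus: two healthy classes dominated by
## ongoing oscillatory background (eyes-open vs eyes-closed, the latter with
## roughly doubled alpha-band amplitude), two interictal classes with sporadic
## biphasic spikes over background, and one ictal class with a sustained
## high-amplitude low-frequency rhythmic discharge. The recipes are
## engineering choices with the right time-frequency contrasts, not a
## physiological simulation.

#' Default per-class synthesis recipes
#'
#' Each recipe lists: `background_sd` (RMS of the 1/f-shaped broadband
#' background), `alpha_amp` (amplitude of the 8-13 Hz narrowband rhythm),
#' `spike_rate` (Poisson rate of interictal spikes, per second), `spike_amp`
#' (mean spike amplitude), `rhythm_freq` (ictal discharge frequency, Hz;
#' jittered +/- `rhythm_jitter` per segment) and `rhythm_amp` (its amplitude).
#'
#' @return Named list of recipes for classes `A`..`E`.
#' @export
default_recipes <- function() {
  base <- list(background_sd = 1, alpha_amp = 0, spike_rate = 0, spike_amp = 0,
               rhythm_freq = 0, rhythm_jitter = 0, rhythm_amp = 0)
  recipe <- function(...) utils::modifyList(base, list(...))
  list(
    # healthy, eyes open: moderate alpha over 1/f background
    A = recipe(alpha_amp = 0.8),
    # healthy, eyes closed: ~2x alpha amplitude
    B = recipe(alpha_amp = 1.6),
    # interictal (hippocampal): sparse, smaller spikes
    C = recipe(alpha_amp = 0.4, spike_rate = 0.5, spike_amp = 4),
    # interictal (epileptogenic zone): denser, larger spikes
    D = recipe(alpha_amp = 0.4, spike_rate = 1.5, spike_amp = 6),
    # ictal: sustained 3-5 Hz rhythmic discharge at >= 3x background
    E = recipe(alpha_amp = 0.2, rhythm_freq = 4, rhythm_jitter = 0.6,
               rhythm_amp = 5)
  )
}

#' Synthesis configuration
#'
#' @param fs sampling rate in Hz (default 173.61, matching the reference
#'   corpus).
#' @param duration segment duration in seconds (default 4; use 23.6 to mimic
#'   the reference corpus).
#' @param n_per_class segments per class.
#' @param seed integer seed; identical `(config, seed)` yields identical data.
#' @param class_recipes named list of recipes as in [default_recipes()].
#' @return An object of class `"synthesis_config"`.
#' @export
synthesis_config <- function(fs = 173.61, duration = 4, n_per_class = 10,
                             seed = 1, class_recipes = default_recipes()) {
  if (fs <= 0 || duration <= 0 || n_per_class < 1) {
    stop_validation("fs and duration must be positive, n_per_class >= 1")
  }
  structure(list(fs = fs, duration = duration,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed), class_recipes = class_recipes),
            class = "synthesis_config")
}

# 1/f-shaped broadband Gaussian background restricted to `band` (Hz), scaled
# to RMS `sd`. Built in the frequency domain: Gaussian spectrum with amplitude
# proportional to 1/sqrt(f) (power ~ 1/f), mirroring the 0.5-40 Hz bandpass of
# the real recordings.
.pink_background <- function(n, fs, sd = 1, band = c(0.5, 40)) {
  if (sd == 0) return(numeric(n))
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  shape <- ifelse(freqs >= band[1] & freqs <= band[2], 1 / sqrt(pmax(freqs, band[1])), 0)
  half <- complex(real = stats::rnorm(length(freqs)),
                  imaginary = stats::rnorm(length(freqs))) * shape
  half[1L] <- 0 # no DC
  spec <- complex(length.out = n)
  spec[seq_along(half)] <- half
  if (n %% 2 == 0) spec[length(half)] <- complex(real = Re(half[length(half)]))
  idx <- seq(2L, length(half) - (n %% 2 == 0))
  spec[n + 2L - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x * (sd / s)
}

# Narrowband rhythm as bandpass-shaped Gaussian noise (8-13 Hz alpha band by
# default), scaled so its RMS equals `amp`.
.band_rhythm <- function(n, fs, amp, band = c(8, 13)) {
  if (amp == 0) return(numeric(n))
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  shape <- as.numeric(freqs >= band[1] & freqs <= band[2])
  half <- complex(real = stats::rnorm(length(freqs)),
                  imaginary = stats::rnorm(length(freqs))) * shape
  half[1L] <- 0
  spec <- complex(length.out = n)
  spec[seq_along(half)] <- half
  if (n %% 2 == 0) spec[length(half)] <- complex(real = Re(half[length(half)]))
  idx <- seq(2L, length(half) - (n %% 2 == 0))
  spec[n + 2L - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x * (amp / s)
}

# Canonical biphasic interictal spike: sharp positive lobe followed by a
# smaller, broader negative lobe, ~70 ms total width.
.spike_waveform <- function(fs, amp) {
  tt <- seq(0, 0.07, by = 1 / fs)
  amp * (exp(-((tt - 0.02) / 0.008)^2) - 0.5 * exp(-((tt - 0.045) / 0.014)^2))
}

#' Generate one synthetic EEG segment
#'
#' Pseudo-randomness for each segment comes from a stream derived from
#' `(config$seed, label, index)`, so any one segment is reproducible
#' independently of generation order.
#'
#' @param label class label with a recipe in `config$class_recipes`.
#' @param config a [synthesis_config()].
#' @param index 1-based segment index within its class.
#' @return An [eeg_segment()] of `round(fs * duration)` samples.
#' @examples
#' seg <- generate_segment("E", synthesis_config(seed = 7), index = 1)
#' @export
generate_segment <- function(label, config, index = 1L) {
  stopifnot(inherits(config, "synthesis_config"))
  r <- config$class_recipes[[label]]
  if (is.null(r)) stop_validation("no synthesis recipe for label '", label, "'")
  n <- round(config$fs * config$duration)
  fs <- config$fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, paste0("segment/", label, "/", index)))

  x <- .pink_background(n, fs, sd = r$background_sd)
  x <- x + .band_rhythm(n, fs, amp = r$alpha_amp)
  if (r$spike_rate > 0 && r$spike_amp > 0) {
    n_spikes <- stats::rpois(1L, r$spike_rate * config$duration)
    if (n_spikes > 0) {
      w <- .spike_waveform(fs, 1)
      onsets <- sort(sample.int(max(n - length(w), 1L), n_spikes, replace = TRUE))
      amps <- r$spike_amp * stats::runif(n_spikes, 0.7, 1.3)
      for (k in seq_len(n_spikes)) {
        idx <- onsets[k]:(onsets[k] + length(w) - 1L)
        idx <- idx[idx <= n]
        x[idx] <- x[idx] + amps[k] * w[seq_along(idx)]
      }
    }
  }
  if (r$rhythm_amp > 0 && r$rhythm_freq > 0) {
    f0 <- r$rhythm_freq + stats::runif(1L, -r$rhythm_jitter, r$rhythm_jitter)
    phase <- stats::runif(1L, 0, 2 * pi)
    tt <- (seq_len(n) - 1L) / fs
    # slight cycle-to-cycle amplitude modulation, as in real discharges
    am <- 1 + 0.15 * sin(2 * pi * 0.5 * tt + stats::runif(1L, 0, 2 * pi))
    x <- x + r$rhythm_amp * sqrt(2) * am * sin(2 * pi * f0 * tt + phase)
  }
  eeg_segment(x, fs = fs,
              segment_id = sprintf("syn_%s_%03d", label, index),
              class_label = label)
}

#' Generate a full labelled synthetic dataset
#'
#' @param config a [synthesis_config()].
#' @param classes labels to generate; default all recipes in the config.
#' @return An [eeg_dataset()] with `n_per_class` segments per label, fully
#'   reproducible from `config$seed`.
#' @examples
#' ds <- generate_dataset(synthesis_config(n_per_class = 2, seed = 1))
#' class_counts(ds)
#' @export
generate_dataset <- function(config, classes = names(config$class_recipes)) {
  stopifnot(inherits(config, "synthesis_config"))
  segments <- list()
  for (cl in classes) {
    for (i in seq_len(config$n_per_class)) {
      segments[[length(segments) + 1L]] <- generate_segment(cl, config, i)
    }
  }
  eeg_dataset(segments, classes = classes)
}

#' Write a synthetic dataset as plain-text class directories
#'
#' Emits the single-column dialect into one subdirectory per class, so the
#' files round-trip through [load_dataset()].
#'
#' @param dataset an [eeg_dataset()].
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_bonn_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  for (cl in dataset$classes) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (seg in dataset$segments) {
    write_bonn_segment(seg, file.path(root, seg$class_label,
                                      paste0(seg$segment_id, ".txt")))
  }
  invisible(root)
}

# Save/restore the global RNG state so seeded generation does not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
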