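# Shared fixtures and independent oracles. Everything is generated in code at
# test time; the heavier fixtures are memoized so multiple test files reuse
# one computation.

suppressMessages(log_level("off"))

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small A-vs-E image set used by the separability and CV tests
fixture_ae_images <- function(n_per_class = 20, seed = 101) {
  memo(sprintf("ae-%d-%d", n_per_class, seed), {
    ds <- generate_dataset(
      synthesis_config(n_per_class = n_per_class, seed = seed),
      classes = c("A", "E"))
    list(dataset = ds, images = dataset_to_inputs(ds))
  })
}

# random valid 32x32 image array with labels, for pure-classifier tests
fixture_random_images <- function(n, n_classes = 2, seed = 7) {
  set.seed(seed)
  x <- array(runif(32 * 32 * n), dim = c(32, 32, n))
  labels <- rep_len(LETTERS[seq_len(n_classes)], n)
  list(x = x, labels = labels)
}

# Independent metric oracle: direct counting over label pairs, no matrix
# algebra shared with the implementation.
oracle_binary_counts <- function(original, predicted, positive) {
  c(TP = sum(original == positive & predicted == positive),
    FP = sum(original != positive & predicted == positive),
    FN = sum(original == positive & predicted != positive),
    TN = sum(original != positive & predicted != positive))
}

oracle_metrics <- function(original, predicted, positive) {
  b <- oracle_binary_counts(original, predicted, positive)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  prec <- pct(b["TP"], b["TP"] + b["FP"])
  rec <- pct(b["TP"], b["TP"] + b["FN"])
  f <- if (is.na(prec) || is.na(rec)) NA_real_
       else if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(counts = b,
       accuracy = pct(b["TP"] + b["TN"], sum(b)),
       precision = prec, recall = rec,
       specificity = pct(b["TN"], b["FP"] + b["TN"]),
       npv = pct(b["TN"], b["TN"] + b["FN"]),
       f_score = unname(f))
}

# Independent CWT oracle: direct time-domain summation of the transform
# definition (O(n * support) per scale), zero samples outside the segment.
oracle_cwt_direct <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  out <- matrix(0 + 0i, length(scales), n)
  for (k in seq_along(scales)) {
    s <- scales[k]
    hl <- ceiling(4 * s * fs)
    for (tau in seq_len(n)) {
      t_idx <- max(1L, tau - hl):min(n, tau + hl)
      u <- ((t_idx - tau) * dt) / s
      psi_conj <- pi^(-0.25) * exp(-u^2 / 2) * exp(-1i * omega0 * u)
      out[k, tau] <- sum(x[t_idx] * psi_conj) * dt / sqrt(s)
    }
  }
  out
}

# band power via periodogram, used as spectral oracle for the generator
oracle_band_power <- function(samples, fs, band) {
  sp <- stats::spec.pgram(stats::ts(samples, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}

oracle_peak_freq <- function(samples, fs, range = c(1, 40)) {
  sp <- stats::spec.pgram(stats::ts(samples, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  keep <- sp$freq >= range[1] & sp$freq <= range[2]
  sp$freq[keep][which.max(sp$spec[keep])]
}

# write a tiny dataset tree of plain-text segment files
write_fixture_tree <- function(root, classes = c("X", "Y"), n = 3,
                               len = 80, seed = 5) {
  set.seed(seed)
  for (cl in classes) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      writeLines(as.character(round(rnorm(len), 4)),
                 file.path(root, cl, sprintf("%s_%02d.txt", cl, i)))
    }
  }
  root
}

# absolute-difference expectation for pinning printed percentages
expect_close <- function(object, expected, tol = 0.011, label = NULL) {
  testthat::expect_lt(abs(object - expected), tol, label = label)
}
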