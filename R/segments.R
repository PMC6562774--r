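## signal IO: the plain-text single-column EEG dialect (one ASCII sample per
## line, as distributed by the public Bonn epilepsy corpus) and a generic
## single-column CSV dialect. Segments are kept raw: no detrending, filtering
## or rescaling is ever applied at read time.

#' Construct an EEG segment
#'
#' A segment is one labelled single-channel recording: a numeric sample vector,
#' its sampling rate, an identifier and a class label. Amplitude units are
#' treated as unitless (the source corpus does not document them).
#'
#' @param samples numeric vector of amplitudes; non-empty, all finite.
#' @param fs sampling rate in Hz (default 173.61, the Bonn corpus rate).
#' @param segment_id character identifier.
#' @param class_label class label, e.g. one of `"A".."E"` or any user label.
#' @return An object of class `"eeg_segment"`.
#' @examples
#' seg <- eeg_segment(sin(2 * pi * 10 * seq(0, 1, by = 1 / 173.61)))
#' seg$fs
#' @export
eeg_segment <- function(samples, fs = 173.61, segment_id = "segment",
                        class_label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop_validation("segment '", segment_id, "': samples must be non-empty")
  }
  if (!all(is.finite(samples))) {
    stop_validation("segment '", segment_id, "': all samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_validation("segment '", segment_id, "': fs must be a positive number")
  }
  structure(
    list(samples = samples, fs = fs,
         segment_id = as.character(segment_id),
         class_label = as.character(class_label)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s  label=%s  n=%d  fs=%.2f Hz  (%.2f s)\n",
              x$segment_id, x$class_label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Read one EEG segment in the plain-text single-column dialect
#'
#' The dialect is one ASCII numeric value per line; surrounding whitespace and
#' trailing blank lines are tolerated. No preprocessing of any kind is applied
#' to the values. Segment length is not constrained to the corpus' 4097
#' samples (that is a property of one dataset, not of the pipeline), so short
#' synthetic fixtures load too.
#'
#' @param path path to the file.
#' @param fs sampling rate in Hz (default 173.61).
#' @param class_label optional class label to attach.
#' @return An [eeg_segment()].
#' @examples
#' f <- tempfile()
#' writeLines(as.character(round(sin(1:100), 4)), f)
#' read_bonn_segment(f, class_label = "A")
#' @export
read_bonn_segment <- function(path, fs = 173.61, class_label = NA_character_) {
  if (!file.exists(path)) {
    stop("cannot read segment file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed))
  if (length(keep) == 0L) {
    stop_validation("segment file is empty: ", path)
  }
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop_validation("non-numeric sample at line ", keep[bad[1L]], " in ", path,
                    ": '", trimmed[keep[bad[1L]]], "'")
  }
  eeg_segment(vals, fs = fs,
              segment_id = tools::file_path_sans_ext(basename(path)),
              class_label = class_label)
}

#' Read one EEG segment from a single-column CSV file
#'
#' @param path path to the CSV file.
#' @param column column name (when the file has a header) or index holding the
#'   samples; default 1.
#' @param header whether the file has a header row; default auto-detected from
#'   the first line.
#' @inheritParams read_bonn_segment
#' @return An [eeg_segment()].
#' @export
read_csv_segment <- function(path, fs = 173.61, column = 1L, header = NA,
                             class_label = NA_character_) {
  if (!file.exists(path)) stop("cannot read segment file: ", path)
  if (is.na(header)) {
    first <- readLines(path, n = 1L)
    header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  }
  df <- utils::read.csv(path, header = header)
  if (is.character(column) && !column %in% names(df)) {
    stop_validation("column '", column, "' not found in ", path)
  }
  vals <- df[[column]]
  if (!is.numeric(vals)) {
    stop_validation("column '", column, "' in ", path, " is not numeric")
  }
  eeg_segment(vals, fs = fs,
              segment_id = tools::file_path_sans_ext(basename(path)),
              class_label = class_label)
}

#' Write a segment in the plain-text single-column dialect
#'
#' Values are written with [format()] at full precision (17 significant
#' digits), so integer-valued segments round-trip exactly and real-valued ones
#' round-trip to full double precision.
#'
#' @param segment an [eeg_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_segment <- function(segment, path) {
  stopifnot(inherits(segment, "eeg_segment"))
  writeLines(format(segment$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Construct a labelled EEG dataset
#'
#' @param segments list of [eeg_segment()] objects.
#' @param classes ordered character vector of class labels; defaults to the
#'   sorted distinct labels present.
#' @return An object of class `"eeg_dataset"`.
#' @export
eeg_dataset <- function(segments, classes = NULL) {
  stopifnot(is.list(segments), length(segments) > 0L)
  labels <- vapply(segments, function(s) s$class_label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  missing_cls <- setdiff(labels, classes)
  if (length(missing_cls) > 0L) {
    stop_validation("segment labels not in declared classes: ",
                    paste(unique(missing_cls), collapse = ", "))
  }
  structure(list(segments = segments, classes = as.character(classes)),
            class = "eeg_dataset")
}

#' Per-class segment counts of a dataset
#'
#' @param dataset an [eeg_dataset()].
#' @return Named integer vector, one entry per declared class (0 where empty).
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  labels <- vapply(dataset$segments, function(s) s$class_label, character(1))
  counts <- vapply(dataset$classes, function(cl) sum(labels == cl), integer(1))
  names(counts) <- dataset$classes
  counts
}

#' @export
print.eeg_dataset <- function(x, ...) {
  counts <- class_counts(x)
  cat(sprintf("<eeg_dataset> %d segments, %d classes\n",
              length(x$segments), length(x$classes)))
  cat(paste(sprintf("  %s: %d", names(counts), counts), collapse = "\n"), "\n")
  invisible(x)
}

#' Keep only the segments of selected classes
#'
#' Class-subset runs (e.g. healthy-vs-ictal "A-E") are the experimental axis
#' of the pipeline; this restricts a dataset to one such subset.
#'
#' @param dataset an [eeg_dataset()].
#' @param classes character vector of labels to keep (>= 2 distinct).
#' @return An [eeg_dataset()] with `classes` in the order given.
#' @export
subset_classes <- function(dataset, classes) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  classes <- as.character(classes)
  unknown <- setdiff(classes, dataset$classes)
  if (length(unknown) > 0L) {
    stop_validation("unknown class label(s): ", paste(unknown, collapse = ", "))
  }
  keep <- vapply(dataset$segments, function(s) s$class_label %in% classes,
                 logical(1))
  eeg_dataset(dataset$segments[keep], classes = classes)
}

#' Load a labelled dataset from a directory tree of segment files
#'
#' @param root root directory.
#' @param layout named list/vector mapping class label to a subdirectory (all
#'   files in it) or a glob pattern relative to `root`. Default: every
#'   immediate subdirectory of `root` is one class.
#' @param fs sampling rate in Hz applied to every segment.
#' @param reader file reader, [read_bonn_segment()] (default) or
#'   [read_csv_segment()].
#' @return An [eeg_dataset()]; files are read in lexicographic order per class
#'   so two calls on the same tree yield identical segment order.
#' @export
load_dataset <- function(root, layout = NULL, fs = 173.61,
                         reader = read_bonn_segment) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  if (is.null(layout)) {
    dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (length(dirs) == 0L) {
      stop_validation("no class subdirectories under ", root)
    }
    layout <- stats::setNames(as.list(dirs), dirs)
  }
  segments <- list()
  for (cl in names(layout)) {
    pat <- layout[[cl]]
    target <- file.path(root, pat)
    files <- if (dir.exists(target)) {
      list.files(target, full.names = TRUE)
    } else {
      Sys.glob(target)
    }
    files <- sort(files[!dir.exists(files)])
    if (length(files) == 0L) {
      stop_validation("class '", cl, "' matched no files (layout entry '",
                      pat, "')")
    }
    segments <- c(segments, lapply(files, reader, fs = fs, class_label = cl))
  }
  eeg_dataset(segments, classes = names(layout))
}
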