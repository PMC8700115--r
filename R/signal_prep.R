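#' Fill missing samples by linear interpolation
#'
#' Replaces every missing sample (`NA`) by linear interpolation along time
#' within its channel. Leading and trailing runs of missing values, where a
#' second anchor point does not exist, are filled with the nearest observed
#' value: this preserves the channel's scale instead of extrapolating a trend.
#' Observed samples are returned bit-identically, so the operation is
#' idempotent.
#'
#' @param recording an [activity_recording()], possibly with missing samples.
#' @return the recording with a complete sample matrix.
#' @export
interpolate_missing <- function(recording) {
  stopifnot(inherits(recording, "activity_recording"))
  x <- recording$samples
  tt <- nrow(x)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    miss <- is.na(col)
    if (!any(miss)) next
    obs <- which(!miss)
    if (length(obs) == 0L) {
      stop(sprintf("channel '%s' has no observed values; cannot interpolate",
                   recording$channel_names[j]))
    }
    if (length(obs) == 1L) {
      col[miss] <- col[obs]
    } else {
      # rule = 2: constant (nearest-value) extension beyond the anchors
      filled <- stats::approx(obs, col[obs], xout = which(miss),
                              method = "linear", rule = 2)$y
      col[miss] <- filled
    }
    x[, j] <- col
  }
  recording$samples <- x
  recording
}

#' A windowed dataset of fixed-length multichannel segments
#'
#' @param windows numeric array `n x S x D`.
#' @param labels integer vector of length `n`, 0-based class ids.
#' @param class_names character vector naming class ids `0..C-1`.
#' @param window_length,step segmentation parameters in samples.
#' @param channel_names character vector of length `D`.
#' @return an object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, labels, class_names,
                             window_length = dim(windows)[2],
                             step = window_length,
                             channel_names = NULL) {
  stopifnot(length(dim(windows)) == 3L)
  labels <- as.integer(labels)
  if (length(labels) != dim(windows)[1]) {
    stop("labels length must equal the number of windows")
  }
  if (anyNA(windows)) stop("windowed data may not contain missing values")
  if (length(labels) > 0 &&
      (min(labels) < 0L || max(labels) >= length(class_names))) {
    stop("labels must lie in [0, #classes)")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(windows)[3]))
  }
  structure(
    list(windows = windows, labels = labels, class_names = class_names,
         window_length = as.integer(window_length), step = as.integer(step),
         channel_names = channel_names),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<windowed_dataset> %d windows x %d samples x %d channels (step %d)\n",
              d[1], d[2], d[3], x$step))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Number of sliding windows fitting a recording of length T
#' @noRd
n_windows <- function(T, S, step) {
  if (T < S) 0L else (T - S) %/% step + 1L
}

#' Segment a recording into fixed-length sliding windows
#'
#' Cuts a continuous recording into windows of `window_length` samples taken
#' every `step` samples; window `i` (0-based) covers samples
#' `[i*step + 1, i*step + window_length]`. A recording shorter than one window
#' yields zero windows. Each window is labelled with the task label of its
#' last sample. Windows never span recording boundaries: segment each
#' recording separately and concatenate with [bind_windowed()].
#'
#' @param recording an [activity_recording()] with no missing samples (run
#'   [interpolate_missing()] first).
#' @param task name of the label sequence to use.
#' @param window_length window length S in samples (default 24).
#' @param step stride in samples (default 12).
#' @return a [windowed_dataset()] with `floor((T - S)/step) + 1` windows
#'   (or 0 when `T < S`).
#' @export
segment_windows <- function(recording, task, window_length = 24L, step = 12L) {
  stopifnot(inherits(recording, "activity_recording"))
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 1L || step < 1L) {
    stop("window_length and step must be >= 1")
  }
  if (!task %in% names(recording$labels)) {
    stop(sprintf("unknown task '%s'; recording has: %s", task,
                 paste(names(recording$labels), collapse = ", ")))
  }
  if (anyNA(recording$samples)) {
    stop("recording contains missing samples; run interpolate_missing() first")
  }
  x <- recording$samples
  lab <- recording$labels[[task]]
  tt <- nrow(x)
  n <- n_windows(tt, window_length, step)
  d <- ncol(x)
  windows <- array(0, dim = c(n, window_length, d))
  labels <- integer(n)
  for (i in seq_len(n)) {
    from <- (i - 1L) * step + 1L
    to <- from + window_length - 1L
    windows[i, , ] <- x[from:to, ]
    labels[i] <- lab[to]           # last-sample labelling policy
  }
  windowed_dataset(windows, labels,
                   class_names = recording$class_names[[task]],
                   window_length = window_length, step = step,
                   channel_names = recording$channel_names)
}

#' Concatenate windowed datasets from separate recordings
#'
#' @param ... `windowed_dataset` objects with identical S, D and class sets.
#' @return a single [windowed_dataset()].
#' @export
bind_windowed <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "windowed_dataset")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1]]
  for (p in parts) {
    stopifnot(inherits(p, "windowed_dataset"),
              dim(p$windows)[2] == dim(ref$windows)[2],
              dim(p$windows)[3] == dim(ref$windows)[3],
              identical(p$class_names, ref$class_names))
  }
  ntot <- sum(vapply(parts, function(p) dim(p$windows)[1], 0L))
  d <- dim(ref$windows)
  windows <- array(0, dim = c(ntot, d[2], d[3]))
  labels <- integer(ntot)
  at <- 0L
  for (p in parts) {
    k <- dim(p$windows)[1]
    if (k > 0) {
      windows[at + seq_len(k), , ] <- p$windows
      labels[at + seq_len(k)] <- p$labels
    }
    at <- at + k
  }
  windowed_dataset(windows, labels, ref$class_names,
                   ref$window_length, ref$step, ref$channel_names)
}

#' Subset a windowed dataset by window index
#' @noRd
subset_windows <- function(dataset, idx) {
  windowed_dataset(dataset$windows[idx, , , drop = FALSE],
                   dataset$labels[idx], dataset$class_names,
                   dataset$window_length, dataset$step,
                   dataset$channel_names)
}

#' Random train/validation split of a windowed dataset
#'
#' Uniformly random, seed-reproducible, disjoint split. The validation half
#' receives `round(fraction * n)` windows; the union of the two halves is the
#' input dataset.
#'
#' @param dataset a [windowed_dataset()].
#' @param fraction validation proportion, strictly between 0 and 1
#'   (default 0.05: a random 5\% held out to monitor loss and F1).
#' @param seed integer seed.
#' @return list with elements `train` and `validation`.
#' @export
train_val_split <- function(dataset, fraction = 0.05, seed = 1L) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- dim(dataset$windows)[1]
  if (n < 2L) stop("need at least 2 windows to split")
  n_val <- round(fraction * n)
  idx_val <- withr::with_seed(seed, sample.int(n, n_val))
  list(train = subset_windows(dataset, setdiff(seq_len(n), idx_val)),
       validation = subset_windows(dataset, sort(idx_val)))
}

#' Restrict a windowed dataset to a set of channels
#'
#' Returns the dataset restricted to `channel_indices`, in the requested
#' order, preserving window order and labels.
#'
#' @param dataset a [windowed_dataset()].
#' @param channel_indices 1-based channel indices; no duplicates.
#' @return a [windowed_dataset()] with `D = length(channel_indices)`.
#' @export
select_channels <- function(dataset, channel_indices) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  channel_indices <- as.integer(channel_indices)
  d <- dim(dataset$windows)[3]
  if (length(channel_indices) == 0L) stop("channel index set is empty")
  if (anyDuplicated(channel_indices)) stop("duplicate channel indices")
  if (any(channel_indices < 1L | channel_indices > d)) {
    stop(sprintf("channel indices must lie in [1, %d]", d))
  }
  windowed_dataset(dataset$windows[, , channel_indices, drop = FALSE],
                   dataset$labels, dataset$class_names,
                   dataset$window_length, dataset$step,
                   dataset$channel_names[channel_indices])
}

#' Persist / restore a windowed dataset
#'
#' Single-file binary container embedding the window tensor together with its
#' metadata block (class names, window length, step, channel names).
#'
#' @param dataset a [windowed_dataset()].
#' @param path file path.
#' @return `write_windowed` returns `path` invisibly; `read_windowed` the
#'   restored [windowed_dataset()].
#' @export
write_windowed <- function(dataset, path) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_windowed
#' @export
read_windowed <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "windowed_dataset"))
  x
}
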