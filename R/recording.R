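#' Construct an activity recording
#'
#' An `activity_recording` holds one continuous multichannel recording from a
#' set of body-worn sensors: a `T x D` sample matrix (one column per sensor
#' channel, units vary per channel), plus one integer label sequence per
#' classification task. Missing samples are encoded as `NA` (any non-finite
#' value in an input file is treated as missing); labels may not be missing.
#'
#' @param samples numeric matrix, `T` samples by `D` channels. Non-finite
#'   entries are converted to `NA` (the missing marker).
#' @param labels named list of integer vectors, one per task. Each vector has
#'   length `T`; values are 0-based class ids (`0` conventionally the Null
#'   class).
#' @param channel_names character vector of length `D`. Defaults to
#'   `ch1..chD`.
#' @param sample_rate sampling frequency in Hz.
#' @param class_names named list (same names as `labels`) of character
#'   vectors; entry `k+1` names class id `k`. Optional.
#' @param source_id identity of the file/subject/run the recording came from.
#'
#' @return an object of class `activity_recording`.
#' @export
activity_recording <- function(samples, labels, channel_names = NULL,
                               sample_rate = 30, class_names = NULL,
                               source_id = "recording") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) == 0L) {
    stop("empty recording: no samples (T = 0)")
  }
  if (ncol(samples) < 1L) {
    stop("recording must have at least one channel")
  }
  samples[!is.finite(samples)] <- NA_real_
  if (is.null(channel_names)) {
    channel_names <- colnames(samples)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_names) != ncol(samples)) {
    stop("channel_names length does not match number of channels")
  }
  if (!is.list(labels) || is.null(names(labels)) || any(names(labels) == "")) {
    stop("labels must be a named list of per-task label vectors")
  }
  labels <- lapply(labels, function(l) {
    l <- as.integer(l)
    if (anyNA(l)) stop("label sequences may not contain missing values")
    l
  })
  bad <- vapply(labels, length, 0L) != nrow(samples)
  if (any(bad)) {
    stop(sprintf("label sequence '%s' does not have length T = %d",
                 names(labels)[bad][1], nrow(samples)))
  }
  if (is.null(class_names)) {
    class_names <- lapply(labels, function(l) {
      paste0("class", seq_len(max(l) + 1L) - 1L)
    })
  }
  structure(
    list(samples = samples, channel_names = channel_names,
         sample_rate = sample_rate, labels = labels,
         class_names = class_names, source_id = source_id),
    class = "activity_recording"
  )
}

#' @export
print.activity_recording <- function(x, ...) {
  cat(sprintf("<activity_recording> %s: %d samples x %d channels @ %g Hz\n",
              x$source_id, nrow(x$samples), ncol(x$samples), x$sample_rate))
  cat(sprintf("  tasks: %s\n", paste(names(x$labels), collapse = ", ")))
  nmiss <- sum(is.na(x$samples))
  if (nmiss > 0) cat(sprintf("  missing samples: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.activity_recording <- function(x) dim(x$samples)

#' Read a labelled multichannel recording from delimited text
#'
#' Reads one sample per row from a whitespace- or comma-delimited file. Column
#' roles are given by a column specification: which columns are sensor
#' channels, which column carries the label for each task, and how raw label
#' codes map to contiguous class ids.
#'
#' @param path file to read.
#' @param colspec a list (or path to a YAML file holding one) with elements:
#'   \describe{
#'     \item{channel_cols}{integer vector of 1-based column indices holding
#'       sensor channels.}
#'     \item{label_cols}{named list task -> 1-based column index.}
#'     \item{label_maps}{named list task -> named list mapping raw label code
#'       (as written in the file) to class name; class ids are assigned in
#'       listed order starting at 0.}
#'     \item{channel_names, sample_rate}{optional.}
#'   }
#' @param source_id recording identity; defaults to the file name.
#' @param sep field separator; `""` (default) splits on whitespace.
#'
#' @return an [activity_recording()]. Non-finite channel entries become
#'   missing markers.
#' @export
read_recording <- function(path, colspec, source_id = basename(path),
                           sep = "") {
  if (is.character(colspec) && length(colspec) == 1L) {
    colspec <- yaml::read_yaml(colspec)
  }
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           na.strings = c("NA", "NaN"),
                           colClasses = "numeric")
  channel_cols <- as.integer(colspec$channel_cols)
  need <- max(channel_cols, unlist(colspec$label_cols))
  if (ncol(raw) < need) {
    stop(sprintf("file %s has %d columns; column spec needs %d",
                 path, ncol(raw), need))
  }
  samples <- as.matrix(raw[, channel_cols, drop = FALSE])
  dimnames(samples) <- NULL

  labels <- list()
  class_names <- list()
  for (task in names(colspec$label_cols)) {
    codes <- raw[[colspec$label_cols[[task]]]]
    map <- colspec$label_maps[[task]]
    if (is.null(map)) stop(sprintf("no label map for task '%s'", task))
    code_keys <- names(map)
    idx <- match(as.character(codes), code_keys)
    if (anyNA(idx)) {
      bad <- unique(codes[is.na(idx)])
      stop(sprintf("unknown label code(s) for task '%s': %s",
                   task, paste(bad, collapse = ", ")))
    }
    labels[[task]] <- idx - 1L
    class_names[[task]] <- unname(unlist(map))
  }

  channel_names <- colspec$channel_names
  if (is.null(channel_names)) channel_names <- paste0("ch", channel_cols)
  activity_recording(
    samples, labels, channel_names = channel_names,
    sample_rate = if (is.null(colspec$sample_rate)) 30 else colspec$sample_rate,
    class_names = class_names, source_id = source_id
  )
}

#' Write a recording as delimited text
#'
#' Emits the format [read_recording()] consumes: one row per sample, channel
#' columns first, then one label-code column per task. Missing samples are
#' written as `NaN`. Returns (invisibly) a column specification list that
#' reads the file back.
#'
#' @param recording an [activity_recording()].
#' @param path output file.
#' @param sep field separator (default single space).
#' @return invisibly, the matching `colspec` list.
#' @export
write_recording <- function(recording, path, sep = " ") {
  stopifnot(inherits(recording, "activity_recording"))
  mat <- recording$samples
  lab <- do.call(cbind, recording$labels)
  out <- cbind(mat, lab)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, na = "NaN")
  ntask <- length(recording$labels)
  label_cols <- as.list(ncol(mat) + seq_len(ntask))
  names(label_cols) <- names(recording$labels)
  label_maps <- lapply(names(recording$labels), function(task) {
    cn <- recording$class_names[[task]]
    stats::setNames(as.list(cn), as.character(seq_along(cn) - 1L))
  })
  names(label_maps) <- names(recording$labels)
  invisible(list(
    channel_cols = seq_len(ncol(mat)),
    label_cols = label_cols,
    label_maps = label_maps,
    channel_names = recording$channel_names,
    sample_rate = recording$sample_rate
  ))
}
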