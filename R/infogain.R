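#' Shannon entropy of a count vector
#'
#' Entropy of the empirical distribution `p_j = counts_j / sum(counts)`,
#' with the convention `0 * log(0) = 0`. Base 2 (bits) by default; the base
#' is configurable because published information-gain tables rarely state it.
#'
#' @param class_counts non-negative integer vector with at least one positive
#'   entry.
#' @param base logarithm base (default 2).
#' @return entropy in `log(base)` units (bits for base 2).
#' @export
shannon_entropy <- function(class_counts, base = 2) {
  if (any(class_counts < 0)) stop("counts must be non-negative")
  total <- sum(class_counts)
  if (total <= 0) stop("all counts are zero; entropy undefined")
  p <- class_counts[class_counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Conditional entropy H(A | F) from a joint count table
#'
#' Rows index feature values `v`, columns index classes. Returns
#' `sum_v P(F = v) * H(A | F = v)`; rows with zero total contribute 0.
#'
#' @param joint_counts non-negative `|F| x |A|` count matrix with positive
#'   total.
#' @param base logarithm base (default 2).
#' @return conditional entropy in `log(base)` units.
#' @export
conditional_entropy <- function(joint_counts, base = 2) {
  joint_counts <- as.matrix(joint_counts)
  if (any(joint_counts < 0)) stop("counts must be non-negative")
  total <- sum(joint_counts)
  if (total <= 0) stop("empty joint table")
  row_tot <- rowSums(joint_counts)
  h <- 0
  for (v in which(row_tot > 0)) {
    h <- h + (row_tot[v] / total) * shannon_entropy(joint_counts[v, ], base)
  }
  unname(h)
}

#' Information gain of one discrete feature about the class label
#'
#' `IG(F, A) = H(A) - H(A | F)`: the reduction in label entropy from
#' observing the feature. Computed from the joint count table of the two
#' sequences. Tiny negative values arising from floating-point round-off are
#' clipped to 0.
#'
#' @param feature_values discrete value sequence (any atomic type).
#' @param labels label sequence of the same length.
#' @param base logarithm base (default 2).
#' @return information gain, `>= 0`.
#' @export
channel_info_gain <- function(feature_values, labels, base = 2) {
  if (length(feature_values) != length(labels)) {
    stop("feature and label sequences must have equal length")
  }
  if (length(labels) == 0L) stop("empty sequences")
  joint <- table(feature_values, labels)
  h_a <- shannon_entropy(colSums(joint), base)
  ig <- h_a - conditional_entropy(joint, base)
  max(ig, 0)
}

#' Discretisation of a continuous channel
#'
#' Information gain is defined over discrete feature values; continuous
#' channels are binned first. The default is equal-frequency binning with 20
#' bins, fit on training data only: quantile edges adapt to the heavy-tailed
#' amplitude distributions typical of accelerometer data. Equal-width binning
#' is available as an alternative. Values outside the fitted range clamp to
#' the end bins. A constant channel degrades gracefully to a single bin
#' (information gain 0 downstream).
#'
#' @param training_channel numeric vector the edges are fit on.
#' @param n_bins number of bins, `>= 2` (default 20).
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return an object of class `discretization` holding the interior bin
#'   edges.
#' @export
fit_discretization <- function(training_channel,
                               n_bins = 20L,
                               strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  x <- training_channel[is.finite(training_channel)]
  if (length(x) == 0L) stop("training channel has no observed values")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (strategy == "equal_frequency") {
    probs <- seq_len(n_bins - 1L) / n_bins
    edges <- unique(unname(stats::quantile(x, probs, type = 7)))
  } else {
    r <- range(x)
    if (r[1] == r[2]) {
      edges <- numeric(0)               # constant channel: one bin
    } else {
      edges <- r[1] + diff(r) * seq_len(n_bins - 1L) / n_bins
    }
  }
  structure(list(edges = edges, n_bins = n_bins, strategy = strategy),
            class = "discretization")
}

#' @rdname fit_discretization
#' @param values numeric vector to discretise.
#' @param fitted a fitted `discretization`.
#' @return `apply_discretization` returns an integer bin id per value
#'   (1-based); out-of-range values clamp to the end bins.
#' @export
apply_discretization <- function(values, fitted) {
  stopifnot(inherits(fitted, "discretization"))
  findInterval(values, fitted$edges) + 1L
}

#' Describe the deployable sensor nodes and the channels they own
#'
#' A sensor layout partitions (a subset of) the channel columns among named
#' body-worn sensor nodes; each node `K_i` owns `C_i` contiguous or scattered
#' channels (e.g. a 9-channel IMU: 3 accelerometer + 3 gyroscope +
#' 3 magnetometer axes). Channel blocks must be disjoint.
#'
#' @param sensors named list: sensor name -> integer vector of 1-based channel
#'   indices (each of length `C_i >= 1`).
#' @param total_channels total number of channels D in the data the layout
#'   refers to; defaults to the largest index used.
#' @return an object of class `sensor_layout`.
#' @export
sensor_layout <- function(sensors, total_channels = NULL) {
  if (!is.list(sensors) || is.null(names(sensors)) || any(names(sensors) == "")) {
    stop("sensors must be a named list of channel index vectors")
  }
  sensors <- lapply(sensors, as.integer)
  if (any(vapply(sensors, length, 0L) < 1L)) {
    stop("every sensor must own at least one channel")
  }
  all_idx <- unlist(sensors, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("sensor channel blocks must be disjoint")
  if (any(all_idx < 1L)) stop("channel indices are 1-based")
  if (is.null(total_channels)) total_channels <- max(all_idx)
  if (max(all_idx) > total_channels) {
    stop("sensor channel index exceeds total_channels")
  }
  structure(list(sensors = sensors, total_channels = as.integer(total_channels)),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sensors over %d channels\n",
              length(x$sensors), x$total_channels))
  for (nm in names(x$sensors)) {
    cat(sprintf("  %-12s C=%d  channels %s\n", nm, length(x$sensors[[nm]]),
                paste(x$sensors[[nm]], collapse = ",")))
  }
  invisible(x)
}

#' Read a sensor layout from a YAML config (sensor name -> channel indices)
#' @param path YAML file mapping sensor names to 1-based channel index lists.
#' @return a [sensor_layout()].
#' @export
read_sensor_layout <- function(path) {
  sensor_layout(yaml::read_yaml(path))
}

#' Aggregate per-channel information gain into a per-sensor report
#'
#' The gain of a sensor is the sum of the gains of its channels; the mean
#' mode (`sum / C_i`) normalises by channel count so many-channel sensors are
#' not favoured merely by size. Both rankings are returned, sorted by
#' descending gain with ties broken by sensor declaration order.
#'
#' @param per_channel_gain numeric vector of length `layout$total_channels`.
#' @param layout a [sensor_layout()].
#' @param binning optional description of the discretisation used (echoed in
#'   the report).
#' @return an object of class `infogain_report`: a per-sensor table
#'   (`sensor`, `Ci`, `gain_sum`, `gain_mean`, `rank_sum`, `rank_mean`),
#'   the per-channel vector, and the two orderings `ranking_sum` /
#'   `ranking_mean`.
#' @export
sensor_info_gain <- function(per_channel_gain, layout, binning = NULL) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (length(per_channel_gain) != layout$total_channels) {
    stop("per_channel_gain length must equal the layout's total channels")
  }
  nm <- names(layout$sensors)
  ci <- vapply(layout$sensors, length, 0L)
  gain_sum <- vapply(layout$sensors,
                     function(ix) sum(per_channel_gain[ix]), 0)
  gain_mean <- gain_sum / ci
  # ties broken by declaration order: order() is stable on the second key
  ord_sum <- order(-gain_sum, seq_along(nm))
  ord_mean <- order(-gain_mean, seq_along(nm))
  tab <- data.frame(
    sensor = nm, Ci = ci, gain_sum = unname(gain_sum),
    gain_mean = unname(gain_mean),
    rank_sum = match(seq_along(nm), ord_sum),
    rank_mean = match(seq_along(nm), ord_mean),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(per_channel_gain = unname(per_channel_gain), table = tab,
         ranking_sum = nm[ord_sum], ranking_mean = nm[ord_mean],
         binning = binning, layout = layout),
    class = "infogain_report"
  )
}

#' @export
print.infogain_report <- function(x, ...) {
  cat("<infogain_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank sensors by the information their raw samples carry about the label
#'
#' Computes per-channel information gain on raw (unwindowed) samples: each
#' channel is discretised (default: 20 equal-frequency bins fit on these
#' same samples) and `IG = H(A) - H(A | F)` is evaluated against the task's
#' label sequence. Channel gains are then aggregated per sensor with
#' [sensor_info_gain()]. Use the training portion of the data only.
#'
#' @param recording an [activity_recording()] with no missing samples, or a
#'   plain numeric sample matrix.
#' @param layout a [sensor_layout()] over the recording's channels.
#' @param task task name (required when `recording` is an
#'   `activity_recording`).
#' @param labels label vector (required when `recording` is a matrix).
#' @param n_bins,strategy discretisation controls, see [fit_discretization()].
#' @param base logarithm base (default 2, bits).
#' @return an `infogain_report`.
#' @export
rank_sensors <- function(recording, layout, task = NULL, labels = NULL,
                         n_bins = 20L, strategy = "equal_frequency",
                         base = 2) {
  if (inherits(recording, "activity_recording")) {
    if (is.null(task)) stop("task is required for an activity_recording")
    if (!task %in% names(recording$labels)) {
      stop(sprintf("unknown task '%s'", task))
    }
    labels <- recording$labels[[task]]
    samples <- recording$samples
  } else {
    samples <- as.matrix(recording)
    if (is.null(labels)) stop("labels are required for a plain matrix")
  }
  if (anyNA(samples)) {
    stop("samples contain missing values; run interpolate_missing() first")
  }
  d <- ncol(samples)
  stopifnot(inherits(layout, "sensor_layout"), layout$total_channels == d)
  gains <- vapply(seq_len(d), function(j) {
    disc <- fit_discretization(samples[, j], n_bins = n_bins,
                               strategy = strategy)
    channel_info_gain(apply_discretization(samples[, j], disc), labels,
                      base = base)
  }, 0)
  sensor_info_gain(gains, layout,
                   binning = list(strategy = strategy, n_bins = n_bins,
                                  base = base))
}

#' Greedy selection of the top-n ranked sensors' channels
#'
#' Takes the `n` sensors with the highest information gain under the chosen
#' ranking mode and returns the union of their channel indices, ordered by
#' layout channel order — the channel set a classifier restricted to those
#' sensors sees.
#'
#' @param report an `infogain_report` from [rank_sensors()] /
#'   [sensor_info_gain()].
#' @param n number of sensors to keep, `1 <= n <= #sensors`.
#' @param mode `"sum"` (sensor gain = sum over its channels) or `"mean"`
#'   (per-channel average).
#' @return integer vector of 1-based channel indices.
#' @export
select_top_sensors <- function(report, n, mode = c("sum", "mean")) {
  stopifnot(inherits(report, "infogain_report"))
  mode <- match.arg(mode)
  layout <- report$layout
  k <- length(layout$sensors)
  n <- as.integer(n)
  if (n < 1L || n > k) stop(sprintf("n must lie in [1, %d]", k))
  ranking <- if (mode == "sum") report$ranking_sum else report$ranking_mean
  top <- ranking[seq_len(n)]
  sort(unlist(layout$sensors[top], use.names = FALSE))
}

#' Export an information-gain report as CSV
#'
#' One row per sensor: name, channel count, summed and per-channel-mean gain,
#' and the rank under each mode.
#'
#' @param report an `infogain_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_infogain_csv <- function(report, path) {
  stopifnot(inherits(report, "infogain_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
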