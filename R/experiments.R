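# Experiment drivers: top-n sensor sweeps, layer-stack ablations and
# half-split stability checks. Each run retrains a fresh model from the same
# seeds so that only the factor under study (channel set, stack, half)
# changes.

#' Named ablation layer stacks
#'
#' The catalogue of alternative architectures commonly compared against the
#' default (BN + 2BiLSTM + Attention + Dense): removing attention or batch
#' normalisation, moving them, and varying the number of recurrent/attention
#' layers.
#'
#' @return named list of layer-token vectors, including `"default"`.
#' @export
ablation_structures <- function() {
  list(
    default = c("bn", "bilstm", "bilstm", "attention", "dense"),
    A = c("bn", "bilstm", "bilstm", "dense"),
    B = c("bilstm", "bilstm", "attention", "dense"),
    C = c("bn", "bilstm", "attention", "dense"),
    D = c("bilstm", "bilstm", "bn", "attention", "dense"),
    E = c("bilstm", "bilstm", "attention", "bn", "dense"),
    F = c("bn", "bilstm", "bilstm", "bilstm", "attention", "dense"),
    G = c("bn", rep("bilstm", 4), "attention", "dense"),
    H = c("bn", rep("bilstm", 5), "attention", "dense"),
    I = c("bn", "attention", "bilstm", "bilstm", "dense"),
    J = c("bn", "bilstm", "attention", "bilstm", "dense"),
    K = c("bn", "bilstm", "attention", "bilstm", "attention", "dense"),
    L = c("bn", "attention", "bilstm", "attention", "bilstm", "dense"),
    M = c("bn", "attention", "bilstm", "attention", "bilstm", "attention",
          "dense")
  )
}

#' Human-readable label for a layer stack
#'
#' Collapses runs of BiLSTM tokens, e.g.
#' `c("bn","bilstm","bilstm","attention","dense")` becomes
#' `"BN + 2BiLSTM + Attention + Dense"`.
#'
#' @param stack character vector of layer tokens.
#' @return a single string.
#' @export
structure_label <- function(stack) {
  pretty <- c(bn = "BN", bilstm = "BiLSTM", attention = "Attention",
              dense = "Dense")
  r <- rle(stack)
  # only bilstm runs collapse to a count; other repeated tokens stay separate
  out <- character(0)
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "bilstm") {
      out <- c(out, if (r$lengths[i] > 1) paste0(r$lengths[i], "BiLSTM")
               else "BiLSTM")
    } else {
      out <- c(out, rep(pretty[v], r$lengths[i]))
    }
  }
  paste(out, collapse = " + ")
}

# train a fresh model on (possibly channel-restricted) windows and score it
train_and_score <- function(train_ds, test_ds, model_cfg, train_cfg) {
  model <- build_model(model_cfg)
  fit <- train_model(model, train_ds, train_cfg)
  pred <- predict(fit$model, test_ds)
  f1 <- weighted_f1(test_ds$labels, pred$labels, model_cfg$n_classes)
  list(fit = fit, f1 = f1)
}

#' Top-n information-gain sensor sweep
#'
#' Ranks sensors by information gain on the raw (unwindowed) training
#' samples, then for each requested `n` restricts both windowed sets to the
#' channels of the top-n sensors, retrains a fresh model with the same seeds,
#' and scores weighted F1 on the test windows. Sensor sets are nested by
#' construction: the set at `n` is a prefix of the set at `n + 1`.
#'
#' @param train_recordings list of training [activity_recording()]s (used
#'   both for information gain, unwindowed, and for training windows).
#' @param test_recordings list of test recordings.
#' @param layout a [sensor_layout()].
#' @param task task name.
#' @param mode ranking mode, `"sum"` or `"mean"`.
#' @param n_values increasing integer vector of sensor counts to evaluate;
#'   default `1..#sensors`.
#' @param model_cfg a [model_config()] whose channel dimension will be
#'   adjusted per sweep point.
#' @param train_cfg a [train_config()].
#' @param window_length,step segmentation parameters.
#' @param n_bins,strategy discretisation controls for the ranking.
#' @return an object of class `sweep_result`: a data frame with one row per
#'   `n` (`n`, `sensors`, `weighted_f1`) plus the ranking used.
#' @export
run_sensor_sweep <- function(train_recordings, test_recordings, layout, task,
                             mode = c("sum", "mean"), n_values = NULL,
                             model_cfg, train_cfg,
                             window_length = 24L, step = 12L,
                             n_bins = 20L, strategy = "equal_frequency") {
  mode <- match.arg(mode)
  k <- length(layout$sensors)
  if (is.null(n_values)) n_values <- seq_len(k)
  n_values <- as.integer(n_values)
  if (any(n_values < 1L | n_values > k)) {
    stop(sprintf("n_values must lie in [1, %d]", k))
  }
  if (is.unsorted(n_values, strictly = TRUE)) {
    stop("n_values must be strictly increasing")
  }
  # information gain on raw, unwindowed training samples
  interped <- lapply(train_recordings, interpolate_missing)
  samples <- do.call(rbind, lapply(interped, function(r) r$samples))
  labels <- unlist(lapply(interped, function(r) r$labels[[task]]),
                   use.names = FALSE)
  report <- rank_sensors(samples, layout, labels = labels, n_bins = n_bins,
                         strategy = strategy)

  train_full <- segment_recordings(train_recordings, task, window_length,
                                   step)
  test_full <- segment_recordings(test_recordings, task, window_length, step)

  rows <- lapply(n_values, function(n) {
    ch <- select_top_sensors(report, n, mode = mode)
    cfg_n <- model_cfg
    cfg_n$input_shape[2] <- length(ch)
    sc <- train_and_score(select_channels(train_full, ch),
                          select_channels(test_full, ch), cfg_n, train_cfg)
    ranking <- if (mode == "sum") report$ranking_sum else report$ranking_mean
    data.frame(n = n,
               sensors = paste(ranking[seq_len(n)], collapse = "+"),
               weighted_f1 = sc$f1, stringsAsFactors = FALSE)
  })
  structure(
    list(results = do.call(rbind, rows), mode = mode, task = task,
         report = report),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> task %s, ranking mode %s\n", x$task, x$mode))
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Layer-stack ablation
#'
#' Trains and scores one model per layer stack with shared seeds and a shared
#' train/test split, so differences in weighted F1 reflect the architecture
#' alone. Duplicate structures are deduplicated with a warning.
#'
#' @param structures named list of layer-token vectors (see
#'   [ablation_structures()]).
#' @param train_ds,test_ds [windowed_dataset()]s.
#' @param model_cfg a [model_config()] providing units/dims; its
#'   `layer_stack` is replaced per structure.
#' @param train_cfg a [train_config()].
#' @return data frame: `model`, `structure`, `weighted_f1`.
#' @export
run_ablation <- function(structures, train_ds, test_ds, model_cfg,
                         train_cfg) {
  if (is.null(names(structures))) {
    names(structures) <- paste0("structure", seq_along(structures))
  }
  key <- vapply(structures, paste, "", collapse = "|")
  if (anyDuplicated(key)) {
    warning("duplicate structures supplied; keeping the first of each")
    structures <- structures[!duplicated(key)]
  }
  rows <- lapply(names(structures), function(nm) {
    cfg <- model_cfg
    cfg$layer_stack <- structures[[nm]]
    # revalidate the stack through the constructor
    cfg <- model_config(cfg$input_shape, cfg$n_classes, cfg$layer_stack,
                        cfg$recurrent_units, cfg$attention_dim,
                        cfg$bidir_combine, cfg$seed)
    sc <- train_and_score(train_ds, test_ds, cfg, train_cfg)
    data.frame(model = nm, structure = structure_label(structures[[nm]]),
               weighted_f1 = sc$f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Half-split stability check
#'
#' Randomly divides the training windows into two disjoint halves of equal
#' size, trains one model per half with shared seeds, and evaluates both on
#' the common test set. Close scores indicate the architecture's result is
#' stable under halving the training data.
#'
#' @param train_ds,test_ds [windowed_dataset()]s.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param seed seed for the half split.
#' @return list with `f1_half1`, `f1_half2` and `abs_diff`.
#' @export
run_stability <- function(train_ds, test_ds, model_cfg, train_cfg,
                          seed = 1L) {
  n <- dim(train_ds$windows)[1]
  if (n < 2L) stop("need at least 2 training windows")
  if (dim(test_ds$windows)[1] < 1L) stop("empty test set")
  halves <- train_val_split(train_ds, fraction = 0.5, seed = seed)
  s1 <- train_and_score(halves$train, test_ds, model_cfg, train_cfg)
  s2 <- train_and_score(halves$validation, test_ds, model_cfg, train_cfg)
  list(f1_half1 = s1$f1, f1_half2 = s2$f1,
       abs_diff = abs(s1$f1 - s2$f1))
}
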