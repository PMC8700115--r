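# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive and coded separately from the package
# internals it cross-checks.

# Shannon entropy straight from the definition, probability by probability.
oracle_entropy <- function(counts, base = 2) {
  p <- counts / sum(counts)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi, base = base)
  s
}

# Information gain by exhaustive enumeration of the joint counts of two
# sequences: H(A) - sum_v P(v) H(A | v), one explicit loop per feature value.
oracle_info_gain <- function(f, a, base = 2) {
  n <- length(a)
  h_a <- oracle_entropy(table(a), base)
  h_cond <- 0
  for (v in unique(f)) {
    sel <- f == v
    h_cond <- h_cond + (sum(sel) / n) * oracle_entropy(table(a[sel]), base)
  }
  h_a - h_cond
}

# Weighted F1 from per-class tallies, no confusion matrix.
oracle_weighted_f1 <- function(y_true, y_pred, n_classes) {
  n <- length(y_true)
  total <- 0
  for (j in seq_len(n_classes) - 1L) {
    tp <- sum(y_true == j & y_pred == j)
    support <- sum(y_true == j)
    predicted <- sum(y_pred == j)
    p <- if (predicted > 0) tp / predicted else 0
    r <- if (support > 0) tp / support else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    total <- total + (support / n) * f
  }
  total
}

# Sliding-window count by naive start-offset enumeration.
oracle_n_windows <- function(T, S, step) {
  n <- 0L
  start <- 1L
  while (start + S - 1L <= T) {
    n <- n + 1L
    start <- start + step
  }
  n
}

# Minimal recording: deterministic ramp samples, explicit labels.
make_recording <- function(T = 30, D = 2, labels = NULL, tasks = "activity") {
  samples <- matrix(seq_len(T * D), T, D)
  if (is.null(labels)) labels <- rep_len(0:1, T)
  lab <- stats::setNames(rep(list(as.integer(labels)), length(tasks)), tasks)
  activity_recording(samples, lab,
                     class_names = stats::setNames(
                       rep(list(c("Null", "Act")), length(tasks)), tasks))
}

# Small, quickly separable windowed dataset for training tests.
make_separable_dataset <- function(T = 3000, seed = 5) {
  spec <- synthetic_spec(n_classes = 2, class_priors = c(0.5, 0.5),
                         n_sensors = 2, channels_per_sensor = 3,
                         informativeness = c(1, 0.9), missing_rate = 0,
                         T = T, seed = seed)
  segment_windows(generate_recording(spec), "activity", 24, 12)
}

# Tiny model configuration used wherever a full-size network is unnecessary.
tiny_model_config <- function(S = 24, D = 6, n_classes = 2, units = 8,
                              stack = c("bn", "bilstm", "bilstm",
                                        "attention", "dense"), seed = 42) {
  model_config(c(S, D), n_classes = n_classes, layer_stack = stack,
               recurrent_units = units, seed = seed)
}

# Synthetic Opportunity-format session files (250 whitespace-delimited
# columns) for loader tests; tiny and generated on the fly.
write_fake_opportunity <- function(path, T = 40, seed = 1) {
  withr::with_seed(seed, {
    row_data <- matrix(round(stats::rnorm(T * 242), 3), T, 242)
    ml_codes <- sample(c(0, 1, 2, 4, 5), T, replace = TRUE)
    gr_codes <- sample(c(0, 406516, 404516, 407521), T, replace = TRUE)
    other_labels <- matrix(0, T, 5)
    tbl <- cbind(seq_len(T) * 33, row_data, ml_codes, other_labels, gr_codes)
    utils::write.table(tbl, path, row.names = FALSE, col.names = FALSE)
  })
  path
}
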