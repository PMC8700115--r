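# Preprocessing: missing-value interpolation, sliding-window segmentation,
# train/validation splitting and channel selection.

test_that("linear interpolation fills gaps and extends edges with nearest values", {
  rec <- make_recording(T = 3, D = 3)
  rec$samples[, 1] <- c(1, NA, 3)
  rec$samples[, 2] <- c(NA, 2, 4)
  rec$samples[, 3] <- c(5, 6, NA)
  out <- interpolate_missing(rec)
  expect_equal(out$samples[, 1], c(1, 2, 3))        # midpoint
  expect_equal(out$samples[, 2], c(2, 2, 4))        # leading run -> nearest
  expect_equal(out$samples[, 3], c(5, 6, 6))        # trailing run -> nearest
})

test_that("interpolation leaves observed samples bit-identical and is idempotent", {
  spec <- synthetic_spec(T = 500, missing_rate = 0.1, seed = 3)
  rec <- generate_recording(spec)
  obs <- !is.na(rec$samples)
  once <- interpolate_missing(rec)
  expect_identical(once$samples[obs], rec$samples[obs])
  twice <- interpolate_missing(once)
  expect_identical(twice$samples, once$samples)

  clean <- generate_recording(synthetic_spec(T = 100, missing_rate = 0,
                                             seed = 4))
  expect_identical(interpolate_missing(clean)$samples, clean$samples)
})

test_that("interpolation rejects unfixable inputs", {
  rec <- make_recording(T = 4, D = 2)
  rec$samples[, 2] <- NA_real_
  expect_error(interpolate_missing(rec), "ch2")
  expect_error(activity_recording(matrix(numeric(0), 0, 2),
                                  list(activity = integer(0))),
               "empty")
})

test_that("segmentation counts match the start-offset formula and edge cases", {
  expect_equal(dim(segment_windows(make_recording(T = 24), "activity",
                                   24, 12)$windows)[1], 1)
  expect_equal(dim(segment_windows(make_recording(T = 60), "activity",
                                   24, 12)$windows)[1], 4)
  expect_equal(dim(segment_windows(make_recording(T = 23), "activity",
                                   24, 12)$windows)[1], 0)
})

test_that("segmentation agrees with naive enumeration on a randomised grid", {
  withr::with_seed(99, {
    for (k in 1:40) {
      T <- sample(1:200, 1)
      S <- sample(1:48, 1)
      step <- sample(1:24, 1)
      rec <- make_recording(T = T, D = 2)
      ds <- segment_windows(rec, "activity", S, step)
      expect_equal(dim(ds$windows)[1], oracle_n_windows(T, S, step),
                   info = sprintf("T=%d S=%d step=%d", T, S, step))
      n <- dim(ds$windows)[1]
      if (n > 0) {
        i <- sample(n, 1)
        from <- (i - 1) * step + 1
        expect_equal(ds$windows[i, , ], rec$samples[from:(from + S - 1), ])
        expect_equal(ds$labels[i], rec$labels$activity[from + S - 1])
      }
    }
  })
})

test_that("window label is the label of the last sample", {
  labels <- c(rep(0L, 23), 1L)                      # Null x23 then Stand
  rec <- make_recording(T = 24, labels = labels)
  ds <- segment_windows(rec, "activity", 24, 12)
  expect_equal(ds$labels, 1L)
})

test_that("segmentation validates its inputs", {
  rec <- make_recording(T = 30)
  expect_error(segment_windows(rec, "nope", 24, 12), "unknown task")
  rec$samples[3, 1] <- NA
  expect_error(segment_windows(rec, "activity", 24, 12), "missing")
})

test_that("train/val split is disjoint, exhaustive, sized and reproducible", {
  ds <- make_separable_dataset(T = 1300, seed = 8)
  n <- dim(ds$windows)[1]
  sp <- train_val_split(ds, fraction = 0.05, seed = 11)
  n_val <- dim(sp$validation$windows)[1]
  expect_equal(n_val, round(0.05 * n))
  expect_equal(dim(sp$train$windows)[1] + n_val, n)

  sp2 <- train_val_split(ds, fraction = 0.05, seed = 11)
  expect_identical(sp$validation$windows, sp2$validation$windows)
  expect_identical(sp$train$labels, sp2$train$labels)

  half <- train_val_split(ds, fraction = 0.5, seed = 2)
  expect_equal(dim(half$train$windows)[1], n - round(n / 2))
  # union of halves recovers every window exactly once (match rows by sum)
  sig <- function(w) sort(apply(w, 1, sum))
  expect_equal(sort(c(apply(half$train$windows, 1, sum),
                      apply(half$validation$windows, 1, sum))),
               sig(ds$windows))
  expect_error(train_val_split(ds, fraction = 1.2), "fraction")
})

test_that("select_channels projects, preserves order, and composes", {
  ds <- make_separable_dataset(T = 600, seed = 9)
  d <- dim(ds$windows)[3]
  expect_identical(select_channels(ds, seq_len(d))$windows, ds$windows)

  one <- select_channels(ds, 1)
  expect_equal(dim(one$windows)[3], 1)
  expect_equal(one$windows[, , 1], ds$windows[, , 1])

  swapped <- select_channels(ds, c(3, 1))
  expect_equal(swapped$windows[, , 1], ds$windows[, , 3])
  expect_equal(swapped$windows[, , 2], ds$windows[, , 1])
  expect_equal(swapped$channel_names, ds$channel_names[c(3, 1)])

  # composition equals index composition
  a <- select_channels(select_channels(ds, c(5, 2, 4)), c(3, 1))
  b <- select_channels(ds, c(5, 2, 4)[c(3, 1)])
  expect_identical(a$windows, b$windows)

  expect_error(select_channels(ds, integer(0)), "empty")
  expect_error(select_channels(ds, c(1, 1)), "duplicate")
  expect_error(select_channels(ds, d + 1), "indices")
})

test_that("windowed datasets round-trip through the on-disk container", {
  ds <- make_separable_dataset(T = 400, seed = 10)
  path <- tempfile(fileext = ".rds")
  write_windowed(ds, path)
  back <- read_windowed(path)
  expect_identical(back$windows, ds$windows)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$class_names, ds$class_names)
  expect_identical(back$step, ds$step)
  unlink(path)
})

test_that("delimited-text recordings round-trip through read_recording", {
  spec <- synthetic_spec(T = 120, missing_rate = 0.05, seed = 12)
  rec <- generate_recording(spec)
  path <- tempfile(fileext = ".txt")
  colspec <- write_recording(rec, path)
  back <- read_recording(path, colspec, source_id = rec$source_id)
  expect_equal(back$samples, rec$samples)
  expect_identical(back$labels$activity, rec$labels$activity)
  expect_identical(back$class_names$activity, rec$class_names$activity)
  unlink(path)
})
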