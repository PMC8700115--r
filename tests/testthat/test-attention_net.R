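# The attention BiLSTM classifier: construction, attention pooling,
# bidirectionality, prediction contracts, gradients and the training loop.

test_that("model builds from the default stack and emits probability rows", {
  cfg <- tiny_model_config(S = 12, D = 4, n_classes = 3, units = 6)
  m <- build_model(cfg)
  X <- withr::with_seed(1, array(rnorm(5 * 12 * 4), c(5, 12, 4)))
  p <- predict(m, X)
  expect_equal(dim(p$probabilities), c(5, 3))
  expect_equal(rowSums(p$probabilities), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p$probabilities >= 0))
})

test_that("zeroed dense weights give uniform class probabilities", {
  cfg <- tiny_model_config(S = 8, D = 3, n_classes = 4, units = 5)
  m <- build_model(cfg)
  k <- length(m$layers)
  m$layers[[k]]$params$W[] <- 0
  m$layers[[k]]$params$b[] <- 0
  X <- withr::with_seed(2, array(rnorm(3 * 8 * 3), c(3, 8, 3)))
  p <- predict(m, X)
  expect_equal(p$probabilities, matrix(0.25, 3, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("stacks without attention classify from the last timestep", {
  cfg <- tiny_model_config(S = 6, D = 3, n_classes = 2, units = 4,
                           stack = c("bn", "bilstm", "bilstm", "dense"))
  m <- build_model(cfg)
  expect_true(m$layers[[length(m$layers)]]$take_last)
  X <- withr::with_seed(3, array(rnorm(4 * 6 * 3), c(4, 6, 3)))
  p <- predict(m, X)
  expect_equal(rowSums(p$probabilities), rep(1, 4), tolerance = 1e-6)
})

test_that("malformed stacks are rejected with the offending tokens", {
  expect_error(model_config(c(8, 3), 2, layer_stack = c("bn", "bilstm")),
               "dense")
  expect_error(model_config(c(8, 3), 2,
                            layer_stack = c("dense", "bilstm", "dense")),
               "dense")
  expect_error(model_config(c(8, 3), 2, layer_stack = c("bn", "lstm",
                                                        "dense")),
               "lstm")
  # recurrent layer after a pooled vector is structurally impossible
  expect_error(
    build_model(model_config(c(8, 3), 2,
                             layer_stack = c("bilstm", "attention", "dense",
                                             "bilstm", "dense"))),
    "dense")
})

test_that("attention weights live on the simplex and pool convexly", {
  withr::with_seed(21, {
    for (k in 1:20) {
      S <- sample(1:10, 1)
      h <- sample(2:8, 1)
      m <- build_model(tiny_model_config(S = max(S, 2), D = 3, units = h))
      params <- m$layers[[4]]$params      # attention layer of default stack
      H <- matrix(rnorm(S * 2 * h), S, 2 * h)
      r <- attention_pool(H, params)
      expect_equal(sum(r$weights), 1, tolerance = 1e-6)
      expect_true(all(r$weights >= 0))
      expect_equal(r$context, as.vector(t(H) %*% r$weights),
                   tolerance = 1e-10)
    }
  })
})

test_that("attention over identical timesteps returns that state exactly", {
  m <- build_model(tiny_model_config(S = 5, D = 3, units = 4))
  params <- m$layers[[4]]$params
  h <- withr::with_seed(5, rnorm(8))
  H <- matrix(h, 5, 8, byrow = TRUE)
  r <- attention_pool(H, params)
  expect_equal(r$context, h, tolerance = 1e-12)
  one <- attention_pool(matrix(h, 1, 8), params)
  expect_equal(one$weights, 1.0)
  expect_equal(one$context, h)
})

test_that("attention-layer analytic gradients match numerical differentiation", {
  ns <- asNamespace("harsense")
  withr::with_seed(33, {
    S <- 3; din <- 4; adim <- 3; B <- 2
    params <- ns$attn_init(din, adim)
    X <- array(rnorm(B * S * din), c(B, S, din))
    probe <- rnorm(din)                     # fixed linear functional
    loss <- function(p) sum(ns$attn_forward(X, p, pool = TRUE)$out %*% probe)
    fw <- ns$attn_forward(X, params, pool = TRUE)
    dOut <- matrix(probe, B, din, byrow = TRUE)
    g <- ns$attn_backward(dOut, params, fw$cache)$grads
    eps <- 1e-6
    for (nm in names(params)) {
      for (k in seq_along(params[[nm]])) {
        p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
        p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - eps
        num <- (loss(p1) - loss(p2)) / (2 * eps)
        expect_equal(g[[nm]][k], num, tolerance = 1e-4,
                     info = sprintf("param %s[%d]", nm, k))
      }
    }
  })
})

test_that("reversing time swaps the roles of the two directions", {
  ns <- asNamespace("harsense")
  withr::with_seed(12, {
    B <- 3; S <- 7; D <- 4; H <- 5
    p <- ns$bilstm_init(D, H)
    X <- array(rnorm(B * S * D), c(B, S, D))
    Xrev <- X[, S:1, , drop = FALSE]
    out <- ns$bilstm_forward(X, p, "concat")$out
    # mirrored parameters: forward cell <-> reverse cell
    p_sw <- list(fwd = p$rev, rev = p$fwd)
    out_sw <- ns$bilstm_forward(Xrev, p_sw, "concat")$out
    # state emitted for timestep t now sits at S+1-t with directions swapped
    expect_equal(out_sw[, S:1, c(H + 1:H, 1:H), drop = FALSE], out,
                 tolerance = 1e-5, ignore_attr = TRUE)
  })
})

test_that("prediction is deterministic, batch-size invariant and tie-breaks low", {
  ds <- make_separable_dataset(T = 800, seed = 14)
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  all_at_once <- predict(m, ds)$probabilities
  one_by_one <- do.call(rbind, lapply(seq_len(dim(ds$windows)[1]), function(i) {
    predict(m, ds$windows[i, , , drop = FALSE])$probabilities
  }))
  expect_equal(one_by_one, all_at_once, tolerance = 1e-12)

  expect_equal(max.col(rbind(c(0.1, 0.7, 0.2)), ties.method = "first") - 1L, 1L)
  tied <- list(probabilities = rbind(c(0.5, 0.5)))
  expect_equal(max.col(tied$probabilities, ties.method = "first") - 1L, 0L)

  empty <- predict(m, array(0, c(0, 24, 6)))
  expect_equal(length(empty$labels), 0)
  expect_equal(nrow(empty$probabilities), 0)

  bad <- array(0, c(2, 24, 7))
  expect_error(predict(m, bad), "shape")
})

test_that("training learns a separable stream, checkpoints the best F1 and reproduces", {
  ds <- make_separable_dataset(T = 3000, seed = 15)
  cfg <- tiny_model_config(units = 8, seed = 42)
  tc <- train_config(max_epochs = 3, seed = 7)
  fit <- train_model(build_model(cfg), ds, tc)
  expect_equal(nrow(fit$history), 3)
  expect_gte(max(fit$history$val_f1), 0.95)
  expect_equal(fit$best_epoch, which.max(fit$history$val_f1))

  fit2 <- train_model(build_model(cfg), ds, tc)
  expect_identical(fit$history, fit2$history)

  # returned parameters are the best-validation snapshot: rescoring the
  # validation split with the returned model reproduces the best F1
  sp <- train_val_split(ds, tc$validation_fraction, seed = tc$seed + 1L)
  pv <- predict(fit$model, sp$validation)
  expect_equal(weighted_f1(sp$validation$labels, pv$labels, 2),
               max(fit$history$val_f1), tolerance = 1e-12)
})

test_that("early stopping triggers after patience epochs without improvement", {
  ds <- make_separable_dataset(T = 700, seed = 16)
  cfg <- tiny_model_config(units = 4, seed = 1)
  # learning rate 0: the loss can never improve after epoch 1
  tc <- train_config(learning_rate = 0, patience = 2, max_epochs = 50,
                     seed = 3)
  fit <- train_model(build_model(cfg), ds, tc)
  expect_equal(fit$stopped_epoch, 3)      # epoch 1 sets the bar; 2 strikes
  expect_equal(nrow(fit$history), 3)
})

test_that("single-class training data is rejected", {
  ds <- make_separable_dataset(T = 700, seed = 17)
  keep <- ds$labels == ds$labels[1]
  mono <- windowed_dataset(ds$windows[keep, , , drop = FALSE],
                           ds$labels[keep], ds$class_names,
                           ds$window_length, ds$step, ds$channel_names)
  expect_error(train_model(build_model(tiny_model_config()), mono,
                           train_config(max_epochs = 1)),
               "single class")
})

test_that("checkpoints round-trip through save_model/load_model", {
  ds <- make_separable_dataset(T = 700, seed = 18)
  cfg <- tiny_model_config(units = 4, seed = 2)
  fit <- train_model(build_model(cfg), ds, train_config(max_epochs = 1,
                                                        seed = 5))
  path <- tempfile(fileext = ".rds")
  save_model(fit$model, path)
  back <- load_model(path)
  expect_identical(predict(back, ds)$probabilities,
                   predict(fit$model, ds)$probabilities)
  expect_identical(back$config$layer_stack, cfg$layer_stack)
  unlink(path)

  hist_path <- tempfile(fileext = ".csv")
  write_history_csv(fit$history, hist_path)
  expect_equal(utils::read.csv(hist_path)$epoch, fit$history$epoch)
  unlink(hist_path)
})
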