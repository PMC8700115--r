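#' Configuration of the attention BiLSTM classifier
#'
#' The default architecture is: batch normalisation of the input windows, two
#' stacked bidirectional LSTM layers emitting hidden states at every
#' timestep, a temporal attention layer that pools the state sequence into a
#' single context vector, and a dense softmax output with one unit per
#' activity class. Alternative layer stacks (used in ablation studies) are
#' expressed as token sequences.
#'
#' An `attention` token placed immediately before the final stages (`dense`,
#' optionally with an intervening `bn`) pools the sequence into a context
#' vector; an `attention` token followed by further recurrent/attention
#' layers instead re-weights the sequence (each timestep scaled by its
#' softmax weight), keeping the time axis so the next layer can consume it.
#' A stack without any pooling attention classifies from the last timestep's
#' state.
#'
#' @param input_shape integer vector `c(S, D)`: window length and channels.
#' @param n_classes number of activity classes.
#' @param layer_stack character vector of tokens from
#'   `{"bn", "bilstm", "attention", "dense"}`, ending in `"dense"`.
#' @param recurrent_units LSTM units per direction (default 192).
#' @param attention_dim dimension of the attention projection; defaults to
#'   the dimension of the states entering the attention layer (2 x units for
#'   concatenated directions).
#' @param bidir_combine how forward and reverse states are combined:
#'   `"concat"` (default) concatenates them; `"sum"` takes a tanh of a
#'   learned scalar-weighted sum.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_shape, n_classes,
                         layer_stack = c("bn", "bilstm", "bilstm",
                                         "attention", "dense"),
                         recurrent_units = 192L,
                         attention_dim = NULL,
                         bidir_combine = c("concat", "sum"),
                         seed = 42L) {
  bidir_combine <- match.arg(bidir_combine)
  stopifnot(length(input_shape) == 2L, all(input_shape >= 1L),
            n_classes >= 2L, recurrent_units >= 1L)
  bad <- setdiff(layer_stack, c("bn", "bilstm", "attention", "dense"))
  if (length(bad) > 0) {
    stop(sprintf("unknown layer token(s): %s", paste(bad, collapse = ", ")))
  }
  if (layer_stack[length(layer_stack)] != "dense" ||
      sum(layer_stack == "dense") != 1L) {
    stop(sprintf("layer stack must end with a single 'dense' token, got: %s",
                 paste(layer_stack, collapse = " + ")))
  }
  structure(
    list(input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes),
         layer_stack = layer_stack,
         recurrent_units = as.integer(recurrent_units),
         attention_dim = attention_dim,
         bidir_combine = bidir_combine,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Training protocol configuration
#'
#' Mirrors the training regime the network is designed for: Adadelta with
#' initial learning rate 1.0, batch size 16, a random 5\% of the training
#' windows held out to monitor loss and weighted F1 each epoch, early
#' stopping when the training loss has not decreased for `patience`
#' consecutive epochs, and checkpointing of the parameters with the highest
#' validation weighted F1.
#'
#' @param learning_rate Adadelta learning-rate multiplier (default 1.0).
#' @param batch_size windows per gradient step (default 16).
#' @param patience epochs without training-loss improvement before stopping
#'   (default 50).
#' @param validation_fraction held-out fraction of the training windows
#'   (default 0.05).
#' @param max_epochs upper bound on epochs (default 300; early stopping
#'   normally triggers first).
#' @param rho,epsilon Adadelta decay rate and stabiliser.
#' @param seed master seed; the validation split and every epoch's shuffle
#'   draw dedicated seeds derived from it, so runs are fully reproducible.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1.0, batch_size = 16L,
                         patience = 50L, validation_fraction = 0.05,
                         max_epochs = 300L, rho = 0.95, epsilon = 1e-6,
                         seed = 1L, verbose = FALSE) {
  stopifnot(patience >= 1L, batch_size >= 1L, max_epochs >= 1L,
            validation_fraction > 0, validation_fraction < 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         patience = as.integer(patience),
         validation_fraction = validation_fraction,
         max_epochs = as.integer(max_epochs), rho = rho, epsilon = epsilon,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

# decide, for each attention token, whether it pools (everything after it is
# bn/dense) or re-weights the sequence
attention_pools <- function(stack) {
  vapply(seq_along(stack), function(i) {
    stack[i] == "attention" &&
      all(stack[seq_along(stack) > i] %in% c("bn", "dense"))
  }, TRUE)
}

#' Build an attention BiLSTM model
#'
#' Initialises all parameters (symmetric uniform fan-based scheme; LSTM
#' forget-gate biases start at 1, the attention context vector is randomly
#' initialised and trained) and returns a trainable model handle.
#'
#' @param config a [model_config()].
#' @return an object of class `har_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  stack <- config$layer_stack
  pools <- attention_pools(stack)
  units <- config$recurrent_units
  layers <- withr::with_seed(config$seed, {
    cur <- config$input_shape[2]
    is_seq <- TRUE
    lapply(seq_along(stack), function(i) {
      tok <- stack[i]
      if (tok == "bn") {
        l <- list(type = "bn", params = bn_init(cur),
                  state = bn_state_init(cur), dim = cur)
      } else if (tok == "bilstm") {
        if (!is_seq) {
          stop(sprintf(
            "invalid stack [%s]: 'bilstm' at position %d receives a pooled vector",
            paste(stack, collapse = ", "), i))
        }
        l <- list(type = "bilstm",
                  params = bilstm_init(cur, units, config$bidir_combine),
                  combine = config$bidir_combine)
        cur <<- bilstm_out_dim(units, config$bidir_combine)
      } else if (tok == "attention") {
        if (!is_seq) {
          stop(sprintf(
            "invalid stack [%s]: 'attention' at position %d receives a pooled vector",
            paste(stack, collapse = ", "), i))
        }
        adim <- if (is.null(config$attention_dim)) cur
                else as.integer(config$attention_dim)
        l <- list(type = "attention", params = attn_init(cur, adim),
                  pool = pools[i])
        if (pools[i]) is_seq <<- FALSE
      } else {                        # dense
        l <- list(type = "dense",
                  params = dense_init(cur, config$n_classes),
                  take_last = is_seq)
        cur <<- config$n_classes
      }
      l
    })
  })
  structure(list(config = config, layers = layers), class = "har_model")
}

#' @export
print.har_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<har_model> input %d x %d -> %d classes\n",
              cfg$input_shape[1], cfg$input_shape[2], cfg$n_classes))
  cat(sprintf("  stack: %s (units %d, combine %s)\n",
              paste(cfg$layer_stack, collapse = " + "),
              cfg$recurrent_units, cfg$bidir_combine))
  n_par <- sum(rapply(lapply(x$layers, `[[`, "params"), length,
                      how = "unlist"))
  cat(sprintf("  parameters: %d\n", n_par))
  invisible(x)
}

# forward pass through the full stack; returns probabilities, per-layer
# caches, and the model (whose BN running statistics advance when training)
net_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  cur <- X
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "bn") {
      r <- bn_forward(cur, l$params, l$state, training = training)
      model$layers[[i]]$state <- r$state
      caches[[i]] <- r$cache
      cur <- r$out
    } else if (l$type == "bilstm") {
      r <- bilstm_forward(cur, l$params, l$combine)
      caches[[i]] <- r$cache
      cur <- r$out
    } else if (l$type == "attention") {
      r <- attn_forward(cur, l$params, pool = l$pool)
      caches[[i]] <- r$cache
      cur <- r$out
    } else {                          # dense
      if (l$take_last) {
        S <- dim(cur)[2]
        caches_last <- list(S = S, in_dims = dim(cur))
        cur <- slice_t(cur, S)
        r <- dense_forward(cur, l$params)
        caches[[i]] <- c(r$cache, caches_last)
      } else {
        r <- dense_forward(cur, l$params)
        caches[[i]] <- r$cache
      }
      cur <- r$out
    }
  }
  list(probs = cur, caches = caches, model = model)
}

# backward pass; returns grads as a list parallel to layers
net_backward <- function(model, caches, probs, y) {
  n_layers <- length(model$layers)
  grads <- vector("list", n_layers)
  i <- n_layers
  l <- model$layers[[i]]
  r <- dense_backward_ce(probs, y, l$params, caches[[i]])
  grads[[i]] <- r$grads
  d <- r$dV
  if (isTRUE(l$take_last)) {
    full <- array(0, caches[[i]]$in_dims)
    full[, caches[[i]]$S, ] <- d
    d <- full
  }
  for (i in rev(seq_len(n_layers - 1L))) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      bn = bn_backward(d, l$params, caches[[i]]),
      bilstm = bilstm_backward(d, l$params, caches[[i]]),
      attention = attn_backward(d, l$params, caches[[i]])
    )
    grads[[i]] <- r$grads
    d <- r$dX
  }
  grads
}

## ---- Adadelta --------------------------------------------------------------

adadelta_init <- function(params) {
  rapply(params, function(p) list(Eg2 = p * 0, Edx2 = p * 0),
         how = "list", classes = "ANY")
}

# walks the (possibly nested) parameter list in lockstep with gradients and
# optimiser state
adadelta_step <- function(params, grads, state, lr, rho, eps) {
  if (is.list(params)) {
    for (k in seq_along(params)) {
      r <- adadelta_step(params[[k]], grads[[k]], state[[k]], lr, rho, eps)
      params[[k]] <- r$params
      state[[k]] <- r$state
    }
    return(list(params = params, state = state))
  }
  g <- grads
  st <- state
  st$Eg2 <- rho * st$Eg2 + (1 - rho) * g * g
  dx <- -sqrt(st$Edx2 + eps) / sqrt(st$Eg2 + eps) * g
  st$Edx2 <- rho * st$Edx2 + (1 - rho) * dx * dx
  list(params = params + lr * dx, state = st)
}

## ---- training --------------------------------------------------------------

#' Train an attention BiLSTM model
#'
#' Splits off a validation fraction, minimises mean cross-entropy with
#' Adadelta (initial rate 1.0, batch size 16 by default), stops early when
#' the training loss has not decreased for `patience` consecutive epochs,
#' and returns the parameter snapshot with the highest validation weighted
#' F1. Fully reproducible given the configs' seeds.
#'
#' @param model a [build_model()] handle.
#' @param train a [windowed_dataset()] containing at least two classes.
#' @param config a [train_config()].
#' @return a list: `model` (best-validation-F1 snapshot), `history`
#'   (data frame: epoch, train_loss, val_f1), `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(model, train, config = train_config()) {
  stopifnot(inherits(model, "har_model"), inherits(train, "windowed_dataset"),
            inherits(config, "train_config"))
  dtr <- dim(train$windows)
  cfg <- model$config
  if (dtr[2] != cfg$input_shape[1] || dtr[3] != cfg$input_shape[2]) {
    stop("dataset window shape does not match the model's input shape")
  }
  if (length(unique(train$labels)) < 2L) {
    stop("training set contains a single class; nothing to discriminate")
  }
  split <- train_val_split(train, config$validation_fraction,
                           seed = config$seed + 1L)
  tr <- split$train
  va <- split$validation
  n <- dim(tr$windows)[1]

  opt_state <- lapply(model$layers, function(l) adadelta_init(l$params))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_f1 = numeric())
  best_loss <- Inf
  wait <- 0L
  best_f1 <- -Inf
  best_layers <- model$layers
  best_epoch <- 0L
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    idx <- withr::with_seed(config$seed + 1000L + epoch, sample.int(n))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      X <- tr$windows[b, , , drop = FALSE]
      y <- tr$labels[b]
      fw <- net_forward(model, X, training = TRUE)
      model <- fw$model
      epoch_loss <- epoch_loss + cross_entropy(fw$probs, y) * length(b)
      grads <- net_backward(model, fw$caches, fw$probs, y)
      for (i in seq_along(model$layers)) {
        r <- adadelta_step(model$layers[[i]]$params, grads[[i]],
                           opt_state[[i]], config$learning_rate,
                           config$rho, config$epsilon)
        model$layers[[i]]$params <- r$params
        opt_state[[i]] <- r$state
      }
    }
    epoch_loss <- epoch_loss / n
    pv <- predict(model, va)
    vf1 <- weighted_f1(va$labels, pv$labels,
                       n_classes = cfg$n_classes)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = epoch_loss,
                                val_f1 = vf1))
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val F1 %.4f",
                      epoch, epoch_loss, vf1))
    }
    if (vf1 > best_f1) {
      best_f1 <- vf1
      best_layers <- model$layers
      best_epoch <- epoch
    }
    if (epoch_loss < best_loss) {
      best_loss <- epoch_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- epoch
        break
      }
    }
  }
  model$layers <- best_layers
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_epoch = stopped)
}

#' Predict activity classes for windowed data
#'
#' Runs the network in inference mode (batch-normalisation running
#' statistics), so results are deterministic and identical whether windows
#' are scored singly or in one batch. Predicted labels are the argmax of the
#' class probabilities; exact ties resolve to the lowest class index.
#'
#' @param object a trained `har_model`.
#' @param dataset a [windowed_dataset()] or a bare `n x S x D` array.
#' @param ... unused.
#' @return list with `probabilities` (`n x n_classes`) and `labels`
#'   (0-based integer vector).
#' @export
predict.har_model <- function(object, dataset, ...) {
  X <- if (inherits(dataset, "windowed_dataset")) dataset$windows else dataset
  stopifnot(length(dim(X)) == 3L)
  cfg <- object$config
  if (dim(X)[2] != cfg$input_shape[1] || dim(X)[3] != cfg$input_shape[2]) {
    stop("dataset window shape does not match the model's input shape")
  }
  if (dim(X)[1] == 0L) {
    return(list(probabilities = matrix(0, 0, cfg$n_classes),
                labels = integer(0)))
  }
  probs <- net_forward(object, X, training = FALSE)$probs
  list(probabilities = probs,
       labels = max.col(probs, ties.method = "first") - 1L)
}

#' Temporal attention pooling of a state sequence
#'
#' The attention step in isolation: projects each timestep's state
#' (`u_t = tanh(t(w_w) H_t + b)`), scores it against the trained context
#' query `u_w`, normalises the scores with a softmax over time, and returns
#' the weighted sum of states.
#'
#' @param H `S x hidden` matrix of per-timestep states.
#' @param params list with `Ww` (`hidden x attention_dim`), `b`
#'   (`attention_dim`), `uw` (`attention_dim`), as produced inside
#'   [build_model()].
#' @return list with `weights` (length-S simplex vector) and `context`
#'   (length-hidden vector, a convex combination of the rows of `H`).
#' @export
attention_pool <- function(H, params) {
  H <- as.matrix(H)
  stopifnot(nrow(H) >= 1L)
  if (ncol(params$Ww) != length(params$uw)) {
    stop("attention projection and context dimensions do not match")
  }
  if (nrow(params$Ww) != ncol(H)) {
    stop("state dimension does not match the attention projection")
  }
  X <- array(0, c(1, nrow(H), ncol(H)))
  X[1, , ] <- H
  r <- attn_forward(X, params, pool = TRUE)
  list(weights = as.vector(r$weights), context = as.vector(r$out))
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the parameters together with an echo of the
#' model configuration.
#'
#' @param model a `har_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "har_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "har_model"))
  m
}

#' Export a training history as CSV
#' @param history the `history` data frame from [train_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
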