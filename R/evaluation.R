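#' Confusion matrix
#'
#' Entry `(i, j)` counts samples whose actual class is `i` and predicted
#' class is `j` (rows = actual, columns = predicted). Labels are 0-based
#' class ids.
#'
#' @param y_true,y_pred integer vectors of equal length, values in
#'   `[0, n_classes)`.
#' @param n_classes number of classes C.
#' @return a `C x C` integer matrix with class ids as dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  n_classes <- as.integer(n_classes)
  if (length(y_true) > 0) {
    rng <- range(c(y_true, y_pred))
    if (rng[1] < 0L || rng[2] >= n_classes) {
      stop(sprintf("labels must lie in [0, %d)", n_classes))
    }
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = seq_len(n_classes) - 1L,
                               predicted = seq_len(n_classes) - 1L))
  for (k in seq_along(y_true)) {
    i <- y_true[k] + 1L
    j <- y_pred[k] + 1L
    cm[i, j] <- cm[i, j] + 1L
  }
  cm
}

#' Class-support-weighted F1 score
#'
#' `F1 = sum_j (N_j / N) * 2 P_j R_j / (P_j + R_j)` where `N_j` is the
#' support (number of actual samples) of class `j`, and `P_j`, `R_j` its
#' precision and recall. A class with `P_j + R_j = 0` (no true positives and
#' either no predictions or no support) contributes an F1 of 0 at weight
#' `N_j / N`; classes absent from `y_true` have zero weight. Appropriate for
#' imbalanced activity data where a dominant Null class would swamp accuracy.
#'
#' @inheritParams confusion_matrix
#' @return the weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(y_true, y_pred, n_classes) {
  if (length(y_true) == 0L) stop("cannot score an empty label vector")
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  per <- per_class_prf(cm)
  sum(per$weight * per$f1)
}

# precision/recall/F1 per class from a confusion matrix; 0/0 cases -> 0
per_class_prf <- function(cm) {
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  data.frame(class = seq_len(nrow(cm)) - 1L,
             support = support, precision = precision, recall = recall,
             f1 = f1, weight = support / sum(cm), row.names = NULL)
}

#' Full evaluation report
#'
#' Confusion matrix plus per-class precision, recall, F1 and support, and the
#' support-weighted F1.
#'
#' @inheritParams confusion_matrix
#' @param class_names optional character vector naming class ids `0..C-1`.
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, n_classes, class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  per <- per_class_prf(cm)
  if (!is.null(class_names)) {
    stopifnot(length(class_names) == n_classes)
    per$class_name <- class_names
    dimnames(cm) <- list(actual = class_names, predicted = class_names)
  }
  structure(
    list(confusion = cm, per_class = per,
         weighted_f1 = sum(per$weight * per$f1), N = sum(cm)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> N = %d, weighted F1 = %.4f\n", x$N,
              x$weighted_f1))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export an evaluation report as CSV
#'
#' Writes the per-class table; the confusion matrix goes to a second file
#' with suffix `_confusion.csv` next to it.
#'
#' @param report an [eval_report()].
#' @param path output CSV path for the per-class table.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(report$per_class, path, row.names = FALSE)
  cm_path <- sub("\\.csv$", "_confusion.csv", path)
  utils::write.csv(as.data.frame(report$confusion), cm_path,
                   row.names = FALSE)
  invisible(path)
}

#' Heat-table plot of a confusion matrix
#'
#' Actual classes on the vertical axis, predicted on the horizontal; each
#' cell is shaded by its count (larger = darker) and annotated with the
#' number.
#'
#' @param report an [eval_report()].
#' @return a ggplot object.
#' @export
plot_confusion <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  cm <- report$confusion
  df <- as.data.frame(as.table(cm), stringsAsFactors = FALSE)
  names(df) <- c("actual", "predicted", "count")
  df$actual <- factor(df$actual, levels = rev(rownames(cm)))
  df$predicted <- factor(df$predicted, levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b") +
    ggplot2::labs(x = "Predicted class", y = "Actual class",
                  fill = "Count") +
    ggplot2::theme_minimal()
}
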