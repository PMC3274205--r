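#' Classification metrics
#'
#' Confusion counts plus the per-class figures of merit used for
#' spectroscopic classifiers: sensitivity (predicted-in-class divided by
#' actually-in-class), specificity (predicted-not-in-class divided by
#' actually-not-in-class), classification error
#' `(1 - sensitivity + 1 - specificity) / 2`, and — when indicator
#' predictions are supplied — the per-class root mean squared error of the
#' class-indicator prediction (RMSEC for calibration, RMSECV when the
#' predictions come from cross-validation).
#'
#' @param truth Character vector of true class labels.
#' @param predicted Character vector of predicted labels (entries outside
#'   `classes`, e.g. `"ambiguous"`, count against every class's
#'   sensitivity).
#' @param classes Class set (default: sorted unique truth labels).
#' @param indicator_pred Optional n x g matrix of predicted class
#'   indicators (columns ordered as `classes`) for the RMSE column.
#' @return A list of class `class_metrics`: `confusion` (g x g,
#'   rows = truth), `per_class` data frame (`sensitivity`, `specificity`,
#'   `class_error`, `rmse`), `accuracy`.
#' @export
class_metrics <- function(truth, predicted, classes = sort(unique(truth)),
                          indicator_pred = NULL) {
  stopifnot(length(truth) == length(predicted))
  g <- length(classes)
  confusion <- matrix(0L, g, g, dimnames = list(truth = classes,
                                                predicted = classes))
  for (i in seq_along(truth)) {
    if (predicted[i] %in% classes) {
      confusion[truth[i], predicted[i]] <- confusion[truth[i], predicted[i]] + 1L
    }
  }
  sens <- spec <- rmse <- numeric(g)
  for (j in seq_len(g)) {
    in_cls <- truth == classes[j]
    sens[j] <- if (any(in_cls)) {
      sum(predicted[in_cls] == classes[j]) / sum(in_cls)
    } else NA_real_
    spec[j] <- if (any(!in_cls)) {
      sum(predicted[!in_cls] != classes[j]) / sum(!in_cls)
    } else NA_real_
    rmse[j] <- if (!is.null(indicator_pred)) {
      sqrt(mean((as.numeric(in_cls) - indicator_pred[, j])^2))
    } else NA_real_
  }
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = classes, sensitivity = sens,
                           specificity = spec,
                           class_error = (1 - sens + 1 - spec) / 2,
                           rmse = rmse, row.names = NULL),
    accuracy = mean(predicted == truth)
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> accuracy %.4f\n", x$accuracy))
  print(x$per_class, digits = 4)
  invisible(x)
}

one_hot <- function(labels, classes = sort(unique(labels))) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}
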