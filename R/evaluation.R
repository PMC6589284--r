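# Confusion matrices, accuracy, per-class sensitivity and multi-run
# aggregation. Accuracy is the diagonal sum over the total count (in
# percent); sensitivity of class i is the diagonal entry over the row sum.
# Aggregates report the mean and the sample (n-1) standard deviation.

#' Build a confusion matrix
#'
#' @param true_labels,predicted_labels equal-length label vectors over
#'   `class_names`.
#' @param class_names ordered class labels (rows = true, columns =
#'   predicted).
#' @return a `confusion_matrix`: integer matrix with class-name dimnames.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_names = blast_classes()) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (!all(c(true_labels, predicted_labels) %in% class_names)) {
    stop("unknown label")
  }
  m <- table(factor(true_labels, levels = class_names),
             factor(predicted_labels, levels = class_names))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = class_names, predicted = class_names)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix, in percent
#'
#' `100 * sum(diag(cm)) / sum(cm)`.
#'
#' @param cm a [confusion()] matrix (or any square count matrix).
#' @return accuracy in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Per-class sensitivity (recall), in percent
#'
#' `100 * cm[i, i] / sum(cm[i, ])`.
#'
#' @param cm a [confusion()] matrix.
#' @param class_i class name or row index.
#' @return sensitivity in `[0, 100]`.
#' @export
sensitivity <- function(cm, class_i) {
  i <- if (is.character(class_i)) match(class_i, rownames(cm)) else class_i
  row_sum <- sum(cm[i, ])
  if (row_sum == 0) stop("empty row for class ", class_i)
  100 * cm[i, i] / sum(cm[i, ])
}

#' Metrics of one evaluation run
#'
#' @param cm a [confusion()] matrix. A warning is raised when the row sums
#'   disagree with `expected_counts` (internally inconsistent report
#'   tables).
#' @param expected_counts optional per-class test counts to validate
#'   against.
#' @return a `run_metrics` list: `accuracy` (percent) and `sensitivities`
#'   (named percents).
#' @export
run_metrics <- function(cm, expected_counts = NULL) {
  if (!is.null(expected_counts) &&
      !all(rowSums(cm) == expected_counts)) {
    warning("confusion-matrix row sums disagree with declared composition")
  }
  structure(
    list(accuracy = accuracy(cm),
         sensitivities = vapply(rownames(cm), function(cl) sensitivity(cm, cl),
                                0)),
    class = "run_metrics"
  )
}

#' Aggregate a set of per-run percentages
#'
#' @param values numeric vector of length >= 2 (percent scale).
#' @return an `aggregate_metrics` list: `mean`, `sd` (sample, n-1
#'   denominator) at full precision, plus `mean_2dp`/`sd_2dp` rounded
#'   half-up to 2 decimals as printed in reports, and `n_runs`.
#' @export
aggregate_metrics <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to aggregate")
  m <- mean(values)
  s <- stats::sd(values)
  round_half_up <- function(x, digits = 2) {
    p <- 10^digits
    floor(x * p + 0.5) / p
  }
  structure(
    list(mean = m, sd = s,
         mean_2dp = round_half_up(m), sd_2dp = round_half_up(s),
         n_runs = length(values)),
    class = "aggregate_metrics"
  )
}

#' Tabulate per-split metrics with an Average row
#'
#' @param metrics_list list of `run_metrics`, one per test set.
#' @return data frame with one row per test set plus an `Average` row
#'   (formatted `mean +/- sd`) mirroring the report-table layout.
#' @export
metrics_report <- function(metrics_list) {
  acc <- vapply(metrics_list, `[[`, 0, "accuracy")
  sens <- t(vapply(metrics_list, `[[`, numeric(3), "sensitivities"))
  df <- data.frame(
    test_set = as.character(seq_along(metrics_list)),
    accuracy = sprintf("%.2f", acc)
  )
  for (j in seq_len(ncol(sens))) {
    df[[colnames(sens)[j]]] <- sprintf("%.2f", sens[, j])
  }
  agg <- function(v) {
    a <- aggregate_metrics(v)
    sprintf("%.2f ± %.2f", a$mean_2dp, a$sd_2dp)
  }
  avg <- c("Average", agg(acc), vapply(seq_len(ncol(sens)),
                                       function(j) agg(sens[, j]), ""))
  rbind(df, stats::setNames(as.data.frame(as.list(avg),
                                          stringsAsFactors = FALSE),
                            names(df)))
}
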