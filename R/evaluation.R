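# Evaluation protocol: stratified 8:2 splitting, accuracy, confusion
# matrices (raw and row-normalized), and one-vs-rest ROC / PR curves with
# trapezoidal AUC and step-interpolated average precision.

#' Stratified train/test split
#'
#' Per class, the test set receives `max(1, round(test_fraction * n_class))`
#' samples (capped at `n_class - 1` so both partitions stay non-empty); the
#' split is a disjoint, exhaustive partition and deterministic per seed.
#'
#' @param labels Label vector.
#' @param test_fraction Fraction per class assigned to the test set.
#' @param seed Integer seed.
#' @return `list(train =, test =)` of integer indices.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_arg("test_fraction must be in (0, 1)")
  counts <- table(labels)
  if (any(counts < 2L))
    stop_arg("split error: every class needs at least 2 samples")
  test <- withr::with_seed(derive_seed(seed, "strat"), {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      k <- min(length(idx) - 1L, max(1L, round(test_fraction * length(idx))))
      idx[sample.int(length(idx), k)]
    }), use.names = FALSE)
  })
  list(train = sort(setdiff(seq_along(labels), test)), test = sort(test))
}

#' Classification accuracy
#'
#' The fraction of predictions that match the ground truth:
#' correct predictions / all predictions.
#'
#' @param predicted,actual Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) == 0L) stop_arg("empty input")
  if (length(predicted) != length(actual)) stop_arg("length mismatch")
  mean(predicted == actual)
}

#' Confusion matrix over a fixed class set
#'
#' `counts[i, j]` tallies samples with actual class `classes[i]` predicted as
#' `classes[j]`. The normalized view divides each row by its sum (rows that
#' sum to zero stay zero), matching per-class test-set normalization.
#'
#' @param predicted,actual Label vectors.
#' @param classes Ordered class set; defaults to the sorted union.
#' @return An object of class `confusion_matrix` with elements `classes`,
#'   `counts` and `normalized`.
#' @export
confusion <- function(predicted, actual, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(predicted, actual)))
  if (!all(c(predicted, actual) %in% classes))
    stop_arg("labels outside the supplied class set")
  counts <- table(factor(actual, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  structure(list(classes = classes, counts = counts, normalized = normalized),
            class = "confusion_matrix")
}

curve_series <- function(points, kind, summary) {
  structure(list(points = points, kind = kind, summary = summary),
            class = "curve_series")
}

#' One-vs-rest ROC curve with trapezoidal AUC
#'
#' Sweeps every distinct score threshold (predict positive when
#' `score >= threshold`), computing the false positive rate
#' `FP / (FP + TN)` and true positive rate `TP / (TP + FN)` at each, with
#' `(0, 0)` prepended and `(1, 1)` appended.
#'
#' @param scores Numeric scores for the positive class.
#' @param is_member Logical (or 0/1) ground-truth membership.
#' @return A `curve_series` with `kind = "roc"` and `summary` the AUC.
#' @export
roc_curve <- function(scores, is_member) {
  is_member <- as.logical(is_member)
  if (length(scores) != length(is_member)) stop_arg("length mismatch")
  np <- sum(is_member); nn <- sum(!is_member)
  if (np == 0L || nn == 0L)
    stop_arg("need at least one positive and one negative sample")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & is_member) / np, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & !is_member) / nn, 0)
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  curve_series(data.frame(x = x, y = y), "roc", auc)
}

#' One-vs-rest precision-recall curve with average precision
#'
#' Sweeps distinct thresholds in decreasing order; at each, recall is
#' `TP / (TP + FN)` and precision `TP / (TP + FP)`. The summary is the
#' step-interpolated average precision `sum((R_i - R_{i-1}) * P_i)`.
#'
#' @param scores Numeric scores for the positive class.
#' @param is_member Logical (or 0/1) ground-truth membership.
#' @return A `curve_series` with `kind = "pr"` and `summary` the AP.
#' @export
pr_curve <- function(scores, is_member) {
  is_member <- as.logical(is_member)
  if (length(scores) != length(is_member)) stop_arg("length mismatch")
  np <- sum(is_member)
  if (np == 0L) stop_arg("need at least one positive sample")
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- numeric(length(th)); prec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tp <- sum(pred & is_member)
    rec[i] <- tp / np
    prec[i] <- tp / sum(pred)
  }
  ap <- sum(diff(c(0, rec)) * prec)
  curve_series(data.frame(x = rec, y = prec), "pr", ap)
}

#' Full per-class evaluation report for a fitted classifier
#'
#' Computes accuracy and the confusion matrix over argmax predictions, plus
#' one-vs-rest ROC and PR curves per class from the classifier's per-class
#' scores.
#'
#' @param classifier A `fitted_classifier`.
#' @param test_embeddings `n x d` embedding matrix.
#' @param test_labels Length-`n` ground-truth labels.
#' @return An `evaluation_report`: `accuracy`, `confusion`, and
#'   `per_class_curves` (a named list of `list(roc =, pr =)`).
#' @export
full_report <- function(classifier, test_embeddings, test_labels) {
  if (length(test_labels) == 0L) stop_arg("empty test set")
  if (length(unique(test_labels)) < 2L)
    stop_arg("test set must cover at least 2 classes")
  pred <- predict_classifier(classifier, test_embeddings)
  classes <- sort(unique(c(classifier$class_set, test_labels)))
  cm <- confusion(pred$identity, test_labels, classes)
  curves <- list()
  for (cl in intersect(classifier$class_set, unique(test_labels))) {
    member <- test_labels == cl
    if (all(member)) next
    sc <- pred$scores[, cl]
    curves[[cl]] <- list(roc = roc_curve(sc, member), pr = pr_curve(sc, member))
  }
  structure(list(accuracy = accuracy(pred$identity, test_labels),
                 confusion = cm, per_class_curves = curves),
            class = "evaluation_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    accuracy = report$accuracy,
    classes = report$confusion$classes,
    confusion_counts = unname(apply(report$confusion$counts, 1, as.integer,
                                    simplify = FALSE)),
    per_class = lapply(report$per_class_curves, function(cv)
      list(auc = cv$roc$summary, ap = cv$pr$summary)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Majority label of a vector (ties broken by first occurrence)
#'
#' Convenience for per-session majority-vote evaluation.
#'
#' @param x Label vector.
#' @return The most frequent label.
#' @export
majority_label <- function(x) {
  tb <- table(factor(x, levels = unique(x)))
  names(tb)[which.max(tb)]
}
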