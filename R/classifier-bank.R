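# Bank of classical embedding classifiers: k-nearest neighbours (Euclidean
# on the unit-normalized embeddings, ties falling back to the single nearest
# neighbour), random forest, and SVM with linear or RBF kernel. All expose
# per-class scores that sum to 1, usable as one-vs-rest thresholds.

#' Specify an embedding classifier
#'
#' @param kind One of `"knn"`, `"random_forest"`, `"svm"`.
#' @param k Neighbourhood size for KNN (3, 5 or 7 in the default bank).
#' @param kernel `"linear"` or `"rbf"`, for SVM.
#' @param seed Seed controlling any stochastic fitting (random forest,
#'   SVM probability calibration).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "random_forest", "svm"),
                            k = 3L, kernel = c("linear", "rbf"), seed = 1L) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  if (kind == "knn" && (length(k) != 1L || k < 1L))
    stop_arg("knn requires a positive k")
  structure(list(kind = kind, k = as.integer(k), kernel = kernel,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

spec_label <- function(spec) {
  switch(spec$kind,
         knn = sprintf("KNN (K = %d)", spec$k),
         random_forest = "Random forest",
         svm = sprintf("SVM (%s kernel)", if (spec$kernel == "linear") "Linear" else "RBF"))
}

#' The default classifier bank
#'
#' KNN with K in 3, 5, 7; a 100-tree random forest; and SVMs with RBF and
#' linear kernels — the six classifiers of the standard comparison.
#'
#' @param seed Shared fitting seed.
#' @return A list of six `classifier_spec`s.
#' @export
default_classifier_specs <- function(seed = 1L) {
  list(classifier_spec("knn", k = 3L, seed = seed),
       classifier_spec("knn", k = 5L, seed = seed),
       classifier_spec("knn", k = 7L, seed = seed),
       classifier_spec("random_forest", seed = seed),
       classifier_spec("svm", kernel = "rbf", seed = seed),
       classifier_spec("svm", kernel = "linear", seed = seed))
}

#' Fit an embedding classifier
#'
#' @param spec A `classifier_spec`.
#' @param embeddings `n x d` matrix of embeddings (rows).
#' @param labels Length-`n` identity labels.
#' @return A `fitted_classifier` whose `class_set` equals the distinct
#'   labels; deterministic given `spec$seed`.
#' @export
fit_classifier <- function(spec, embeddings, labels) {
  if (!inherits(spec, "classifier_spec")) stop_arg("spec must be a classifier_spec")
  E <- as_embedding_matrix(embeddings)
  labels <- as.character(labels)
  if (nrow(E) != length(labels)) stop_arg("embeddings/labels length mismatch")
  class_set <- sort(unique(labels))
  if (length(class_set) < 2L) stop_arg("fit error: need at least 2 classes")
  if (spec$kind == "knn" && nrow(E) < spec$k)
    stop_arg("fit error: knn needs at least k training samples")
  model <- switch(spec$kind,
    knn = list(train = E, labels = labels),
    random_forest = withr::with_seed(derive_seed(spec$seed, "rf"),
      randomForest::randomForest(x = E, y = factor(labels, levels = class_set),
                                 ntree = 100L)),
    svm = withr::with_seed(derive_seed(spec$seed, "svm"),
      e1071::svm(x = E, y = factor(labels, levels = class_set),
                 kernel = if (spec$kernel == "linear") "linear" else "radial",
                 gamma = 1 / (ncol(E) * max(var(as.vector(E)), 1e-12)),
                 cost = 1, probability = TRUE)))
  structure(list(spec = spec, class_set = class_set, model = model,
                 dim = ncol(E)),
            class = "fitted_classifier")
}

knn_predict <- function(fc, Q) {
  tr <- fc$model$train
  lab <- fc$model$labels
  k <- fc$spec$k
  scores <- matrix(0, nrow(Q), length(fc$class_set),
                   dimnames = list(NULL, fc$class_set))
  identity <- character(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    d2 <- rowSums((tr - matrix(Q[i, ], nrow(tr), ncol(tr), byrow = TRUE))^2)
    ord <- order(d2, seq_along(d2))
    nb <- lab[ord[seq_len(k)]]
    counts <- table(factor(nb, levels = fc$class_set))
    scores[i, ] <- as.numeric(counts) / k
    top <- names(counts)[counts == max(counts)]
    identity[i] <- if (length(top) == 1L) top else lab[ord[1L]]
  }
  list(identity = identity, scores = scores)
}

#' Predict identities and per-class scores from embeddings
#'
#' The predicted identity is the argmax of the per-class scores (for KNN,
#' vote ties fall back to the label of the single nearest neighbour); scores
#' are nonnegative and sum to 1 per sample.
#'
#' @param fc A `fitted_classifier`.
#' @param embeddings A single length-`d` vector or an `n x d` matrix.
#' @return `list(identity = character(n), scores = n x n_classes matrix)`.
#' @export
predict_classifier <- function(fc, embeddings) {
  if (!inherits(fc, "fitted_classifier")) stop_arg("fc must be a fitted_classifier")
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  Q <- as_embedding_matrix(embeddings)
  if (ncol(Q) != fc$dim)
    stop_arg("embedding dimension mismatch: expected ", fc$dim, ", got ", ncol(Q))
  res <- switch(fc$spec$kind,
    knn = knn_predict(fc, Q),
    random_forest = {
      pr <- predict(fc$model, Q, type = "prob")
      pr <- pr[, fc$class_set, drop = FALSE]
      list(identity = fc$class_set[max.col(pr, ties.method = "first")],
           scores = pr)
    },
    svm = {
      pv <- predict(fc$model, Q, probability = TRUE)
      pr <- attr(pv, "probabilities")[, fc$class_set, drop = FALSE]
      list(identity = fc$class_set[max.col(pr, ties.method = "first")],
           scores = pr)
    })
  rownames(res$scores) <- NULL
  res
}

#' Compare classifiers on a shared train/test split
#'
#' Fits every spec on the training embeddings and scores it on the test set;
#' rows are sorted by accuracy (descending, ties by spec order).
#'
#' @param specs List of `classifier_spec`s (default: the six-classifier bank).
#' @param train,test Lists with `$embeddings` (`n x d`) and `$labels`.
#' @return A data frame with columns `classifier`, `kind`, `accuracy`.
#' @export
compare_classifiers <- function(specs = default_classifier_specs(), train, test) {
  if (is.null(test$labels) || length(test$labels) == 0L) stop_arg("empty test set")
  acc <- vapply(specs, function(sp) {
    fc <- fit_classifier(sp, train$embeddings, train$labels)
    accuracy(predict_classifier(fc, test$embeddings)$identity, test$labels)
  }, 0)
  out <- data.frame(classifier = vapply(specs, spec_label, ""),
                    kind = vapply(specs, `[[`, "", "kind"),
                    accuracy = acc)
  out[order(-out$accuracy, seq_len(nrow(out))), , drop = FALSE]
}
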