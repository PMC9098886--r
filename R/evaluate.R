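#' Confusion matrix from label sequences
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param labels Ordered label set; defaults to the sorted union of the
#'   labels present in `y_true` and `y_pred`.
#' @return A `confusion_matrix`: `counts` (rows = true class, columns =
#'   predicted class) and `class_labels`.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.", class = "sdcl_validation_error")
  }
  labels <- labels %||% sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(unknown)) {
    abort(sprintf("Label '%s' is not in the label set.", unknown[1]),
          class = "sdcl_validation_error")
  }
  counts <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(true = labels, predicted = labels))
  structure(list(counts = counts, class_labels = labels), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$counts), responseName = "n")
  tibble(true = as.character(df$true), predicted = as.character(df$predicted),
         n = as.integer(df$n))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Precision, recall and F1 are
#' computed per class one-vs-rest (`TP = counts[c, c]`,
#' `FP = column sum - TP`, `FN = row sum - TP`) with
#' `F1 = 2 * precision * recall / (precision + recall)`, then aggregated:
#' `"weighted"` (support-weighted mean, the default), `"macro"` (plain
#' mean), or `"binary"` (a 2-class matrix scored with the second label as
#' the positive class). A class with a zero denominator contributes 0 with
#' a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param averaging Aggregation scheme.
#' @return A `metrics_report`: `accuracy`, `precision`, `recall`, `f1`,
#'   `per_class` tibble, and the averaging scheme.
#' @export
classification_metrics <- function(cm, averaging = c("weighted", "macro", "binary")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) abort("Confusion matrix is empty.", class = "sdcl_validation_error")
  C <- nrow(counts)
  if (averaging == "binary" && C != 2) {
    abort("`binary` averaging needs a 2-class matrix.", class = "sdcl_validation_error")
  }

  tp <- unname(diag(counts))
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- total - tp - fp - fn

  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warn(sprintf("Zero denominator for %s in class(es) %s; contributing 0.",
                   what, paste(cm$class_labels[den == 0], collapse = ", ")))
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  precision <- unname(precision); recall <- unname(recall); f1 <- unname(f1)
  support <- unname(rowSums(counts))

  per_class <- tibble(
    class = cm$class_labels, support = as.integer(support),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn), tn = as.integer(tn),
    precision = unname(precision), recall = unname(recall), f1 = unname(f1)
  )

  accuracy <- sum(tp) / total
  agg <- switch(averaging,
    weighted = {
      w <- support / total
      c(precision = sum(w * precision), recall = sum(w * recall), f1 = sum(w * f1))
    },
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    binary = c(precision = precision[2], recall = recall[2], f1 = f1[2])
  )
  structure(list(accuracy = unname(accuracy), precision = unname(agg["precision"]),
                 recall = unname(agg["recall"]), f1 = unname(agg["f1"]),
                 per_class = per_class, averaging = averaging),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s averaging)\n", x$averaging))
  cat(sprintf("  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision,
         recall = x$recall, f1 = x$f1, averaging = x$averaging)
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr_pivot(glance(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

tidyr_pivot <- function(g) {
  tibble(metric = c("accuracy", "precision", "recall", "f1"),
         value = c(g$accuracy, g$precision, g$recall, g$f1))
}

# ---- classifier adapters -------------------------------------------------
# A classifier is a list with fit(x, y) -> model and predict(model, x) ->
# character labels. x is a plain numeric matrix, y a factor.

#' Classifier adapters
#'
#' Thin wrappers exposing a uniform `fit`/`predict` contract over standard
#' classifiers, for use with [evaluate_features()].
#'
#' @param kernel,cost SVM kernel and cost ([e1071::svm()]).
#' @param k Neighbour count for k-NN.
#' @param ntree Tree count for random forest.
#' @param size,maxit,decay Hidden-layer size, iteration cap and weight
#'   decay for the single-hidden-layer network.
#' @return A classifier adapter (list with `fit`, `predict`, `name`).
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_svm <- function(kernel = "linear", cost = 1) {
  list(
    name = paste0("svm_", kernel),
    fit = function(x, y) e1071::svm(x, y, kernel = kernel, cost = cost, scale = TRUE),
    predict = function(model, x) as.character(predict(model, x))
  )
}

#' @rdname classifiers
#' @export
classifier_knn <- function(k = 5) {
  list(
    name = sprintf("knn%d", k),
    fit = function(x, y) list(x = x, y = y, k = k),
    predict = function(model, x) {
      as.character(class::knn(model$x, x, model$y, k = model$k))
    }
  )
}

#' @rdname classifiers
#' @export
classifier_rf <- function(ntree = 200) {
  list(
    name = "rf",
    fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree),
    predict = function(model, x) as.character(predict(model, x))
  )
}

#' @rdname classifiers
#' @export
classifier_lda <- function() {
  list(
    name = "lda",
    fit = function(x, y) {
      # drop zero-variance columns, which lda() refuses
      keep <- apply(x, 2, function(v) sd(v) > 1e-12)
      list(model = MASS::lda(x[, keep, drop = FALSE], grouping = y), keep = keep)
    },
    predict = function(model, x) {
      as.character(predict(model$model, x[, model$keep, drop = FALSE])$class)
    }
  )
}

#' @rdname classifiers
#' @export
classifier_mlp <- function(size = 16, maxit = 300, decay = 1e-3) {
  list(
    name = "mlp",
    fit = function(x, y) {
      nnet::nnet(x, nnet::class.ind(y), size = size, maxit = maxit, decay = decay,
                 softmax = TRUE, trace = FALSE, MaxNWts = 1e5)
    },
    predict = function(model, x) {
      pr <- predict(model, x)
      colnames(pr)[max.col(pr, ties.method = "first")]
    }
  )
}

#' Train/test evaluation of a feature table
#'
#' Splits the items into stratified train and test sets, fits the supplied
#' classifier adapter on the training portion, predicts the test portion,
#' and reports support-weighted one-vs-rest metrics. Deterministic given
#' `seed` and a deterministic classifier (the RNG is seeded around both the
#' split and the fit).
#'
#' @param features Items x features: a matrix, data frame or tibble of
#'   numeric columns.
#' @param labels Label vector, one per row of `features` (>= 10 rows).
#' @param classifier A classifier adapter, e.g. [classifier_svm()].
#' @param test_fraction Fraction of items held out (default 0.2).
#' @param stratified Stratify the split by class (default `TRUE`).
#' @param seed Integer seed.
#' @return A `metrics_report` with attributes `test_index` (held-out row
#'   indices) and `classifier` (adapter name).
#' @export
evaluate_features <- function(features, labels, classifier = classifier_svm(),
                              test_fraction = 0.2, stratified = TRUE, seed = 1) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  y <- factor(as.character(labels))
  if (nrow(x) != length(y)) {
    abort("`features` rows and `labels` length differ.", class = "sdcl_validation_error")
  }
  if (nrow(x) < 10) abort("Need at least 10 items.", class = "sdcl_validation_error")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).", class = "sdcl_validation_error")
  }

  test_idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(levels(y), function(lv) {
        rows <- which(y == lv)
        n_test <- max(1L, round(length(rows) * test_fraction))
        if (n_test >= length(rows)) {
          abort(sprintf(
            "Class '%s' would be absent from the training split; lower `test_fraction`.",
            lv), class = "sdcl_validation_error")
        }
        sample(rows, n_test)
      }), use.names = FALSE)
    } else {
      sample(nrow(x), max(1L, round(nrow(x) * test_fraction)))
    }
  })
  train_idx <- setdiff(seq_len(nrow(x)), test_idx)
  missing_train <- setdiff(levels(y), unique(as.character(y[train_idx])))
  if (length(missing_train)) {
    abort(sprintf("Class '%s' absent from the training split; lower `test_fraction`.",
                  missing_train[1]), class = "sdcl_validation_error")
  }

  model <- with_seed(seed + 1L, classifier$fit(x[train_idx, , drop = FALSE], y[train_idx]))
  pred <- with_seed(seed + 2L,
                    classifier$predict(model, x[test_idx, , drop = FALSE]))
  cm <- confusion_matrix(as.character(y[test_idx]), pred, labels = levels(y))
  rep <- classification_metrics(cm, "weighted")
  attr(rep, "test_index") <- sort(test_idx)
  attr(rep, "classifier") <- classifier$name
  attr(rep, "confusion") <- cm
  rep
}
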