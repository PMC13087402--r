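#' Confusion matrix and classification metrics
#'
#' Scores predicted against actual binary antimicrobial classes with
#' `"active"` as the positive class. Accuracy is reported in percent,
#' `100 (tp + tn) / n`. Precision, recall and F-measure are computed per
#' class and then averaged, by default weighted by true class support
#' (which makes weighted recall equal accuracy / 100); macro averaging is
#' available via `average = "macro"`. A class never predicted has undefined
#' precision, which is counted as 0 and flagged.
#'
#' @param actual character vector of `"active"`/`"inactive"`.
#' @param predicted character vector, same length.
#' @param average `"weighted"` (default) or `"macro"`.
#' @return A list of class `classification_metrics`: `confusion` (list tp,
#'   fp, tn, fn), `accuracy` (percent), `precision`, `recall`, `f_measure`,
#'   `per_class` (data frame), `undefined_precision` (character vector of
#'   classes with no predictions).
#' @export
classification_metrics <- function(actual, predicted,
                                   average = c("weighted", "macro")) {
  average <- match.arg(average)
  actual <- as.character(actual); predicted <- as.character(predicted)
  n <- length(actual)
  if (n == 0L || length(predicted) != n) {
    stop("actual and predicted must have equal nonzero length", call. = FALSE)
  }
  lv <- c("active", "inactive")
  if (!all(c(actual, predicted) %in% lv)) {
    stop("labels must be 'active' or 'inactive'", call. = FALSE)
  }
  tp <- sum(actual == "active" & predicted == "active")
  fp <- sum(actual == "inactive" & predicted == "active")
  tn <- sum(actual == "inactive" & predicted == "inactive")
  fn <- sum(actual == "active" & predicted == "inactive")
  per <- data.frame(class = lv, support = c(tp + fn, tn + fp),
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                    stringsAsFactors = FALSE)
  undefined <- character(0)
  for (i in seq_len(2L)) {
    cls <- lv[i]
    tpi <- sum(actual == cls & predicted == cls)
    ppi <- sum(predicted == cls)  # predicted positives for this class
    api <- sum(actual == cls)     # actual positives
    prec <- if (ppi == 0L) { undefined <- c(undefined, cls); 0 } else tpi / ppi
    rec <- if (api == 0L) 0 else tpi / api
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    per$precision[i] <- prec; per$recall[i] <- rec; per$f1[i] <- f1
  }
  w <- if (average == "weighted") per$support / n else rep(0.5, 2L)
  structure(list(
    confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
    accuracy = 100 * (tp + tn) / n,
    precision = sum(w * per$precision),
    recall = sum(w * per$recall),
    f_measure = sum(w * per$f1),
    per_class = per,
    average = average,
    undefined_precision = undefined,
    n = n), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "Classification (%s avg, n = %d): accuracy %.2f%%, precision %.3f, recall %.3f, F %.3f\n",
    x$average, x$n, x$accuracy, x$precision, x$recall, x$f_measure))
  cat(sprintf("  confusion: tp %d, fp %d, tn %d, fn %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  invisible(x)
}

#' Cross-validated decision-tree classification
#'
#' Re-induces a tree on each training complement and scores the pooled
#' out-of-fold predictions with [classification_metrics()]. `scheme = "loo"`
#' performs n single-row hold-outs; `scheme = "kfold"` uses a seeded
#' stratified partition (classes balanced across folds). A training fold
#' containing a single class yields a single-leaf tree, which is allowed.
#'
#' @param table a [descriptor_table()] or numeric matrix with colnames.
#' @param classes character vector of `"active"`/`"inactive"`.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k folds for `"kfold"` (default 5).
#' @param seed seed for the stratified fold assignment.
#' @param min_leaf passed to [induce_tree()].
#' @return A `classification_metrics` object with extra fields
#'   `fold_assignment` and `n_inductions`.
#' @export
cv_classification <- function(table, classes, scheme = c("loo", "kfold"),
                              k = 5L, seed = 20260417L, min_leaf = 2L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(table)
  classes <- as.character(classes)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  fold <- if (scheme == "loo") seq_len(n) else
    .make_folds(n, k, seed, strata = classes)
  pred <- character(n)
  n_ind <- 0L
  for (f in sort(unique(fold))) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    tcls <- classes[train]
    if (length(unique(tcls)) == 1L) {
      tree <- as_tree_model(tree_leaf(tcls[1L], length(tcls), 0L))
    } else {
      tree <- induce_tree(X[train, , drop = FALSE], tcls, min_leaf = min_leaf)
    }
    n_ind <- n_ind + 1L
    pred[test] <- apply_tree(tree, X[test, , drop = FALSE])
  }
  out <- classification_metrics(classes, pred)
  out$fold_assignment <- fold
  out$n_inductions <- n_ind
  out$scheme <- scheme
  out
}
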