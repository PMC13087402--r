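#' Acceptance thresholds for regression QSAR models
#'
#' Conventional minimum performance thresholds for a reliable small-dataset
#' QSAR regression model: squared correlation R2 > 0.6, cross-validated Q2
#' > 0.5, mean absolute error < 0.6, concordance correlation > 0.85.
#' @export
qsar_thresholds <- c(r2 = 0.6, q2 = 0.5, mae = 0.6, ccc = 0.85)

#' Regression performance metrics
#'
#' Computes the standard QSAR regression statistics for observed/predicted
#' pairs:
#' * `r2 = 1 - SSres / SStot` about `mean(y)`;
#' * `r2_adjusted = 1 - (1 - r2) (n - 1) / (n - p - 1)`;
#' * `rmse`, `mae`;
#' * `ccc`, Lin's concordance correlation coefficient
#'   `2 cov(y, yhat) / (var(y) + var(yhat) + (mean(y) - mean(yhat))^2)` with
#'   population (1/n) moments.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @param p number of descriptors in the model (for `r2_adjusted`; `NA`
#'   returned when `n <= p + 1`).
#' @return Named list: `r2`, `r2_adjusted`, `rmse`, `mae`, `ccc`, `n`, `p`.
#' @export
regression_metrics <- function(y, yhat, p = NA_integer_) {
  n <- length(y)
  if (length(yhat) != n || n < 2L) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("zero variance in y: r2 and ccc undefined", call. = FALSE)
  res <- y - yhat
  r2 <- 1 - sum(res^2) / sstot
  r2_adj <- if (!is.na(p) && n > p + 1) {
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else NA_real_
  # population moments for CCC (Lin 1989)
  vy <- mean((y - mean(y))^2)
  vh <- mean((yhat - mean(yhat))^2)
  cv <- mean((y - mean(y)) * (yhat - mean(yhat)))
  ccc <- 2 * cv / (vy + vh + (mean(y) - mean(yhat))^2)
  list(r2 = r2, r2_adjusted = r2_adj,
       rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
       ccc = ccc, n = n, p = as.integer(p))
}

# leave-one-out predictions via the hat-matrix shortcut:
# loo_resid_i = resid_i / (1 - h_ii) for OLS with the row left out
.loo_predictions <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop("need n >= p + 2 for leave-one-out validation", call. = FALSE)
  }
  design <- cbind(1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient design in leave-one-out fit", call. = FALSE)
  }
  fit <- stats::lm.fit(design, y)
  h <- rowSums(qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-12)) {
    stop("leave-one-out fit rank-deficient when removing row ",
         which(h >= 1 - 1e-12)[1L], call. = FALSE)
  }
  y - fit$residuals / (1 - h)
}

#' Leave-one-out cross-validated Q2
#'
#' For each compound, refits the OLS model on the remaining n - 1 compounds
#' and predicts the held-out one (computed by the exact hat-matrix shortcut,
#' algebraically identical to n explicit refits). Scores the pooled
#' predictions as `q2 = 1 - PRESS / SStot` with SStot about the full-sample
#' mean of `y`, plus RMSE/MAE/CCC of the leave-one-out predictions.
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response.
#' @return Named list: `q2`, `rmse`, `mae`, `ccc`, `predictions`.
#' @export
q2_loo <- function(X, y) {
  pred <- .loo_predictions(X, y)
  m <- regression_metrics(y, pred, p = ncol(as.matrix(X)))
  list(q2 = m$r2, rmse = m$rmse, mae = m$mae, ccc = m$ccc,
       predictions = pred)
}

# seeded partition of n items into k near-equal folds
.make_folds <- function(n, k, seed, strata = NULL) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  rng <- .seeded_rng(seed)
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    sizes <- rep(seq_len(k), length.out = length(idx))
    fold[idx] <- sizes[rng$sample_int(length(idx))]
  }
  fold
}

# small seeded RNG wrapper; isolates package randomness from the global stream
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, size = n) with_state(function() sample.int(n, size)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(function() stats::rbinom(n, size, prob))
  )
}

#' k-fold cross-validated Q2
#'
#' Partitions compounds into `k` near-equal folds with a seeded uniform
#' random assignment, refits on each training complement, and pools the
#' out-of-fold predictions into a single PRESS-based Q2 (denominator about
#' the full-sample mean, as in [q2_loo()]). With `k = n` this reduces
#' exactly to leave-one-out.
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return Named list: `q2`, `rmse`, `mae`, `ccc`, `predictions`,
#'   `fold_assignment`, `k`, `seed`.
#' @export
q2_kfold <- function(X, y, k = 5L, seed = 20260417L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  fold <- .make_folds(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    if (length(train) < ncol(X) + 2L) {
      stop("fold ", f, " leaves too few training rows", call. = FALSE)
    }
    fit <- fit_ols(X[train, , drop = FALSE], y[train])
    pred[test] <- predict(fit$model, X[test, , drop = FALSE])
  }
  m <- regression_metrics(y, pred, p = ncol(X))
  list(q2 = m$r2, rmse = m$rmse, mae = m$mae, ccc = m$ccc,
       predictions = pred, fold_assignment = fold, k = as.integer(k),
       seed = as.integer(seed))
}

#' Y-randomization (response scrambling) test
#'
#' Permutes the response vector `n_reps` times with a seeded generator,
#' refits the model on each scrambled response, and records the training R2
#' and leave-one-out Q2 of every randomized model. The test passes when all
#' randomized R2 and Q2 values fall below the original model's, evidence
#' that the original fit is not a chance correlation.
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response.
#' @param n_reps number of permutations (default 10).
#' @param seed integer seed.
#' @return A list of class `y_randomization_report`: `n_reps`, `original`
#'   (r2, q2), `reps` (data frame of per-rep r2, q2), `pass`.
#' @export
y_randomization <- function(X, y, n_reps = 10L, seed = 20260417L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  fit0 <- fit_ols(X, y)
  r2_0 <- regression_metrics(y, fit0$fitted_values, p = ncol(X))$r2
  q2_0 <- q2_loo(X, y)$q2
  rng <- .seeded_rng(seed)
  reps <- data.frame(rep = seq_len(n_reps), r2 = NA_real_, q2 = NA_real_)
  for (r in seq_len(n_reps)) {
    perm <- rng$sample_int(length(y))
    ys <- y[perm]
    fit <- fit_ols(X, ys)
    reps$r2[r] <- regression_metrics(ys, fit$fitted_values, p = ncol(X))$r2
    reps$q2[r] <- q2_loo(X, ys)$q2
  }
  structure(list(n_reps = as.integer(n_reps),
                 original = c(r2 = r2_0, q2 = q2_0),
                 reps = reps,
                 pass = all(reps$r2 < r2_0) && all(reps$q2 < q2_0),
                 seed = as.integer(seed)),
            class = "y_randomization_report")
}

#' @export
print.y_randomization_report <- function(x, ...) {
  cat(sprintf(
    "Y-randomization: %d reps; original R2 = %.4f, Q2 = %.4f; %s\n",
    x$n_reps, x$original["r2"], x$original["q2"],
    if (x$pass) "all randomized models below original (pass)" else
      "some randomized model reached the original (fail)"))
  invisible(x)
}

#' Full validation report for a QSAR regression model
#'
#' Bundles training metrics, leave-one-out and k-fold cross-validation into
#' one report with pass/fail flags against [qsar_thresholds].
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response.
#' @param k folds for the k-fold component (default 5).
#' @param seed seed for fold assignment.
#' @return A list of class `validation_report` with components `training`,
#'   `loo`, `kfold`, `thresholds`, `flags`.
#' @export
validation_report <- function(X, y, k = 5L, seed = 20260417L) {
  X <- as.matrix(X)
  fit <- fit_ols(X, y)
  training <- regression_metrics(y, fit$fitted_values, p = ncol(X))
  loo <- q2_loo(X, y)
  kf <- q2_kfold(X, y, k = k, seed = seed)
  flags <- c(
    r2 = unname(training$r2 > qsar_thresholds["r2"]),
    q2_loo = unname(loo$q2 > qsar_thresholds["q2"]),
    q2_kfold = unname(kf$q2 > qsar_thresholds["q2"]),
    mae = unname(training$mae < qsar_thresholds["mae"]),
    ccc = unname(loo$ccc > qsar_thresholds["ccc"]))
  structure(list(training = training, loo = loo, kfold = kf,
                 thresholds = qsar_thresholds, flags = flags,
                 model = fit$model, seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("QSAR validation report\n")
  cat(sprintf("  training: R2 = %.4f, R2adj = %.4f, RMSE = %.4f, MAE = %.4f\n",
              x$training$r2, x$training$r2_adjusted, x$training$rmse,
              x$training$mae))
  cat(sprintf("  LOO-CV:   Q2 = %.4f, RMSE = %.4f, MAE = %.4f, CCC = %.4f\n",
              x$loo$q2, x$loo$rmse, x$loo$mae, x$loo$ccc))
  cat(sprintf("  %d-fold:   Q2 = %.4f, RMSE = %.4f\n",
              x$kfold$k, x$kfold$q2, x$kfold$rmse))
  cat("  thresholds met:", paste(names(x$flags)[x$flags], collapse = ", "),
      "\n")
  invisible(x)
}
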