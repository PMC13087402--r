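#' Fit an ordinary least squares QSAR model
#'
#' Fits `y = b + X %*% m` by QR decomposition (via [stats::lm.fit()] on the
#' design with an intercept column). The intercept is always included. Rank
#' deficiency or near-singularity is an error, not a silent pseudo-inverse:
#' a reported QSAR equation must be unique.
#'
#' @param X numeric matrix (n compounds x p descriptors) with colnames.
#' @param y numeric response vector of length n.
#' @param name label for the resulting model.
#' @param response_label endpoint name stored in the model.
#' @param allow_saturated allow `n == p + 1` (exact fit); off by default.
#' @param condition_limit condition number of the design above which the fit
#'   is rejected as numerically collinear.
#' @return A list of class `fit_result`: `model` ([linear_model()]),
#'   `fitted_values`, `residuals`, `n`, `p`.
#' @export
fit_ols <- function(X, y, name = "mlr", response_label = "y",
                    allow_saturated = FALSE, condition_limit = 1e10) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  min_n <- if (allow_saturated) p + 1L else p + 2L
  if (n < min_n) {
    stop(sprintf("under-determined fit: n = %d compounds for p = %d descriptors",
                 n, p), call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- colnames(design)[qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  if (kappa(design, exact = TRUE) > condition_limit) {
    stop("design is numerically collinear (condition number > ",
         format(condition_limit), ")", call. = FALSE)
  }
  fit <- stats::lm.fit(design, y)
  coefs <- fit$coefficients
  model <- linear_model(name, response_label, colnames(X),
                        coefs[-1L], coefs[[1L]])
  structure(list(model = model,
                 fitted_values = as.numeric(fit$fitted.values),
                 residuals = as.numeric(fit$residuals),
                 n = n, p = p),
            class = "fit_result")
}

#' Predict activities from a linear model
#'
#' Applies `yhat_i = b + sum_j m_j x_ij` in the model's descriptor order.
#' Extra columns in the table are ignored; a missing model descriptor is an
#' error. Descriptor names are resolved through
#' [canonical_descriptor_name()] so ASCII aliases match.
#'
#' @param object a [linear_model()].
#' @param table a [descriptor_table()] or numeric matrix with colnames.
#' @param ... unused.
#' @return Named numeric vector of predictions (names = compound ids where
#'   available).
#' @export
predict.linear_model <- function(object, table, ...) {
  X <- as.matrix(table)
  have <- canonical_descriptor_name(colnames(X))
  want <- canonical_descriptor_name(object$descriptor_names)
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("descriptor(s) missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Xo <- X[, match(want, have), drop = FALSE]
  out <- as.numeric(Xo %*% unname(object$coefficients) + object$intercept)
  names(out) <- rownames(X)
  out
}

#' Published antioxidant QSAR models
#'
#' The two reported four-descriptor regression equations for the
#' quinoline-sulfonamide panel, carried as fixtures with their printed
#' coefficients (they cannot be refit here because the full descriptor
#' matrix is not part of this package):
#'
#' * DPPH radical scavenging (percent):
#'   `%DPPH = 0.0685 ATS5s - 74.5372 GATS1e - 6.0133 Mor04p - 12.0745 Mor24u + 20.4924`
#' * Superoxide scavenging (pIC50):
#'   `pIC50 = 7.8664 R1v - 2.2827 AATS8p - 0.1794 B08[C-O] + 22.3828 D211 - 3.3978`
#'
#' @return A list with components `dpph` and `sod`, each a [linear_model()].
#' @export
published_models <- function() {
  list(
    dpph = linear_model(
      name = "dpph", response_label = "dpph_percent",
      descriptor_names = c("ATS5s", "GATS1e", "Mor04p", "Mor24u"),
      coefficients = c(0.0685, -74.5372, -6.0133, -12.0745),
      intercept = 20.4924),
    sod = linear_model(
      name = "sod", response_label = "sod_pic50",
      descriptor_names = c("R1v", "AATS8p", "B08[C–O]", "D211"),
      coefficients = c(7.8664, -2.2827, -0.1794, 22.3828),
      intercept = -3.3978)
  )
}
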