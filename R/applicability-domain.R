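#' Leverage values of a descriptor design
#'
#' Diagonal of the hat matrix `H = D (D'D)^-1 D'` of the design `D = [1, X]`
#' (intercept always included). A compound's leverage measures how far its
#' descriptor profile lies from the centroid of the training set.
#'
#' @param X numeric descriptor matrix (n x p), full rank with `n > p + 1`.
#' @return Numeric vector `h` of length n; satisfies `sum(h) == p + 1`.
#' @export
leverages <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 for leverage analysis", call. = FALSE)
  design <- cbind(1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient design in leverage computation", call. = FALSE)
  }
  h <- rowSums(qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]^2)
  stats::setNames(h, rownames(X))
}

#' Critical leverage threshold
#'
#' The warning leverage `h* = 3 (p + 1) / n` conventionally used to bound
#' the applicability domain in a Williams plot.
#'
#' @param p number of descriptors in the model.
#' @param n number of training compounds (> 0).
#' @return `h*`.
#' @export
critical_leverage <- function(p, n) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (p < 0) stop("p must be >= 0", call. = FALSE)
  3 * (p + 1) / n
}

#' Standardized residuals
#'
#' Residuals divided by their sample (n - 1) standard deviation, in sigma
#' units. With `studentized = TRUE`, each residual is additionally
#' leverage-adjusted (internally studentized,
#' `e_i / (s * sqrt(1 - h_i))`), requiring `h`.
#'
#' @param residuals raw residual vector (n >= 2, non-zero spread).
#' @param studentized use internal studentization (default `FALSE`).
#' @param h leverage vector, required when `studentized = TRUE`.
#' @return Standardized residuals.
#' @export
standardized_residuals <- function(residuals, studentized = FALSE, h = NULL) {
  n <- length(residuals)
  if (n < 2L) stop("need at least 2 residuals", call. = FALSE)
  s <- stats::sd(residuals)
  if (s == 0) stop("zero residual spread: standardization undefined", call. = FALSE)
  if (!studentized) return(residuals / s)
  if (is.null(h)) stop("h required for studentized residuals", call. = FALSE)
  residuals / (s * sqrt(pmax(1 - h, .Machine$double.eps)))
}

#' Williams-plot applicability domain report
#'
#' Combines descriptor-space leverages with standardized residuals of a
#' fitted (or supplied) linear model. A compound is inside the
#' applicability domain iff its leverage is below `h* = 3(p+1)/n` and its
#' standardized residual lies within +/- `sigma_band` sigma.
#'
#' @param X numeric descriptor matrix restricted to the model descriptors.
#' @param y observed response.
#' @param model optional [linear_model()]; when `NULL`, an OLS model is fit
#'   to `(X, y)` first.
#' @param sigma_band residual band half-width in sigma units (default 3).
#' @param studentized standardization variant passed to
#'   [standardized_residuals()].
#' @return A list of class `ad_report`: `table` (data frame with columns
#'   id, leverage, std_residual, in_domain), `h_star`, `sigma_band`, `n`,
#'   `p`.
#' @export
williams_report <- function(X, y, model = NULL, sigma_band = 3,
                            studentized = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (is.null(model)) model <- fit_ols(X, y)$model
  pred <- predict(model, X)
  res <- y - pred
  h <- leverages(X)
  sr <- standardized_residuals(res, studentized = studentized, h = h)
  hs <- critical_leverage(p, n)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  tab <- data.frame(id = ids, leverage = as.numeric(h),
                    std_residual = as.numeric(sr),
                    in_domain = as.numeric(h) < hs & abs(sr) <= sigma_band,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, h_star = hs, sigma_band = sigma_band,
                 n = n, p = p, model = model),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf(
    "Applicability domain (Williams): n = %d, p = %d, h* = %.2f, band = +/-%g sigma\n",
    x$n, x$p, x$h_star, x$sigma_band))
  cat(sprintf("  %d of %d compounds in domain\n",
              sum(x$table$in_domain), nrow(x$table)))
  invisible(x)
}

#' Write Williams plot data to CSV
#'
#' Emits the (id, leverage, std_residual, in_domain) rows behind a Williams
#' plot.
#'
#' @param report an [williams_report()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ad_plot_data <- function(report, path) {
  stopifnot(inherits(report, "ad_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
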