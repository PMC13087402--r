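#' Construct a linear QSAR model
#'
#' A fitted (or published) multiple linear regression model
#' `Y = m1*x1 + m2*x2 + ... + mn*xn + b` mapping named molecular descriptors
#' to an activity endpoint.
#'
#' @param name short model label.
#' @param response_label name of the modeled endpoint (e.g. `"dpph_percent"`).
#' @param descriptor_names ordered character vector of descriptor names.
#' @param coefficients numeric vector `m_i`, same length and order as
#'   `descriptor_names`.
#' @param intercept numeric intercept `b`.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(name, response_label, descriptor_names,
                         coefficients, intercept) {
  descriptor_names <- as.character(descriptor_names)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(descriptor_names)) {
    stop("coefficients and descriptor_names must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(descriptor_names)) {
    stop("duplicated descriptor names in model", call. = FALSE)
  }
  if (any(!is.finite(coefficients)) || !is.finite(intercept)) {
    stop("model coefficients and intercept must be finite", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 response_label = as.character(response_label),
                 descriptor_names = descriptor_names,
                 coefficients = stats::setNames(coefficients, descriptor_names),
                 intercept = as.numeric(intercept)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, digits = 4, ...) {
  terms <- character(0)
  if (length(x$coefficients)) {
    terms <- sprintf("%+.*f(%s)", digits, x$coefficients, x$descriptor_names)
  }
  cat(sprintf("Linear model '%s': %s = %s %+.*f\n", x$name, x$response_label,
              paste(terms, collapse = " "), digits, x$intercept))
  invisible(x)
}

#' Write / read a linear model as JSON
#'
#' Serialization is lossless: coefficients are written at full double
#' precision with stable field order.
#'
#' @param model a [linear_model()].
#' @param path file path.
#' @return `write_linear_model` returns `path` invisibly;
#'   `read_linear_model` returns a [linear_model()].
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  obj <- list(type = "linear_model",
              name = model$name,
              response_label = model$response_label,
              descriptor_names = model$descriptor_names,
              coefficients = unname(model$coefficients),
              intercept = model$intercept)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed model file: ", path, call. = FALSE)
                  })
  if (!identical(obj$type, "linear_model")) {
    stop("not a linear_model JSON file: ", path, call. = FALSE)
  }
  linear_model(obj$name, obj$response_label,
               as.character(obj$descriptor_names %||% character(0)),
               as.numeric(obj$coefficients %||% numeric(0)),
               obj$intercept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
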