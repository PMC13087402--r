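#' Screen designed candidate compounds with stored models
#'
#' Applies regression QSAR models and (optionally) a classification tree to
#' a candidate descriptor table, ranks candidates per endpoint by predicted
#' activity (descending; ties broken by compound id), and, where a
#' candidate maps to a prototype compound with a known experimental value,
#' flags whether the prediction improves on the prototype.
#'
#' @param candidates a [descriptor_table()] of designed compounds.
#' @param models named list of [linear_model()]s (e.g.
#'   `list(dpph = ..., sod = ...)`); names become endpoint labels.
#' @param tree optional `tree_model` for antimicrobial class prediction.
#' @param prototype_map optional named character vector mapping candidate id
#'   to prototype compound id.
#' @param prototype_values optional named list, one named numeric vector per
#'   endpoint, giving experimental prototype values keyed by prototype id.
#' @return A list of class `screening_report`: `table` (data frame with one
#'   row per candidate: predictions, per-endpoint rank, predicted class,
#'   improvement flags) and `endpoints`.
#' @export
screen <- function(candidates, models, tree = NULL,
                   prototype_map = NULL, prototype_values = NULL) {
  stopifnot(inherits(candidates, "descriptor_table") || is.matrix(candidates))
  if (!length(models) || is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be a non-empty named list", call. = FALSE)
  }
  X <- as.matrix(candidates)
  ids <- rownames(X)
  n <- nrow(X)
  tab <- data.frame(id = ids, stringsAsFactors = FALSE)
  endpoints <- names(models)
  for (ep in endpoints) {
    pred <- if (n) predict(models[[ep]], X) else numeric(0)
    tab[[paste0("pred_", ep)]] <- as.numeric(pred)
    # rank by predicted value descending, ties by id
    if (n) {
      ord <- order(-as.numeric(pred), ids)
      rk <- integer(n); rk[ord] <- seq_len(n)
      tab[[paste0("rank_", ep)]] <- rk
    } else {
      tab[[paste0("rank_", ep)]] <- integer(0)
    }
    proto_val <- rep(NA_real_, n)
    if (!is.null(prototype_map) && !is.null(prototype_values[[ep]])) {
      pid <- prototype_map[ids]
      hit <- !is.na(pid) & pid %in% names(prototype_values[[ep]])
      proto_val[hit] <- prototype_values[[ep]][pid[hit]]
      missed <- ids[is.na(pid)]
      if (length(missed)) {
        warning("no prototype mapping for candidate(s): ",
                paste(missed, collapse = ", "))
      }
    }
    tab[[paste0("prototype_", ep)]] <- proto_val
    tab[[paste0("improved_", ep)]] <- !is.na(proto_val) &
      tab[[paste0("pred_", ep)]] > proto_val
  }
  if (!is.null(tree)) {
    tab$pred_class <- if (n) unname(apply_tree(tree, X)) else character(0)
  }
  # linear predictions of a percent endpoint can leave [0, 100]
  if ("pred_dpph" %in% colnames(tab)) {
    tab$dpph_out_of_range <- tab$pred_dpph < 0 | tab$pred_dpph > 100
  }
  structure(list(table = tab, endpoints = endpoints),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report: %d candidate(s), endpoint(s): %s\n",
              nrow(x$table), paste(x$endpoints, collapse = ", ")))
  if ("pred_class" %in% colnames(x$table) && nrow(x$table)) {
    cat("  predicted classes:",
        paste(sprintf("%s = %d", names(table(x$table$pred_class)),
                      as.integer(table(x$table$pred_class))), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Top-k candidates for an endpoint
#'
#' @param report a [screen()] result.
#' @param endpoint endpoint label present in the report.
#' @param k number of candidates to return (>= 1); if `k` exceeds the table
#'   size the full ranking is returned with a warning.
#' @return Data frame of the first `k` rows by rank for the endpoint.
#' @export
top_k <- function(report, endpoint, k) {
  stopifnot(inherits(report, "screening_report"))
  if (!endpoint %in% report$endpoints) {
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  tab <- report$table
  if (k > nrow(tab)) {
    warning("k exceeds number of candidates; returning all")
    k <- nrow(tab)
  }
  ord <- order(tab[[paste0("rank_", endpoint)]])
  tab[ord[seq_len(k)], , drop = FALSE]
}
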