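#' Remove constant and duplicated descriptor columns
#'
#' Wide descriptor tables (thousands of columns from several generators)
#' routinely contain zero-variance columns and exact duplicates; both are
#' uninformative for regression and are dropped before selection, keeping
#' the first occurrence of each duplicated column.
#'
#' @param table a [descriptor_table()].
#' @return A [descriptor_table()] with the surviving columns, in original
#'   order. Dropped names are attached as attributes `dropped_constant` and
#'   `dropped_duplicate`.
#' @export
constant_redundant_filter <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  X <- unclass(table)
  is_const <- apply(X, 2L, function(v) max(v) == min(v))
  keep <- !is_const
  # exact duplicates among non-constant columns, first occurrence kept
  dup <- rep(FALSE, ncol(X))
  seen <- list()
  for (j in which(keep)) {
    key <- paste(X[, j], collapse = "\r")
    if (!is.null(seen[[key]])) dup[j] <- TRUE else seen[[key]] <- j
  }
  keep <- keep & !dup
  if (!any(keep)) {
    stop("all descriptor columns removed by constant/duplicate filter",
         call. = FALSE)
  }
  out <- descriptor_table(X[, keep, drop = FALSE],
                          compound_ids = rownames(X),
                          descriptor_names = colnames(X)[keep])
  attr(out, "dropped_constant") <- colnames(X)[is_const]
  attr(out, "dropped_duplicate") <- colnames(X)[dup]
  out
}

# residual sum of squares of y on design [1, X[, cols]]
.rss <- function(X, y, cols) {
  d <- cbind(1, X[, cols, drop = FALSE])
  f <- stats::lm.fit(d, y)
  sum(f$residuals^2)
}

#' Stepwise multiple linear regression descriptor selection
#'
#' Classical forward-entry / backward-removal stepwise selection driven by
#' partial-F p-values. At each forward step the candidate with the smallest
#' entry p-value below `alpha_enter` is added (ties broken by column order);
#' after each entry, entered descriptors whose removal p-value exceeds
#' `alpha_remove` are dropped, worst first. Candidates that would make the
#' design rank-deficient are skipped with a logged reason. Terminates when
#' no entry or removal changes the set.
#'
#' @param X numeric matrix with descriptor colnames.
#' @param y numeric response.
#' @param alpha_enter p-to-enter threshold (default 0.05).
#' @param alpha_remove p-to-remove threshold (default 0.10), must be
#'   `>= alpha_enter`.
#' @param max_terms optional cap on model size (default `n - 2` so the fit
#'   keeps a residual degree of freedom).
#' @return A list of class `selection_result`: `method`, `selected_names`
#'   (in entry order), `trace` (data frame of step records).
#' @export
stepwise_select <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                            max_terms = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("X has no columns", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  if (alpha_enter > alpha_remove) {
    stop("alpha_enter must be <= alpha_remove", call. = FALSE)
  }
  if (is.null(max_terms)) max_terms <- n - 2L
  sel <- integer(0)
  trace <- list()
  note <- function(action, cand, crit) {
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, candidate = cand, p_value = crit,
      stringsAsFactors = FALSE)
  }
  sstot <- sum((y - mean(y))^2)
  rss_floor <- max(1e-10 * sstot, 1e-25)
  partial_f_p <- function(cols_small, cols_big) {
    rss0 <- .rss(X, y, cols_small); rss1 <- .rss(X, y, cols_big)
    df2 <- n - length(cols_big) - 1L
    if (df2 <= 0L) return(NA_real_)
    # the smaller model already fits to numerical precision: nothing to gain
    if (rss0 <= rss_floor) return(1)
    if (rss1 <= rss_floor) return(0)
    f <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    # forward entry
    if (length(sel) < max_terms) {
      cand <- setdiff(seq_len(ncol(X)), sel)
      best_j <- NA_integer_; best_p <- Inf
      for (j in cand) {
        d <- cbind(1, X[, c(sel, j), drop = FALSE])
        if (qr(d)$rank < ncol(d)) {
          note("skip_collinear", colnames(X)[j], NA_real_)
          next
        }
        pj <- partial_f_p(sel, c(sel, j))
        if (!is.na(pj) && pj < best_p - 1e-12) { best_p <- pj; best_j <- j }
      }
      if (!is.na(best_j) && best_p < alpha_enter) {
        sel <- c(sel, best_j)
        note("enter", colnames(X)[best_j], best_p)
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (length(sel) < 2L) break
      worst_j <- NA_integer_; worst_p <- -Inf
      for (j in sel) {
        pj <- partial_f_p(setdiff(sel, j), sel)
        if (!is.na(pj) && pj > worst_p + 1e-12) { worst_p <- pj; worst_j <- j }
      }
      if (!is.na(worst_j) && worst_p > alpha_remove) {
        sel <- setdiff(sel, worst_j)
        note("remove", colnames(X)[worst_j], worst_p)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  structure(list(method = "stepwise",
                 selected_names = colnames(X)[sel],
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(action = character(0), candidate = character(0),
                              p_value = numeric(0))),
            class = "selection_result")
}

# CFS merit of a feature subset: k * mean|r_cf| / sqrt(k + k(k-1) mean|r_ff|)
.cfs_merit <- function(r_cf, r_ff, subset) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(abs(r_cf[subset]))
  if (k == 1L) return(rcf)
  rff <- mean(abs(r_ff[subset, subset][upper.tri(diag(k))]))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature subset selection with best-first search
#'
#' Scores subsets by the CFS merit
#' `k * mean|r_cf| / sqrt(k + k(k-1) * mean|r_ff|)` — high mean
#' feature-class correlation, low mean feature-feature intercorrelation —
#' and searches forward from the empty set by best-first expansion, stopping
#' after `stale_limit` consecutive expansions that fail to improve the best
#' merit. Deterministic: ties are broken by column order.
#'
#' @param X numeric matrix with colnames.
#' @param y numeric response.
#' @param stale_limit consecutive non-improving expansions tolerated
#'   (default 5).
#' @return A `selection_result` (see [stepwise_select()]); the trace records
#'   each expansion with its merit.
#' @export
cfs_bestfirst <- function(X, y, stale_limit = 5L) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("X has no columns", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  r_cf <- rep(0, p)
  ok <- sds > 0 & stats::sd(y) > 0
  r_cf[ok] <- abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE], y)))
  r_ff <- matrix(0, p, p)
  if (any(ok)) {
    r_ff[ok, ok] <- abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE])))
  }
  r_ff[is.na(r_ff)] <- 0
  key <- function(s) paste(sort(s), collapse = ",")
  open <- list(list(s = integer(0), merit = 0))
  visited <- new.env(parent = emptyenv())
  best_s <- integer(0); best_merit <- 0; stale <- 0L
  trace <- list()
  while (length(open) && stale < stale_limit) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    i <- which.max(merits)            # which.max takes the first on ties
    node <- open[[i]]; open[[i]] <- NULL
    open <- open[!vapply(open, is.null, logical(1))]
    improved <- FALSE
    for (j in setdiff(seq_len(p), node$s)) {
      s2 <- c(node$s, j)
      k2 <- key(s2)
      if (!is.null(visited[[k2]])) next
      assign(k2, TRUE, envir = visited)
      m2 <- .cfs_merit(r_cf, r_ff, s2)
      trace[[length(trace) + 1L]] <- data.frame(
        action = "expand", candidate = key(s2), merit = m2,
        stringsAsFactors = FALSE)
      open[[length(open) + 1L]] <- list(s = s2, merit = m2)
      if (m2 > best_merit + 1e-12) {
        best_merit <- m2; best_s <- s2; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(method = "cfs_bestfirst",
                 selected_names = colnames(X)[sort(best_s)],
                 merit = best_merit,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(action = character(0), candidate = character(0),
                              merit = numeric(0))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection (%s): %d descriptor(s) selected\n",
              x$method, length(x$selected_names)))
  if (length(x$selected_names)) {
    cat("  ", paste(x$selected_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise intercorrelation check of selected descriptors
#'
#' Computes the Pearson correlation matrix of the selected descriptors and
#' checks that every off-diagonal `|r|` is at or below `cutoff` (default
#' 0.9), the usual independence screen applied to a final QSAR descriptor
#' set.
#'
#' @param table a [descriptor_table()] or numeric matrix restricted to the
#'   selected descriptors.
#' @param cutoff maximum tolerated absolute pairwise correlation.
#' @return A list: `r_matrix` (symmetric, unit diagonal), `pass` (logical),
#'   `violations` (data frame of offending pairs).
#' @export
intercorrelation_check <- function(table, cutoff = 0.9) {
  X <- as.matrix(table)
  if (ncol(X) < 2L) stop("need at least 2 selected descriptors", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance descriptor(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(X)
  off <- abs(r); diag(off) <- 0
  bad <- which(off > cutoff, arr.ind = TRUE)
  bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
  violations <- data.frame(
    descriptor_1 = colnames(X)[bad[, 1L]],
    descriptor_2 = colnames(X)[bad[, 2L]],
    r = r[bad],
    stringsAsFactors = FALSE)
  list(r_matrix = r, pass = nrow(violations) == 0L, violations = violations,
       cutoff = cutoff)
}
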