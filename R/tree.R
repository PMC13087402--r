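#' Decision tree model constructors
#'
#' A `tree_model` is a finite binary tree over continuous descriptor
#' thresholds. Rows route left when `value <= threshold` and right when
#' `value > threshold`; leaves carry a class label and the training
#' (correct, incorrect) counts.
#'
#' @param class_label leaf class (`"active"` or `"inactive"`).
#' @param n_correct,n_incorrect training counts at the leaf.
#' @return `tree_leaf` / `tree_split` return node lists; both are wrapped in
#'   class `tree_model` when used as a tree root via [as_tree_model()].
#' @export
tree_leaf <- function(class_label, n_correct = 0L, n_incorrect = 0L) {
  stopifnot(class_label %in% c("active", "inactive"))
  list(kind = "leaf", class_label = class_label,
       n_correct = as.integer(n_correct), n_incorrect = as.integer(n_incorrect))
}

#' @rdname tree_leaf
#' @param descriptor_name split descriptor.
#' @param threshold split point; `<=` goes left.
#' @param left,right child nodes.
#' @export
tree_split <- function(descriptor_name, threshold, left, right) {
  stopifnot(is.finite(threshold))
  list(kind = "split", descriptor_name = as.character(descriptor_name),
       threshold = as.numeric(threshold), left = left, right = right)
}

#' @rdname tree_leaf
#' @param node root node built from [tree_leaf()] / [tree_split()].
#' @export
as_tree_model <- function(node) structure(list(root = node), class = "tree_model")

#' @export
print.tree_model <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      cat(sprintf("%s-> %s (%d/%d)\n", pad, node$class_label,
                  node$n_correct, node$n_correct + node$n_incorrect))
    } else {
      cat(sprintf("%s%s <= %g:\n", pad, node$descriptor_name, node$threshold))
      show(node$left, indent + 1L)
      cat(sprintf("%s%s >  %g:\n", pad, node$descriptor_name, node$threshold))
      show(node$right, indent + 1L)
    }
  }
  cat("Decision tree:\n"); show(x$root, 1L)
  invisible(x)
}

# entropy in bits of a class count vector
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# best (threshold, gain_ratio, gain) for one numeric column; candidate
# thresholds are midpoints between consecutive distinct sorted values
.best_split_for_column <- function(v, cls, min_leaf) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NULL)
  thr <- (u[-length(u)] + u[-1L]) / 2
  n <- length(v)
  h0 <- .entropy(table(cls))
  best <- NULL
  for (t in thr) {
    left <- v <= t
    nl <- sum(left); nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    hl <- .entropy(table(cls[left]))
    hr <- .entropy(table(cls[!left]))
    gain <- h0 - (nl / n) * hl - (nr / n) * hr
    if (gain <= 1e-12) next
    split_info <- .entropy(c(nl, nr))
    gr <- gain / split_info
    if (is.null(best) || gr > best$gain_ratio + 1e-12) {
      best <- list(threshold = t, gain_ratio = gr, gain = gain)
    }
  }
  best
}

.majority <- function(cls) {
  tab <- table(factor(cls, levels = c("active", "inactive")))
  # ties resolved toward "active" (first level)
  names(tab)[which.max(tab)]
}

#' Induce a C4.5-style decision tree
#'
#' Recursive binary splitting of continuous descriptors for binary
#' active/inactive classification. At each node every
#' (descriptor, threshold) pair is scored — candidate thresholds are
#' midpoints between consecutive distinct sorted values — and the split with
#' maximal information gain ratio (information gain divided by split
#' information) is taken. Recursion stops at class purity, when fewer than
#' `2 * min_leaf` rows remain, or when no split has positive gain; leaves
#' are labeled by majority class with (correct, incorrect) training counts.
#' No pruning is applied.
#'
#' @param table a [descriptor_table()] or numeric matrix with colnames.
#' @param classes character vector of `"active"`/`"inactive"`, one per row.
#' @param min_leaf minimum rows in each child of a split (default 2).
#' @return A `tree_model`.
#' @export
induce_tree <- function(table, classes, min_leaf = 2L) {
  X <- as.matrix(table)
  if (ncol(X) == 0L) stop("no descriptors to split on", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  classes <- as.character(classes)
  if (length(classes) != nrow(X)) {
    stop("classes must have one entry per row", call. = FALSE)
  }
  if (!all(classes %in% c("active", "inactive"))) {
    stop("classes must be 'active' or 'inactive'", call. = FALSE)
  }
  min_leaf <- max(1L, as.integer(min_leaf))
  grow <- function(idx) {
    cls <- classes[idx]
    maj <- .majority(cls)
    n_cor <- sum(cls == maj); n_inc <- length(cls) - n_cor
    if (n_inc == 0L || length(idx) < 2L * min_leaf) {
      return(tree_leaf(maj, n_cor, n_inc))
    }
    best <- NULL
    for (j in seq_len(ncol(X))) {
      cand <- .best_split_for_column(X[idx, j], cls, min_leaf)
      # ties between descriptors broken by column order (strict improvement)
      if (!is.null(cand) &&
          (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12)) {
        best <- c(cand, list(j = j))
      }
    }
    if (is.null(best)) return(tree_leaf(maj, n_cor, n_inc))
    left_idx <- idx[X[idx, best$j] <= best$threshold]
    right_idx <- idx[X[idx, best$j] > best$threshold]
    tree_split(colnames(X)[best$j], best$threshold,
               grow(left_idx), grow(right_idx))
  }
  as_tree_model(grow(seq_len(nrow(X))))
}

#' Reference antimicrobial QSPR tree
#'
#' The published two-level classification rule for the
#' quinoline-sulfonamide panel, carried with its printed cutoffs: compounds
#' with solvation connectivity index `X4sol <= 7.564` are active; otherwise
#' the Barysz-matrix ionization-potential index decides —
#' `VR2_Dzi <= 11.729` inactive, `> 11.729` active. Leaf counts are the
#' training-set tallies (5/0, 3/0, 2/1; one inactive compound falls in the
#' high-`VR2_Dzi` active leaf).
#'
#' @return A `tree_model`.
#' @export
paper_tree <- function() {
  as_tree_model(tree_split(
    "X4sol", 7.564,
    tree_leaf("active", 5L, 0L),
    tree_split("VR2_Dzi", 11.729,
               tree_leaf("inactive", 3L, 0L),
               tree_leaf("active", 2L, 1L))))
}

#' Apply a decision tree to a descriptor table
#'
#' Routes each row through the tree (`<=` left, `>` right) and returns the
#' leaf class labels. Extra columns are ignored; a missing split descriptor
#' is an error.
#'
#' @param tree a `tree_model`.
#' @param table a [descriptor_table()] or numeric matrix with colnames.
#' @return Character vector of predicted classes, named by row.
#' @export
apply_tree <- function(tree, table) {
  stopifnot(inherits(tree, "tree_model"))
  X <- as.matrix(table)
  have <- canonical_descriptor_name(colnames(X))
  route <- function(node, row) {
    if (node$kind == "leaf") return(node$class_label)
    j <- match(canonical_descriptor_name(node$descriptor_name), have)
    if (is.na(j)) {
      stop("descriptor missing from table: ", node$descriptor_name,
           call. = FALSE)
    }
    if (row[j] <= node$threshold) route(node$left, row) else route(node$right, row)
  }
  out <- vapply(seq_len(nrow(X)), function(i) route(tree$root, X[i, ]),
                character(1))
  names(out) <- rownames(X)
  out
}

#' Write / read a tree model as JSON
#'
#' The schema stores explicit `left` (`<=`) and `right` (`>`) children and
#' full-precision thresholds; the round-trip is lossless.
#'
#' @param tree a `tree_model`.
#' @param path file path.
#' @return `write_tree_model` returns `path` invisibly; `read_tree_model`
#'   returns a `tree_model`.
#' @export
write_tree_model <- function(tree, path) {
  stopifnot(inherits(tree, "tree_model"))
  jsonlite::write_json(list(type = "tree_model", root = tree$root), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_model
#' @export
read_tree_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed tree file: ", path,
                                           call. = FALSE))
  if (!identical(obj$type, "tree_model")) {
    stop("not a tree_model JSON file: ", path, call. = FALSE)
  }
  rebuild <- function(node) {
    if (identical(node$kind, "leaf")) {
      tree_leaf(node$class_label, node$n_correct, node$n_incorrect)
    } else if (identical(node$kind, "split")) {
      tree_split(node$descriptor_name, node$threshold,
                 rebuild(node$left), rebuild(node$right))
    } else stop("malformed tree node", call. = FALSE)
  }
  as_tree_model(rebuild(obj$root))
}
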