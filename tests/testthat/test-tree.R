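# independent exhaustive oracle: best (column, midpoint threshold) by gain
# ratio, scanning every candidate split
exhaustive_best_split <- function(X, cls, min_leaf = 1L) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts); -sum(p * log2(p))
  }
  n <- nrow(X)
  h0 <- ent(table(cls))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    for (t in (u[-length(u)] + u[-1]) / 2) {
      left <- X[, j] <= t
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      gain <- h0 - nl / n * ent(table(cls[left])) - nr / n * ent(table(cls[!left]))
      if (gain <= 1e-12) next
      si <- ent(c(nl, nr))
      gr <- gain / si
      if (is.null(best) || gr > best$gr + 1e-12) {
        best <- list(j = j, t = t, gr = gr)
      }
    }
  }
  best
}

test_that("perfectly separable 1-D data yields a single midpoint split", {
  X <- matrix(c(1, 2, 3, 4, 6, 7, 8, 9), ncol = 1,
              dimnames = list(NULL, "d"))
  cls <- c(rep("active", 4), rep("inactive", 4))
  tr <- induce_tree(X, cls, min_leaf = 1)
  expect_identical(tr$root$kind, "split")
  expect_equal(tr$root$threshold, 5)
  expect_identical(tr$root$left$class_label, "active")
  expect_identical(tr$root$right$class_label, "inactive")
  expect_identical(unname(apply_tree(tr, X)), cls)
})

test_that("induced splits match exhaustive gain-ratio enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    cls <- ifelse(X[, 2] + 0.3 * rnorm(n) > 0, "active", "inactive")
    if (length(unique(cls)) < 2) next
    tr <- induce_tree(X, cls, min_leaf = 2)
    oracle <- exhaustive_best_split(X, cls, min_leaf = 2)
    if (is.null(oracle)) {
      expect_identical(tr$root$kind, "leaf")
    } else {
      expect_identical(tr$root$descriptor_name, colnames(X)[oracle$j])
      expect_equal(tr$root$threshold, oracle$t, tolerance = 1e-12)
    }
  }
})

test_that("a planted two-level rule is reproduced with 100% training accuracy", {
  gen <- gen_classification(40, margin = 0.25, seed = 99)
  tr <- induce_tree(gen$table, gen$classes, min_leaf = 1)
  pred <- apply_tree(tr, gen$table)
  expect_identical(unname(pred), gen$classes)
  # two-level structure using both rule descriptors (the generating rule is
  # expressible with either descriptor at the root, so only the shape and
  # the split variables are pinned, not their order)
  splits <- list()
  walk <- function(node) {
    if (node$kind == "split") {
      splits[[length(splits) + 1L]] <<- node
      walk(node$left); walk(node$right)
    }
  }
  walk(tr$root)
  expect_length(splits, 2L)
  expect_setequal(vapply(splits, `[[`, character(1), "descriptor_name"),
                  c(gen$rule$d1, gen$rule$d2))
  # each threshold falls inside the margin gap around its true cutoff
  for (s in splits) {
    truth <- if (s$descriptor_name == gen$rule$d1) gen$rule$t1 else gen$rule$t2
    expect_lt(abs(s$threshold - truth), 0.25)
  }
})

test_that("single-class input yields a single-leaf tree, zero descriptors error", {
  X <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "d"))
  tr <- induce_tree(X, rep("active", 6))
  expect_identical(tr$root$kind, "leaf")
  expect_identical(tr$root$class_label, "active")
  expect_error(induce_tree(X[, 0, drop = FALSE], rep("active", 6)),
               "no descriptors")
})

test_that("the reference tree routes by the published cutoffs", {
  tr <- paper_tree()
  X <- descriptor_table(
    rbind(c(7.0, 50), c(8.0, 11.0), c(8.0, 12.0), c(7.564, 0)),
    compound_ids = c("low_x4", "high_x4_low_vr", "high_x4_high_vr", "at_cut"),
    descriptor_names = c("X4sol", "VR2_Dzi"))
  pred <- apply_tree(tr, X)
  expect_identical(unname(pred),
                   c("active", "inactive", "active", "active"))
  # value exactly at the threshold goes left (<=): at_cut is active
  expect_identical(unname(pred["at_cut"]), "active")
})

test_that("apply_tree ignores extra columns and errors on missing ones", {
  tr <- paper_tree()
  X <- matrix(c(7, 12, 1), 1, 3,
              dimnames = list("c", c("X4sol", "VR2_Dzi", "junk")))
  expect_identical(unname(apply_tree(tr, X)), "active")
  expect_error(apply_tree(tr, X[, "junk", drop = FALSE]), "X4sol")
  single <- as_tree_model(tree_leaf("inactive"))
  expect_identical(unname(apply_tree(single, X)), "inactive")
})

test_that("the published worked example scores 90.91 / 0.920 / 0.909 / 0.906", {
  panel <- as.character(c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13))
  actual <- ifelse(panel %in% c("3", "4", "5", "6", "8", "10", "12"),
                   "active", "inactive")
  predicted <- ifelse(panel %in% c("3", "4", "5", "6", "7", "8", "10", "12"),
                      "active", "inactive")
  m <- classification_metrics(actual, predicted)
  expect_equal(round(m$accuracy, 2), 90.91)
  expect_equal(round(m$precision, 3), 0.920)
  expect_equal(round(m$recall, 3), 0.909)
  expect_equal(round(m$f_measure, 3), 0.906)
  expect_identical(m$confusion, list(tp = 7L, fp = 1L, tn = 3L, fn = 0L))
})

test_that("classification metrics match brute-force per-class computation", {
  set.seed(13)
  actual <- sample(c("active", "inactive"), 30, replace = TRUE)
  predicted <- sample(c("active", "inactive"), 30, replace = TRUE)
  m <- classification_metrics(actual, predicted)
  # independent hand computation
  per <- sapply(c("active", "inactive"), function(cl) {
    tp <- sum(actual == cl & predicted == cl)
    prec <- if (sum(predicted == cl) == 0) 0 else tp / sum(predicted == cl)
    rec <- tp / sum(actual == cl)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec = prec, rec = rec, f1 = f1, w = mean(actual == cl))
  })
  expect_equal(m$precision, sum(per["prec", ] * per["w", ]))
  expect_equal(m$recall, sum(per["rec", ] * per["w", ]))
  expect_equal(m$f_measure, sum(per["f1", ] * per["w", ]))
  expect_equal(m$accuracy, 100 * mean(actual == predicted))
})

test_that("weighted recall equals accuracy/100 for random confusion matrices", {
  set.seed(29)
  for (r in 1:25) {
    n <- sample(5:40, 1)
    actual <- sample(c("active", "inactive"), n, replace = TRUE)
    predicted <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(actual)) < 2) next
    m <- classification_metrics(actual, predicted)
    expect_equal(m$recall * 100, m$accuracy, tolerance = 1e-12)
  }
})

test_that("perfect prediction scores 100 / 1 / 1 / 1", {
  actual <- c("active", "inactive", "active")
  m <- classification_metrics(actual, actual)
  expect_equal(m$accuracy, 100)
  expect_equal(c(m$precision, m$recall, m$f_measure), c(1, 1, 1))
})

test_that("LOO classification on wide-margin data reaches 100% accuracy", {
  # two tight clusters separated by a wide gap: every training complement
  # induces its single split inside the gap, so each held-out point is
  # routed correctly
  set.seed(17)
  X <- cbind(d = c(runif(14, 0, 1), runif(8, 9, 10)),
             noise = rnorm(22))
  cls <- c(rep("active", 14), rep("inactive", 8))
  cv <- cv_classification(X, cls, scheme = "loo", min_leaf = 1)
  expect_equal(cv$accuracy, 100)
  expect_identical(cv$n_inductions, 22L)
})

test_that("boundary-adjacent data drops CV accuracy below training accuracy", {
  gen <- gen_classification(24, margin = 0.01, spread = 0.4, seed = 5)
  tr <- induce_tree(gen$table, gen$classes, min_leaf = 1)
  train_acc <- classification_metrics(
    gen$classes, unname(apply_tree(tr, gen$table)))$accuracy
  cv <- cv_classification(gen$table, gen$classes, scheme = "loo",
                          min_leaf = 1)
  expect_equal(train_acc, 100)
  expect_lt(cv$accuracy, train_acc)
})

test_that("stratified k-fold classification is seeded and reproducible", {
  gen <- gen_classification(22, margin = 0.1, seed = 71)
  a <- cv_classification(gen$table, gen$classes, scheme = "kfold", k = 5,
                         seed = 11)
  b <- cv_classification(gen$table, gen$classes, scheme = "kfold", k = 5,
                         seed = 11)
  expect_identical(a$fold_assignment, b$fold_assignment)
  expect_identical(a$accuracy, b$accuracy)
  # stratification: every fold contains both classes where sizes allow
  tab <- table(a$fold_assignment, gen$classes)
  expect_true(all(rowSums(tab > 0) >= 1))
})
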