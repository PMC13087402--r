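test_that("constant and duplicate columns are removed, first kept", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  X[, 3] <- 1.5          # constant
  X[, 5] <- X[, 2]       # duplicate
  tab <- descriptor_table(X, sprintf("c%d", 1:8), sprintf("d%d", 1:5))
  out <- constant_redundant_filter(tab)
  # brute-force scan oracle
  keep <- rep(TRUE, 5)
  for (j in 1:5) {
    if (length(unique(X[, j])) == 1L) keep[j] <- FALSE
    else for (i in seq_len(j - 1L)) {
      if (keep[i] && all(X[, i] == X[, j])) { keep[j] <- FALSE; break }
    }
  }
  expect_identical(colnames(out), sprintf("d%d", which(keep)))
  expect_identical(attr(out, "dropped_constant"), "d3")
  expect_identical(attr(out, "dropped_duplicate"), "d5")
  expect_error(constant_redundant_filter(
    descriptor_table(matrix(1, 3, 2), letters[1:3], c("x", "y"))), "all")
})

test_that("stepwise selection recovers an exactly planted two-column signal", {
  set.seed(42)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("d", 1:10)))
  y <- 2 * X[, 3] - 3 * X[, 7] + 5
  sel <- stepwise_select(X, y)
  expect_setequal(sel$selected_names, c("d3", "d7"))
  expect_true(all(sel$trace$action %in% c("enter", "remove", "skip_collinear")))
})

test_that("stepwise selection on pure noise stays near-empty", {
  # false-entry behaviour consistent with alpha: over repeats, selecting
  # nothing is the most common outcome and large sets never occur
  sizes <- integer(20)
  for (r in seq_len(20)) {
    set.seed(100 + r)
    X <- matrix(rnorm(50 * 8), 50, 8)
    y <- rnorm(50)
    sizes[r] <- length(stepwise_select(X, y, alpha_enter = 0.05)$selected_names)
  }
  expect_gte(sum(sizes == 0L), 10L)
  expect_lte(max(sizes), 3L)
})

test_that("stepwise never selects a zero-variance column", {
  set.seed(9)
  X <- cbind(const = rep(2, 20), signal = rnorm(20))
  y <- 3 * X[, "signal"] + rnorm(20, sd = 0.01)
  sel <- stepwise_select(X, y)
  expect_false("const" %in% sel$selected_names)
  expect_true("signal" %in% sel$selected_names)
})

test_that("stepwise selection is invariant to row order and constant columns", {
  set.seed(33)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X[, 2] - 2 * X[, 5] + rnorm(25, sd = 0.05)
  base <- stepwise_select(X, y)$selected_names
  perm <- sample(25)
  expect_identical(stepwise_select(X[perm, ], y[perm])$selected_names, base)
  Xc <- cbind(X, kconst = 7)
  expect_identical(stepwise_select(Xc, y)$selected_names, base)
})

cfs_merit_oracle <- function(X, y, subset) {
  k <- length(subset)
  if (k == 0) return(0)
  rcf <- mean(abs(cor(X[, subset, drop = FALSE], y)))
  if (k == 1) return(rcf)
  rff <- abs(cor(X[, subset, drop = FALSE]))
  rff <- mean(rff[upper.tri(rff)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

test_that("a perfectly correlated singleton wins CFS", {
  set.seed(4)
  X <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X[, 4]
  sel <- cfs_bestfirst(X, y)
  expect_true("d4" %in% sel$selected_names)
  expect_gte(sel$merit, cfs_merit_oracle(X, y, 4))
})

test_that("best-first CFS matches exhaustive subset enumeration on 4 columns", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("d", 1:4)))
    y <- 1.5 * X[, 1] + 0.8 * X[, 3] + rnorm(25, sd = 0.5)
    sel <- cfs_bestfirst(X, y, stale_limit = 10L)
    # exhaustive oracle over all 15 nonempty subsets
    subsets <- unlist(lapply(1:4, function(k) combn(4, k, simplify = FALSE)),
                      recursive = FALSE)
    merits <- vapply(subsets, function(s) cfs_merit_oracle(X, y, s), numeric(1))
    best <- subsets[[which.max(merits)]]
    expect_identical(sel$selected_names, paste0("d", best))
    expect_equal(sel$merit, max(merits), tolerance = 1e-10)
  }
})

test_that("CFS redundancy penalty admits only one of two identical columns", {
  set.seed(17)
  base <- rnorm(30)
  X <- cbind(a = base, b = base, c = rnorm(30))
  y <- base + rnorm(30, sd = 0.1)
  sel <- cfs_bestfirst(X, y)
  expect_equal(sum(c("a", "b") %in% sel$selected_names), 1L)
})

test_that("intercorrelation check matches the direct Pearson formula", {
  set.seed(8)
  X <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, paste0("d", 1:4)))
  chk <- intercorrelation_check(X, cutoff = 0.9)
  # brute-force pairwise r
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(chk$r_matrix[i, j], r, tolerance = 1e-12)
  }
  expect_equal(chk$r_matrix, t(chk$r_matrix))
  expect_equal(unname(diag(chk$r_matrix)), rep(1, 4))
  expect_true(chk$pass)
})

test_that("identical columns fail and orthogonal columns pass the cutoff", {
  x <- c(1, 2, 3, 4)
  dup <- cbind(a = x, b = x)
  chk <- intercorrelation_check(dup)
  expect_false(chk$pass)
  expect_equal(chk$violations$r, 1)
  orth <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_true(intercorrelation_check(orth)$pass)
  expect_error(intercorrelation_check(cbind(a = rep(1, 4), b = x)),
               "zero-variance")
})
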