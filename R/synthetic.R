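#' Generate a descriptor table with planted linear activity structure
#'
#' Emulates the small-n / wide-p regime of descriptor-based QSAR modeling:
#' a handful of informative descriptors carrying an exact linear signal,
#' buried among nuisance descriptors. The nuisance block is equicorrelated
#' (pairwise correlation `rho`), mimicking the strong intercorrelation of
#' real autocorrelation descriptor families, so the `|r| <= 0.9`
#' independence screen is exercised meaningfully. Optional Bernoulli
#' columns mimic binary atom-pair fingerprint descriptors.
#'
#' @param n_compounds number of compounds (rows).
#' @param n_descriptors total descriptors (columns), `>=` number of
#'   informative ones.
#' @param informative named numeric vector: true coefficients keyed by
#'   descriptor name (these columns are generated independently, unit
#'   scale).
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation on the response
#'   (response units, `>= 0`).
#' @param rho pairwise correlation within the nuisance block (`|rho| < 1`).
#' @param n_binary number of nuisance columns drawn as Bernoulli(0.5)
#'   flags.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `table` ([descriptor_table()]), `y` (response vector),
#'   `truth` (list with `informative`, `intercept`, `noise_sd`, `seed`).
#' @export
gen_regression <- function(n_compounds, n_descriptors, informative,
                           intercept = 0, noise_sd = 0, rho = 0.6,
                           n_binary = 0L, seed = 20260417L) {
  if (is.null(names(informative)) || any(!nzchar(names(informative)))) {
    stop("informative must be a named coefficient vector", call. = FALSE)
  }
  k <- length(informative)
  if (n_descriptors < k) {
    stop("n_descriptors must be >= number of informative descriptors",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  rng <- .seeded_rng(seed)
  n <- n_compounds
  inf_names <- names(informative)
  X_inf <- matrix(rng$rnorm(n * k), n, k)
  n_nuis <- n_descriptors - k
  n_binary <- min(n_binary, n_nuis)
  n_gauss <- n_nuis - n_binary
  X_nuis <- NULL
  if (n_gauss > 0) {
    # equicorrelated block: common factor + idiosyncratic part
    common <- rng$rnorm(n)
    X_nuis <- sqrt(abs(rho)) * matrix(common, n, n_gauss) +
      sqrt(1 - abs(rho)) * matrix(rng$rnorm(n * n_gauss), n, n_gauss)
  }
  X_bin <- if (n_binary > 0) {
    matrix(rng$rbinom(n * n_binary, 1L, 0.5), n, n_binary)
  } else NULL
  X <- cbind(X_inf, X_nuis, X_bin)
  nuis_names <- if (n_nuis > 0) sprintf("nd%03d", seq_len(n_nuis)) else character(0)
  colnames(X) <- c(inf_names, nuis_names)
  ids <- sprintf("c%03d", seq_len(n))
  y <- as.numeric(X_inf %*% unname(informative)) + intercept
  if (noise_sd > 0) y <- y + rng$rnorm(n, sd = noise_sd)
  list(table = descriptor_table(X, compound_ids = ids),
       y = y,
       truth = list(informative = informative, intercept = intercept,
                    noise_sd = noise_sd, rho = rho, seed = as.integer(seed)))
}

#' Generate classification data from a two-level threshold rule
#'
#' Draws two descriptor columns and assigns classes exactly by the rule
#' `d1 <= t1 -> active; else d2 > t2 -> active, else inactive` (the shape
#' of a two-node antimicrobial classification tree). Every generated point
#' keeps at least `margin` distance from both thresholds, so a
#' margin-positive dataset is perfectly separable by the rule.
#'
#' @param n number of compounds.
#' @param rule list with `d1`, `t1`, `d2`, `t2` (descriptor names and
#'   thresholds).
#' @param margin minimum distance of any generated value from its
#'   threshold (`>= 0`).
#' @param class_balance target proportion of actives (default 7/11, the
#'   canonical small-panel imbalance).
#' @param spread half-width of the uniform band around each threshold from
#'   which values are drawn (must exceed `margin`).
#' @param seed integer seed.
#' @return A list: `table` ([descriptor_table()]), `classes` (character
#'   vector), `rule`.
#' @export
gen_classification <- function(n, rule = list(d1 = "X4sol", t1 = 7.564,
                                              d2 = "VR2_Dzi", t2 = 11.729),
                               margin = 0.2, class_balance = 7 / 11,
                               spread = 2, seed = 20260417L) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  if (spread <= margin) stop("spread must exceed margin", call. = FALSE)
  rng <- .seeded_rng(seed)
  n_active <- round(n * class_balance)
  if (n_active < 1L || n_active > n - 1L) {
    stop("class_balance incompatible with n", call. = FALSE)
  }
  # draw a value at distance in [margin, spread] on the chosen side
  draw <- function(m, thr, below) {
    offs <- rng$runif(m, margin, spread)
    if (below) thr - offs else thr + offs
  }
  # actives split between the two active leaves; inactives take one leaf
  n_a1 <- ceiling(n_active / 2)          # d1 <= t1 leaf
  n_a2 <- n_active - n_a1                # d1 > t1, d2 > t2 leaf
  n_i <- n - n_active                    # d1 > t1, d2 <= t2 leaf
  d1 <- c(draw(n_a1, rule$t1, TRUE), draw(n_a2, rule$t1, FALSE),
          draw(n_i, rule$t1, FALSE))
  # for the d1 <= t1 leaf d2 is irrelevant; straddle the threshold so no
  # single d2 split can separate the classes by itself
  offs_a1 <- rng$runif(n_a1, margin, spread)
  side_a1 <- rng$runif(n_a1) < 0.5
  d2 <- c(ifelse(side_a1, rule$t2 - offs_a1, rule$t2 + offs_a1),
          draw(n_a2, rule$t2, FALSE),
          draw(n_i, rule$t2, TRUE))
  X <- cbind(d1, d2)
  colnames(X) <- c(rule$d1, rule$d2)
  classes <- c(rep("active", n_active), rep("inactive", n_i))
  perm <- rng$sample_int(n)
  X <- X[perm, , drop = FALSE]
  classes <- classes[perm]
  list(table = descriptor_table(X, compound_ids = sprintf("c%03d", seq_len(n))),
       classes = classes, rule = rule, seed = as.integer(seed))
}

#' Generate a two-fold dilution assay series with known IC50
#'
#' Produces a strictly descending two-fold concentration ladder and percent
#' inhibition responses from a monotone saturating log-logistic curve that
#' passes through 50 percent exactly at `true_ic50`, plus optional seeded
#' Gaussian noise.
#'
#' @param true_ic50 true half-maximal concentration (same unit as
#'   `top_conc`).
#' @param top_conc highest tested concentration (> 0).
#' @param n_dilutions number of two-fold steps (>= 2).
#' @param noise_sd response noise standard deviation (percent units).
#' @param hill Hill slope of the generating curve (default 1.5).
#' @param seed integer seed.
#' @return A [dilution_series()]; the truth is attached as attribute
#'   `true_ic50`.
#' @export
gen_assay <- function(true_ic50, top_conc, n_dilutions = 8L, noise_sd = 0,
                      hill = 1.5, seed = 20260417L) {
  if (top_conc <= 0 || true_ic50 <= 0) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (n_dilutions < 2L) stop("need at least 2 dilutions", call. = FALSE)
  conc <- top_conc / 2^(seq_len(n_dilutions) - 1L)
  resp <- 100 / (1 + (true_ic50 / conc)^hill)
  if (noise_sd > 0) {
    rng <- .seeded_rng(seed)
    resp <- resp + rng$rnorm(n_dilutions, sd = noise_sd)
  }
  out <- dilution_series(conc, resp)
  attr(out, "true_ic50") <- true_ic50
  out
}
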