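#' Pipeline configuration
#'
#' Bundles the tunable parameters of the modeling pipeline with validated
#' defaults: the seed recorded in every report, cross-validation folds,
#' Y-randomization repetitions, stepwise entry/removal thresholds, the
#' descriptor intercorrelation cutoff, the tree minimum leaf size, and
#' report rounding.
#'
#' @param seed integer RNG seed (default 20260417).
#' @param cv_folds folds for k-fold CV (>= 2, default 5).
#' @param y_randomization_reps permutations for the scrambling test
#'   (default 10).
#' @param alpha_enter,alpha_remove stepwise thresholds,
#'   `0 < alpha_enter <= alpha_remove < 1`.
#' @param intercorrelation_cutoff maximum tolerated pairwise `|r|`
#'   (default 0.9).
#' @param tree_min_leaf minimum rows per tree leaf (default 2).
#' @param rounding decimals used when printing report statistics.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 20260417L, cv_folds = 5L,
                            y_randomization_reps = 10L,
                            alpha_enter = 0.05, alpha_remove = 0.10,
                            intercorrelation_cutoff = 0.9,
                            tree_min_leaf = 2L, rounding = 4L) {
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (y_randomization_reps < 0L) stop("y_randomization_reps must be >= 0",
                                      call. = FALSE)
  if (!(alpha_enter > 0 && alpha_enter <= alpha_remove && alpha_remove < 1)) {
    stop("need 0 < alpha_enter <= alpha_remove < 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), cv_folds = as.integer(cv_folds),
                 y_randomization_reps = as.integer(y_randomization_reps),
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove,
                 intercorrelation_cutoff = intercorrelation_cutoff,
                 tree_min_leaf = as.integer(tree_min_leaf),
                 rounding = as.integer(rounding)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Paths to bundled example data
#'
#' * `"activity"` — the experimental endpoint table of the eleven
#'   quinoline-sulfonamide compounds (percent DPPH inhibition at 300 ug/ml,
#'   superoxide-scavenging IC50 in uM, molecular weight, and per-organism
#'   MIC records in ug/ml with `"<="` marking censored bounds).
#' * `"tree_descriptors"` — a synthetic stand-in for the two
#'   classification descriptors (X4sol, VR2_Dzi) of the same panel. The
#'   true per-compound values are not published; these values are invented
#'   but consistent with the published ordering of every compound relative
#'   to the two tree cutoffs, so the reference tree routes each compound to
#'   its published leaf.
#'
#' @param which `"activity"` or `"tree_descriptors"`.
#' @return File path inside the installed package.
#' @export
qsarpipe_example <- function(which = c("activity", "tree_descriptors")) {
  which <- match.arg(which)
  fname <- switch(which,
                  activity = "quinoline_sulfonamide_activity.csv",
                  tree_descriptors = "tree_descriptors_synthetic.csv")
  system.file("extdata", fname, package = "qsarpipe", mustWork = TRUE)
}
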