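#' Construct an activity table
#'
#' Per-compound experimental endpoints for a compound panel: percent
#' radical-scavenging (DPPH) at a fixed test concentration, superoxide
#' scavenging IC50 in micromolar, per-organism minimum inhibitory
#' concentrations (MIC, ug/ml), and molecular weight. The pIC50 and the
#' binary antimicrobial class (active iff any MIC record exists) are derived
#' on construction.
#'
#' @param compound_id character vector of unique compound labels.
#' @param dpph_percent numeric, percent inhibition; `NA` if not measured.
#' @param sod_ic50 numeric, IC50 in uM (> 0); `NA` if not determined.
#' @param mw numeric molecular weight, g/mol (> 0).
#' @param mic_records named list, one element per compound: a named numeric
#'   vector of MIC values in ug/ml keyed by organism label (may be empty).
#' @param mic_censored named list parallel to `mic_records`: logical vectors
#'   marking "<=" censored bounds (value is an upper bound, not an exact MIC).
#' @return An object of class `activity_table`.
#' @export
activity_table <- function(compound_id, dpph_percent = NA_real_,
                           sod_ic50 = NA_real_, mw,
                           mic_records = NULL, mic_censored = NULL) {
  compound_id <- as.character(compound_id)
  n <- length(compound_id)
  if (anyDuplicated(compound_id)) {
    stop("duplicated compound id(s) in activity table", call. = FALSE)
  }
  dpph_percent <- rep_len(as.numeric(dpph_percent), n)
  sod_ic50 <- rep_len(as.numeric(sod_ic50), n)
  mw <- rep_len(as.numeric(mw), n)
  if (any(!is.na(sod_ic50) & sod_ic50 <= 0)) {
    stop("sod_ic50 must be > 0 when present", call. = FALSE)
  }
  if (any(is.na(mw) | mw <= 0)) stop("mw must be > 0", call. = FALSE)
  if (is.null(mic_records)) {
    mic_records <- rep(list(stats::setNames(numeric(0), character(0))), n)
  }
  if (is.null(mic_censored)) {
    mic_censored <- lapply(mic_records, function(m) rep(FALSE, length(m)))
  }
  stopifnot(length(mic_records) == n, length(mic_censored) == n)
  for (i in seq_len(n)) {
    m <- mic_records[[i]]
    if (length(m) && any(m <= 0)) {
      stop("MIC values must be > 0 (compound ", compound_id[i], ")",
           call. = FALSE)
    }
  }
  names(mic_records) <- compound_id
  names(mic_censored) <- compound_id
  structure(
    list(compound_id = compound_id,
         dpph_percent = dpph_percent,
         sod_ic50 = sod_ic50,
         sod_pic50 = {
           p <- rep(NA_real_, n)
           ok <- !is.na(sod_ic50)
           if (any(ok)) p[ok] <- pic50_from_micromolar(sod_ic50[ok])
           p
         },
         mw = mw,
         mic_records = mic_records,
         mic_censored = mic_censored,
         antimicrobial_class = vapply(mic_records, function(m) {
           if (length(m) > 0L) "active" else "inactive"
         }, character(1))),
    class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  n_act <- sum(x$antimicrobial_class == "active")
  cat(sprintf(
    "Activity table: %d compounds (%d antimicrobial-active, %d inactive)\n",
    length(x$compound_id), n_act, length(x$compound_id) - n_act))
  df <- data.frame(compound_id = x$compound_id,
                   dpph_percent = x$dpph_percent,
                   sod_ic50 = x$sod_ic50,
                   sod_pic50 = round(x$sod_pic50, 3),
                   mw = x$mw,
                   n_mic = vapply(x$mic_records, length, integer(1)),
                   class = x$antimicrobial_class)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read an activity table from CSV
#'
#' Expected columns: `compound_id`, then any of `dpph_percent`,
#' `sod_ic50_uM`, `mw`, followed by one MIC column per organism (ug/ml).
#' Empty MIC cells mean no inhibition observed for that organism; a cell
#' prefixed `"<="` stores the bound with a censor flag.
#'
#' @param path path to a CSV file.
#' @param mic_columns optional character vector naming the MIC columns;
#'   defaults to every column not among the known endpoint columns.
#' @return An [activity_table()].
#' @export
read_activity_table <- function(path, mic_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (!"compound_id" %in% colnames(raw)) {
    stop("activity CSV must have a 'compound_id' column", call. = FALSE)
  }
  known <- c("compound_id", "dpph_percent", "sod_ic50_uM", "mw")
  if (is.null(mic_columns)) mic_columns <- setdiff(colnames(raw), known)
  num_col <- function(nm) {
    if (!nm %in% colnames(raw)) return(rep(NA_real_, nrow(raw)))
    v <- trimws(raw[[nm]])
    out <- suppressWarnings(as.numeric(v))
    out[!nzchar(v)] <- NA_real_
    out
  }
  n <- nrow(raw)
  mic_records <- vector("list", n)
  mic_censored <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- numeric(0); cens <- logical(0); orgs <- character(0)
    for (org in mic_columns) {
      cell <- trimws(raw[[org]][i])
      if (!nzchar(cell)) next
      is_cens <- startsWith(cell, "<=")
      num <- suppressWarnings(as.numeric(sub("^<=", "", cell)))
      if (is.na(num)) {
        stop(sprintf("unparseable MIC cell '%s' (row %d, column '%s')",
                     cell, i, org), call. = FALSE)
      }
      vals <- c(vals, num); cens <- c(cens, is_cens); orgs <- c(orgs, org)
    }
    mic_records[[i]] <- stats::setNames(vals, orgs)
    mic_censored[[i]] <- stats::setNames(cens, orgs)
  }
  activity_table(compound_id = raw[["compound_id"]],
                 dpph_percent = num_col("dpph_percent"),
                 sod_ic50 = num_col("sod_ic50_uM"),
                 mw = num_col("mw"),
                 mic_records = mic_records,
                 mic_censored = mic_censored)
}

#' Assemble a modeling dataset from descriptor and activity tables
#'
#' Joins on compound id and keeps only the compounds with a defined value of
#' the requested endpoint (compounds with an inactive or undetermined
#' endpoint are excluded from regression modeling, never imputed). Row order
#' follows the descriptor table.
#'
#' @param desc a [descriptor_table()].
#' @param act an [activity_table()].
#' @param response one of `"dpph_percent"`, `"sod_pic50"`, `"sod_ic50"`.
#' @return A list with elements `X` (numeric matrix), `y` (numeric vector)
#'   and `ids` (character vector), rows aligned.
#' @export
join_tables <- function(desc, act,
                        response = c("dpph_percent", "sod_pic50", "sod_ic50")) {
  stopifnot(inherits(desc, "descriptor_table"), inherits(act, "activity_table"))
  response <- match.arg(response)
  common <- intersect(rownames(desc), act$compound_id)
  if (length(common) == 0L) {
    stop("no compound ids shared between descriptor and activity tables",
         call. = FALSE)
  }
  idx <- match(common, act$compound_id)
  y_all <- act[[response]][idx]
  keep <- !is.na(y_all)
  if (!any(keep)) {
    stop("no compound has a defined value for endpoint '", response, "'",
         call. = FALSE)
  }
  ids <- common[keep]
  list(X = unclass(desc)[ids, , drop = FALSE], y = y_all[keep], ids = ids)
}
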