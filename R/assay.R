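#' Percent inhibition from paired absorbances
#'
#' Reduces a sample/control absorbance pair to percent inhibition,
#' `(1 - Abs_sample / Abs_control) * 100`. Used both for DPPH radical
#' scavenging and for superoxide (SOD-mimic) scavenging readings. Negative
#' values (pro-oxidant readings, sample absorbs more than control) are
#' returned as measured, with a warning.
#'
#' @param abs_sample absorbance of the test reaction (>= 0).
#' @param abs_control absorbance of the control reaction (> 0).
#' @return Percent inhibition (vectorized).
#' @export
percent_inhibition <- function(abs_sample, abs_control) {
  if (any(abs_control <= 0)) {
    stop("abs_control must be > 0", call. = FALSE)
  }
  if (any(abs_sample < 0)) stop("abs_sample must be >= 0", call. = FALSE)
  out <- (1 - abs_sample / abs_control) * 100
  if (any(out < 0)) {
    warning("negative percent inhibition (pro-oxidant reading) retained")
  }
  out
}

#' Build a two-fold dilution series
#'
#' @param concentrations strictly decreasing positive concentrations
#'   (two-fold steps by assay design; the constructor only enforces strict
#'   decrease).
#' @param responses percent inhibition at each concentration.
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(concentrations, responses) {
  if (length(concentrations) != length(responses) || length(responses) < 2L) {
    stop("concentrations and responses must have equal length >= 2",
         call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (any(diff(concentrations) >= 0)) {
    stop("concentrations must be strictly decreasing", call. = FALSE)
  }
  structure(list(concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses)),
            class = "dilution_series")
}

#' IC50 from a dilution series
#'
#' Determines the half-maximal inhibitory concentration from percent
#' inhibition measured along a two-fold dilution series. If no response
#' reaches 50 percent the IC50 is undefined (returned as `NA` with attribute
#' `defined = FALSE`), matching the convention of reporting no IC50 for
#' compounds below half-maximal activity at the top test concentration. An
#' exact 50 percent response returns its concentration. Otherwise the
#' crossing is located by linear interpolation of response against
#' log2(concentration) between the lowest concentration with response >= 50
#' and the next dilution below it. If every response is >= 50 the lowest
#' tested concentration is returned with attribute `censored = "<="` (the
#' true IC50 lies at or below it).
#'
#' @param series a [dilution_series()].
#' @return IC50 in the series' concentration unit, with attributes
#'   `defined` (logical) and possibly `censored`.
#' @export
ic50_from_series <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  conc <- series$concentrations
  resp <- series$responses
  if (max(resp) < 50) {
    return(structure(NA_real_, defined = FALSE))
  }
  exact <- which(resp == 50)
  if (length(exact)) {
    # lowest concentration hitting 50 exactly
    return(structure(conc[max(exact)], defined = TRUE))
  }
  # lowest concentration whose response is still >= 50
  ge <- which(resp >= 50)
  i_hi <- max(ge)
  if (i_hi == length(conc)) {
    return(structure(conc[length(conc)], defined = TRUE, censored = "<="))
  }
  i_lo <- i_hi + 1L
  lc_hi <- log2(conc[i_hi]); lc_lo <- log2(conc[i_lo])
  w <- (50 - resp[i_lo]) / (resp[i_hi] - resp[i_lo])
  structure(2^(lc_lo + w * (lc_hi - lc_lo)), defined = TRUE)
}

#' pIC50 from an IC50 in micromolar
#'
#' `pIC50 = -log10(IC50 in molar) = 6 - log10(IC50 in uM)`. Higher pIC50
#' means higher potency.
#'
#' @param ic50 IC50 in uM (> 0), vectorized.
#' @return pIC50 (dimensionless, molar basis).
#' @export
pic50_from_micromolar <- function(ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0)) {
    stop("ic50 must be finite and > 0", call. = FALSE)
  }
  6 - log10(ic50)
}

#' Convert an MIC from ug/ml to micromolar
#'
#' `MIC[uM] = MIC[ug/ml] / MW[g/mol] * 1000`.
#'
#' @param mic MIC in ug/ml (> 0), vectorized.
#' @param mw molecular weight in g/mol (> 0).
#' @return MIC in uM.
#' @export
mic_to_micromolar <- function(mic, mw) {
  if (any(mic <= 0) || any(mw <= 0)) {
    stop("mic and mw must be > 0", call. = FALSE)
  }
  mic / mw * 1000
}

#' Antimicrobial class from MIC records
#'
#' A compound is classed `"active"` iff it has at least one recorded MIC
#' against any tested organism, and `"inactive"` otherwise (no growth
#' inhibition at the highest tested concentration).
#'
#' @param act an [activity_table()].
#' @return Character vector of `"active"`/`"inactive"`, named by compound id.
#' @export
classify_antimicrobial <- function(act) {
  stopifnot(inherits(act, "activity_table"))
  stats::setNames(act$antimicrobial_class, act$compound_id)
}
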