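## Per-image multi-point calibration and the semi-quantitative readout:
## g maps measured intensity to the standardized signal scale of the
## printed reference ladder, the concentration model maps standardized
## signals to ng/mL, and the classifier bins the estimate into the three
## clinical categories.

#' Fit the intensity-to-signal calibration curve
#'
#' Ordinary least squares of the nominal signals \eqn{R_k} on a degree-1
#' or degree-2 polynomial in the measured intensities \eqn{I_k}, using
#' only the non-outlier ladder points. The fitted curve must be strictly
#' increasing over the intensity range of the ladder (an inverted ladder
#' is rejected).
#'
#' @param ladder a [ReferenceLadder-class].
#' @param degree 1 (default) or 2.
#' @return A [CalibrationCurve-class].
#' @examples
#' lad <- buildLadder(c(0.1, 0.2, 0.4, 0.6, 0.8), c(10, 20, 40, 60, 80))
#' fitCalibration(lad)
#' @export
fitCalibration <- function(ladder, degree = 1L) {
  stopifnot(is(ladder, "ReferenceLadder"), degree %in% c(1L, 2L))
  keep <- !ladder@outlier
  I <- ladder@intensity[keep]
  R <- ladder@nominal[keep]
  if (length(I) < degree + 1L)
    stop("ladder unusable: not enough surviving points for the requested degree")
  X <- if (degree == 1L) cbind(1, I) else cbind(1, I, I^2)
  fit <- stats::lm.fit(X, R)
  if (fit$rank < ncol(X))
    stop("ladder unusable: rank-deficient design")
  cf <- fit$coefficients
  a0 <- cf[1]; a1 <- cf[2]; a2 <- if (degree == 2L) cf[3] else 0
  rng <- range(I)
  ## derivative a1 + 2 a2 I is linear in I: checking the endpoints suffices
  if (min(a1 + 2 * a2 * rng) <= 0)
    stop("calibration curve is not strictly increasing over the ladder range")
  new("CalibrationCurve", a0 = unname(a0), a1 = unname(a1), a2 = unname(a2),
      residRMS = sqrt(mean(fit$residuals^2)), iRange = rng)
}

#' Evaluate a calibration curve
#'
#' @param curve a [CalibrationCurve-class].
#' @param I measured intensity (vectorized).
#' @return Standardized signal \eqn{S = g(I)}.
#' @export
evalCalibration <- function(curve, I) {
  curve@a0 + curve@a1 * I + curve@a2 * I^2
}

#' Standardize the test- and control-line intensities
#'
#' Maps the raw background-corrected line intensities through the
#' per-image calibration: \eqn{S_T = g(I_T)}, \eqn{S_C = g(I_C)}, and the
#' control-normalized ratio \eqn{S_{T|C} = S_T / S_C}. A non-positive
#' control signal invalidates the strip (no flow / insufficient
#' reaction).
#'
#' @param curve a [CalibrationCurve-class].
#' @param iT,iC background-corrected T and C intensities (must be >= 0).
#' @return A list of class `"StandardizedSignals"`: `sT`, `sC`, `sTC`.
#' @export
standardize <- function(curve, iT, iC) {
  stopifnot(iT >= 0, iC >= 0)
  sT <- evalCalibration(curve, iT)
  sC <- evalCalibration(curve, iC)
  if (sC <= 0) stop("control signal invalid: S_C <= 0")
  structure(list(sT = sT, sC = sC, sTC = sT / sC),
            class = "StandardizedSignals")
}

#' Fit the signal-to-concentration regression
#'
#' Least squares of known concentration on the standardized test-line
#' signal (`mode = "ST"`) or on the control-normalized ratio
#' (`mode = "ST_over_SC"`, default), from a reference panel.
#'
#' @param signals list of `"StandardizedSignals"` (or a data.frame with
#'   columns `sT` and `sTC`).
#' @param conc known concentrations (ng/mL), same length.
#' @param mode `"ST_over_SC"` (default) or `"ST"`.
#' @param rangeLow,rangeHigh reportable range bounds (ng/mL).
#' @return A [ConcentrationModel-class].
#' @export
fitConcentrationModel <- function(signals, conc, mode = c("ST_over_SC", "ST"),
                                  rangeLow = 5, rangeHigh = 100) {
  mode <- match.arg(mode)
  if (is.data.frame(signals)) {
    x <- if (mode == "ST") signals$sT else signals$sTC
  } else {
    x <- vapply(signals, function(s) if (mode == "ST") s$sT else s$sTC,
                numeric(1))
  }
  stopifnot(length(x) == length(conc))
  if (length(x) < 3L) stop("need at least 3 reference samples")
  if (length(unique(conc)) < 2L || stats::var(x) <= 0)
    stop("zero variance in predictor: cannot fit concentration model")
  fit <- stats::lm.fit(cbind(1, x), conc)
  new("ConcentrationModel", mode = mode,
      alpha = unname(fit$coefficients[2]), beta = unname(fit$coefficients[1]),
      rangeLow = rangeLow, rangeHigh = rangeHigh,
      residRMS = sqrt(mean(fit$residuals^2)))
}

#' Clinical three-level classification of a concentration
#'
#' Level 1 (deficient) below 20 ng/mL, level 2 (insufficient) on the
#' closed interval 20–30 ng/mL, level 3 (sufficient) above 30 ng/mL.
#'
#' @param conc concentration in ng/mL (vectorized).
#' @return Integer level(s) 1, 2 or 3.
#' @export
classifyLevel <- function(conc) {
  ifelse(conc < 20, 1L, ifelse(conc <= 30, 2L, 3L))
}

.LEVEL_LABELS <- c("deficient", "insufficient", "sufficient")

#' Estimate and classify the concentration
#'
#' Applies the concentration regression to the standardized signals and
#' bins the result. Estimates below the reportable range are censored as
#' `"<5"` (level 1) and above it as `">100"` (level 3); the censored
#' marker is carried alongside, never silently clamped.
#'
#' @param model a [ConcentrationModel-class].
#' @param signals a `"StandardizedSignals"` list from [standardize()].
#' @return A list of class `"ClassifiedResult"`: `raw` (uncensored
#'   regression value), `concentration` (ng/mL, `NA` when censored),
#'   `censored` (`NA`, `"<5"` or `">100"`), `level` (1/2/3), `label`.
#' @export
estimateConcentration <- function(model, signals) {
  stopifnot(is(model, "ConcentrationModel"))
  x <- if (model@mode == "ST") signals$sT else signals$sTC
  raw <- model@alpha * x + model@beta
  if (raw < model@rangeLow) {
    res <- list(raw = raw, concentration = NA_real_,
                censored = paste0("<", model@rangeLow), level = 1L)
  } else if (raw > model@rangeHigh) {
    res <- list(raw = raw, concentration = NA_real_,
                censored = paste0(">", model@rangeHigh), level = 3L)
  } else {
    res <- list(raw = raw, concentration = raw, censored = NA_character_,
                level = classifyLevel(raw))
  }
  res$label <- .LEVEL_LABELS[res$level]
  structure(res, class = "ClassifiedResult")
}

#' @export
print.ClassifiedResult <- function(x, ...) {
  shown <- if (is.na(x$censored)) sprintf("%.2f ng/mL", x$concentration)
           else sprintf("%s ng/mL (censored)", x$censored)
  cat(sprintf("ClassifiedResult: %s -> level %d (%s)\n",
              shown, x$level, x$label))
  invisible(x)
}
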