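## End-to-end orchestration: photograph -> detection -> rectification ->
## (optional cross-device alignment) -> profile -> line measurement ->
## per-image ladder calibration -> standardized signals -> concentration
## -> clinical category, plus the method-comparison and detection-limit
## studies and JSON model serialization.

#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline: the layout,
#' QC thresholds, calibration degree, concentration-model mode, and
#' version tags. Serializable to/from YAML with [writeConfig()] /
#' [readConfig()].
#'
#' @param layout a [StripLayout-class].
#' @param concentrationModel optional [ConcentrationModel-class]; without
#'   one, [analyzeImage()] stops after signal standardization.
#' @param transform optional [PhotometricTransform-class] applied after
#'   rectification.
#' @return A named list.
#' @export
defaultConfig <- function(layout = StripLayout(),
                          concentrationModel = NULL, transform = NULL) {
  list(layout = layout,
       qc = list(overexposure_frac_max = 0.05, c_min_contrast = 0.05),
       calibration = list(degree = 1L),
       mode = "ST_over_SC",
       concentrationModel = concentrationModel,
       transform = transform,
       modelVersion = "lfareader-1",
       calibrationVersion = "cal-1")
}

## Run one stage, rethrowing errors tagged with the stage name.
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Analyze one strip photograph end to end
#'
#' Runs detection, rectification, optional photometric alignment, QC,
#' line measurement, per-image ladder calibration, signal
#' standardization, and (when the config carries a concentration model)
#' concentration estimation and classification. A QC failure
#' (insufficient reaction) short-circuits: the record carries the flags
#' and no concentration.
#'
#' @param input a file path (PNG) or a [StripImage-class]; a
#'   [RectifiedStrip-class] skips detection.
#' @param config list from [defaultConfig()].
#' @param detect set `FALSE` when `input` is already a canonical-frame
#'   image (it is then linearized and wrapped as rectified directly).
#' @return A list of class `"AnalysisRecord"`: `inputPath`, `corners`,
#'   `qc`, `measurements`, `ladder`, `calibration`, `signals`, `result`,
#'   `modelVersion`, `calibrationVersion`, `timestamp`.
#' @export
analyzeImage <- function(input, config = defaultConfig(), detect = TRUE) {
  layout <- config$layout
  inputPath <- NA_character_
  if (is.character(input)) {
    inputPath <- input
    input <- withStage("read", readStripImage(input))
  }
  if (is(input, "RectifiedStrip")) {
    rs <- input
    corners <- NULL
  } else if (!detect) {
    rs <- asRectified(input)
    corners <- canonicalCorners(layout)
  } else {
    corners <- withStage("detect", detectStrip(input))
    rs <- withStage("rectify", rectify(input, corners, layout))
  }
  if (!is.null(config$transform))
    rs <- withStage("align", alignImage(rs, config$transform))
  qc <- withStage("qc", qcCheck(rs, layout,
                                cMinContrast = config$qc$c_min_contrast,
                                overexposureFracMax = config$qc$overexposure_frac_max))
  rec <- list(inputPath = inputPath, corners = corners, qc = qc,
              measurements = NULL, ladder = NULL, calibration = NULL,
              signals = NULL, result = NULL,
              modelVersion = config$modelVersion,
              calibrationVersion = config$calibrationVersion,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(rec) <- "AnalysisRecord"
  if ("insufficient reaction" %in% qc$flags) return(rec)
  meas <- withStage("measure", measureStrip(rs, layout))
  rec$measurements <- meas
  ladder <- withStage("ladder", buildLadder(
    meas[paste0("ref", 1:5), "intensity"], layout@nominalSignals))
  rec$ladder <- ladder
  curve <- withStage("calibrate", fitCalibration(ladder,
                                                 config$calibration$degree))
  rec$calibration <- curve
  rec$signals <- withStage("standardize", standardize(
    curve, meas["T", "intensity"], meas["C", "intensity"]))
  if (!is.null(config$concentrationModel)) {
    rec$result <- withStage("estimate", estimateConcentration(
      config$concentrationModel, rec$signals))
  }
  rec
}

#' @export
print.AnalysisRecord <- function(x, ...) {
  cat("AnalysisRecord",
      if (!is.na(x$inputPath)) paste0("(", x$inputPath, ")"), "\n")
  print(x$qc)
  if (!is.null(x$signals))
    cat(sprintf("  S_T = %.3f, S_C = %.3f, S_T/S_C = %.4f\n",
                x$signals$sT, x$signals$sC, x$signals$sTC))
  if (!is.null(x$result)) print(x$result)
  invisible(x)
}

#' Fit the concentration model from a synthetic reference panel
#'
#' Analyzes every panel image up to signal standardization and regresses
#' the known concentrations on the standardized signals — the reference-
#' material calibration step a kit lot undergoes before deployment.
#'
#' @param panel list of `list(image, truth)` from
#'   [generateValidationPanel()] (or [renderStrip()]).
#' @param config pipeline config (its `concentrationModel` is ignored).
#' @param mode `"ST_over_SC"` (default) or `"ST"`.
#' @param detect `FALSE` (default) when the panel images are canonical
#'   frames; `TRUE` to run detection on posed photographs.
#' @return A [ConcentrationModel-class].
#' @export
fitConcentrationFromPanel <- function(panel, config = defaultConfig(),
                                      mode = c("ST_over_SC", "ST"),
                                      detect = FALSE) {
  mode <- match.arg(mode)
  recs <- lapply(panel, function(p) analyzeImage(p$image, config, detect))
  sig <- lapply(recs, `[[`, "signals")
  conc <- vapply(panel, function(p) p$truth$concentration, numeric(1))
  ok <- !vapply(sig, is.null, logical(1))
  fitConcentrationModel(sig[ok], conc[ok], mode)
}

#' Method-comparison study from paired calls
#'
#' Cross-classifies the strip reader's categorical calls against
#' reference-method concentrations (binned with the same 20/30 ng/mL
#' thresholds) and computes the full agreement report. Malformed rows
#' (missing values, levels outside 1–3) are skipped with a message.
#'
#' @param records a data.frame with columns `candidate_level` and
#'   `reference_conc`, or a path to such a CSV.
#' @param conf confidence level for the Wilson intervals.
#' @return An `"AgreementReport"` (see [agreementReport()]).
#' @export
runMethodComparison <- function(records, conf = 0.95) {
  if (is.character(records)) records <- utils::read.csv(records)
  stopifnot(all(c("candidate_level", "reference_conc") %in% names(records)))
  ok <- !is.na(records$candidate_level) & !is.na(records$reference_conc) &
        records$candidate_level %in% 1:3 & records$reference_conc >= 0
  if (any(!ok))
    message(sum(!ok), " malformed row(s) skipped")
  if (!any(ok)) stop("no valid record pairs")
  tab <- contingencyFromCalls(records$candidate_level[ok],
                              records$reference_conc[ok])
  agreementReport(tab, conf)
}

#' Synthetic detection-limit study
#'
#' Renders replicate blank and low-level strips, runs the full readout on
#' each, and computes LoB and LoD from the uncensored concentration
#' estimates per CLSI EP17-A2 (blank replicates give the LoB; low-level
#' replicates give the LoD).
#'
#' @param cmodel the deployed [ConcentrationModel-class].
#' @param layout,dr,device generator settings.
#' @param nBlank,nLow replicate counts (default 20 each).
#' @param lowConc low-level concentration (ng/mL, default 5).
#' @param seed base seed; replicate i uses `seed + i`.
#' @param config pipeline config (layout should match).
#' @return A `"DetectionLimits"` list with the raw estimate vectors
#'   attached as attributes `blanks` and `lows`.
#' @export
lodStudy <- function(cmodel, layout = StripLayout(), dr = DoseResponse(),
                     device = DeviceModel(), nBlank = 20L, nLow = 20L,
                     lowConc = 5, seed = 1L,
                     config = defaultConfig(layout, cmodel)) {
  estimateAt <- function(conc, seeds) {
    vapply(seeds, function(s) {
      img <- renderStrip(layout, conc, dr, device, seed = s)$image
      analyzeImage(img, config, detect = FALSE)$result$raw
    }, numeric(1))
  }
  blanks <- estimateAt(0, seed + seq_len(nBlank))
  lows <- estimateAt(lowConc, seed + nBlank + seq_len(nLow))
  dl <- limitOfDetection(limitOfBlank(blanks), lowReplicates = lows)
  attr(dl, "blanks") <- blanks
  attr(dl, "lows") <- lows
  dl
}

## ---- serialization ---------------------------------------------------

#' Serialize / restore calibration objects as JSON
#'
#' Writes a [CalibrationCurve-class], [ConcentrationModel-class] or
#' [PhotometricTransform-class] as tagged JSON carrying `model_version`
#' and `calibration_version` for traceability; `readModelJSON` restores
#' the object from the tag.
#'
#' @param object the object to serialize.
#' @param path output / input file path.
#' @param modelVersion,calibrationVersion version tags.
#' @return `writeModelJSON` returns `path` invisibly; `readModelJSON`
#'   returns the restored object with the version tags as attributes.
#' @export
writeModelJSON <- function(object, path, modelVersion = "lfareader-1",
                           calibrationVersion = "cal-1") {
  payload <- if (is(object, "CalibrationCurve")) {
    list(type = "CalibrationCurve", a0 = object@a0, a1 = object@a1,
         a2 = object@a2, resid_rms = object@residRMS,
         i_range = object@iRange)
  } else if (is(object, "ConcentrationModel")) {
    list(type = "ConcentrationModel", mode = object@mode,
         alpha = object@alpha, beta = object@beta,
         range_low = object@rangeLow, range_high = object@rangeHigh,
         resid_rms = object@residRMS)
  } else if (is(object, "PhotometricTransform")) {
    list(type = "PhotometricTransform", gamma = object@gamma,
         wb_gains = object@wbGains, shading_coeffs = object@shadingCoeffs,
         ccm = object@ccm, intensity_scale = object@intensityScale)
  } else stop("unsupported object type")
  payload$model_version <- modelVersion
  payload$calibration_version <- calibrationVersion
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- switch(p$type,
    CalibrationCurve = new("CalibrationCurve", a0 = p$a0, a1 = p$a1,
                           a2 = p$a2, residRMS = p$resid_rms,
                           iRange = p$i_range),
    ConcentrationModel = new("ConcentrationModel", mode = p$mode,
                             alpha = p$alpha, beta = p$beta,
                             rangeLow = p$range_low, rangeHigh = p$range_high,
                             residRMS = p$resid_rms),
    PhotometricTransform = new("PhotometricTransform", gamma = p$gamma,
                               wbGains = p$wb_gains,
                               shadingCoeffs = p$shading_coeffs,
                               ccm = as.matrix(p$ccm),
                               intensityScale = p$intensity_scale),
    stop("unknown model type in ", path))
  attr(obj, "modelVersion") <- p$model_version
  attr(obj, "calibrationVersion") <- p$calibration_version
  obj
}

#' Write / read the pipeline configuration as YAML
#'
#' Numeric configuration only; the layout and any fitted models are
#' stored inline (models as their JSON payloads).
#'
#' @param config list from [defaultConfig()].
#' @param path YAML file path.
#' @return `readConfig` returns the config list.
#' @export
writeConfig <- function(config, path) {
  lay <- config$layout
  out <- list(
    layout = list(width = lay@width, height = lay@height,
                  line_centers = as.list(lay@lineCenters),
                  line_width_frac = lay@lineWidthFrac,
                  neutral_zone = lay@neutralZone,
                  nominal_signals = lay@nominalSignals),
    qc = config$qc,
    calibration = config$calibration,
    mode = config$mode,
    model_version = config$modelVersion,
    calibration_version = config$calibrationVersion)
  if (!is.null(config$concentrationModel)) {
    cm <- config$concentrationModel
    out$concentration_model <- list(mode = cm@mode, alpha = cm@alpha,
                                    beta = cm@beta, range_low = cm@rangeLow,
                                    range_high = cm@rangeHigh)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  layout <- StripLayout(width = y$layout$width, height = y$layout$height,
                        lineCenters = unlist(y$layout$line_centers),
                        lineWidthFrac = y$layout$line_width_frac,
                        neutralZone = unlist(y$layout$neutral_zone),
                        nominalSignals = unlist(y$layout$nominal_signals))
  cm <- NULL
  if (!is.null(y$concentration_model)) {
    q <- y$concentration_model
    cm <- new("ConcentrationModel", mode = q$mode, alpha = q$alpha,
              beta = q$beta, rangeLow = q$range_low, rangeHigh = q$range_high,
              residRMS = NA_real_)
  }
  cfg <- defaultConfig(layout, cm)
  cfg$qc <- y$qc
  cfg$calibration <- y$calibration
  cfg$mode <- y$mode
  cfg$modelVersion <- y$model_version
  cfg$calibrationVersion <- y$calibration_version
  cfg
}
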