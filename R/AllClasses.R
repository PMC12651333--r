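#' @import methods
NULL

## Coordinate convention used throughout the package: pixel arrays are
## indexed [row, col, channel], 1-based, origin at the top-left; corner
## quadrilaterals are 4x2 (row, col) matrices ordered clockwise from the
## top-left corner (TL, TR, BR, BL). Longitudinal positions run along
## columns (the strip lies horizontally in its canonical frame).

#' StripLayout: canonical cassette geometry
#'
#' Describes the canonical (rectified) strip frame: its pixel size, the
#' longitudinal positions of the control (C) line, test (T) line and the
#' five printed reference lines, the line width, the neutral (blank
#' substrate) zone used for white balance, and the nominal signal values
#' \eqn{R_k} assigned to the reference lines.
#'
#' @slot width canonical strip length in pixels (columns).
#' @slot height canonical strip height in pixels (rows).
#' @slot lineCenters named numeric vector of longitudinal line centers as
#'   fractions of the strip length, names `C`, `T`, `ref1`..`ref5`.
#' @slot lineWidthFrac line width as a fraction of the strip length.
#' @slot neutralZone numeric length-4 vector `(top, left, bottom, right)`
#'   as fractions of height/length: a rectangle of bare substrate.
#' @slot nominalSignals numeric length-5, strictly increasing nominal
#'   reference signals \eqn{R_k} (arbitrary signal units).
#' @exportClass StripLayout
setClass("StripLayout", representation(
  width = "integer", height = "integer",
  lineCenters = "numeric", lineWidthFrac = "numeric",
  neutralZone = "numeric", nominalSignals = "numeric"))

setValidity("StripLayout", function(object) {
  msg <- character()
  if (object@width < 32L || object@height < 32L)
    msg <- c(msg, "canonical frame must be at least 32x32 px")
  nm <- c("C", "T", paste0("ref", 1:5))
  if (!identical(names(object@lineCenters), nm))
    msg <- c(msg, "lineCenters must be named C, T, ref1..ref5")
  ctr <- sort(object@lineCenters)
  gap <- min(diff(ctr))
  if (object@lineWidthFrac <= 0 || object@lineWidthFrac >= gap)
    msg <- c(msg, "lineWidthFrac must be in (0, min gap between line centers)")
  ## line windows pairwise disjoint
  half <- object@lineWidthFrac / 2
  if (any(diff(ctr) <= object@lineWidthFrac))
    msg <- c(msg, "line windows overlap")
  nz <- object@neutralZone
  if (length(nz) != 4L || any(nz < 0) || any(nz > 1) || nz[1] >= nz[3] || nz[2] >= nz[4])
    msg <- c(msg, "neutralZone must be (top, left, bottom, right) fractions with top<bottom, left<right")
  ## neutral zone disjoint from every line window (longitudinally)
  if (length(nz) == 4L &&
      any(object@lineCenters + half > nz[2] & object@lineCenters - half < nz[4]))
    msg <- c(msg, "neutral zone overlaps a line window")
  rk <- object@nominalSignals
  if (length(rk) != 5L || any(diff(rk) <= 0))
    msg <- c(msg, "nominalSignals must be 5 strictly increasing values")
  if (length(msg)) msg else TRUE
})

#' DoseResponse: saturating test-line dose-response
#'
#' Langmuir-form (rectangular hyperbola) optical-density response of the
#' test line to analyte concentration:
#' \deqn{d(c) = floor + d_{max} \, c / (k_{half} + c).}
#' The gold-nanoparticle band darkens monotonically with concentration and
#' saturates at `floor + dMax`.
#'
#' @slot dMax density gain at saturation (absorbance-proxy units).
#' @slot kHalf concentration at half-saturation (ng/mL).
#' @slot floor residual density at zero analyte.
#' @exportClass DoseResponse
setClass("DoseResponse", representation(
  dMax = "numeric", kHalf = "numeric", floor = "numeric"))

setValidity("DoseResponse", function(object) {
  msg <- character()
  if (object@dMax <= 0) msg <- c(msg, "dMax must be > 0")
  if (object@kHalf <= 0) msg <- c(msg, "kHalf must be > 0")
  if (object@floor < 0) msg <- c(msg, "floor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DeviceModel: camera/device distortion model
#'
#' Photometric distortions a capture device imposes on the ideal strip
#' radiance, in the order they are applied by [renderStrip()]:
#' multiplicative shading (vignetting), 3x3 channel mixing, global
#' intensity scale, inverse white-balance tint, optional sRGB gamma
#' encoding, then additive Gaussian noise (clipped to `[0, 1]`).
#'
#' @slot wbGains three positive per-channel gains; the *inverse* gains are
#'   applied at render time (the tint a later correction must undo).
#' @slot shadingCoeffs six coefficients of a 2-D polynomial
#'   `(1, u, v, u^2, uv, v^2)` in centred normalized coordinates, defining
#'   a multiplicative field; must stay positive over the frame.
#' @slot colorMatrix invertible 3x3 channel-mixing matrix.
#' @slot intensityScale positive global scale.
#' @slot gamma `"srgb"` (encode output) or `"none"` (stay linear).
#' @slot noiseSd additive Gaussian noise standard deviation in `[0, 1]` units.
#' @exportClass DeviceModel
setClass("DeviceModel", representation(
  wbGains = "numeric", shadingCoeffs = "numeric", colorMatrix = "matrix",
  intensityScale = "numeric", gamma = "character", noiseSd = "numeric"))

setValidity("DeviceModel", function(object) {
  msg <- character()
  if (length(object@wbGains) != 3L || any(object@wbGains <= 0))
    msg <- c(msg, "wbGains must be 3 positive values")
  if (length(object@shadingCoeffs) != 6L)
    msg <- c(msg, "shadingCoeffs must have 6 coefficients (1, u, v, u^2, uv, v^2)")
  else {
    u <- rep(seq(-0.5, 0.5, length.out = 9), 9)
    v <- rep(seq(-0.5, 0.5, length.out = 9), each = 9)
    f <- cbind(1, u, v, u^2, u * v, v^2) %*% object@shadingCoeffs
    if (any(f <= 0)) msg <- c(msg, "shading field must be positive over the frame")
  }
  if (!all(dim(object@colorMatrix) == c(3L, 3L)) ||
      abs(det(object@colorMatrix)) < 1e-10)
    msg <- c(msg, "colorMatrix must be an invertible 3x3 matrix")
  if (object@intensityScale <= 0) msg <- c(msg, "intensityScale must be > 0")
  if (!object@gamma %in% c("srgb", "none"))
    msg <- c(msg, "gamma must be 'srgb' or 'none'")
  if (object@noiseSd < 0 || object@noiseSd > 1)
    msg <- c(msg, "noiseSd must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StripImage: an RGB raster with a color-space tag
#'
#' @slot pixels H x W x 3 numeric array with values in `[0, 1]`.
#' @slot colorSpace `"srgb"` (gamma-encoded) or `"linear"`.
#' @exportClass StripImage
setClass("StripImage", representation(
  pixels = "array", colorSpace = "character"))

setValidity("StripImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1] < 32L || d[2] < 32L)
    msg <- c(msg, "image must be at least 32 x 32")
  if (!object@colorSpace %in% c("srgb", "linear"))
    msg <- c(msg, "colorSpace must be 'srgb' or 'linear'")
  rng <- range(object@pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "pixel values must be finite and in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RectifiedStrip: a strip warped to the canonical frame
#'
#' A [StripImage-class] in the canonical layout frame, always in linear
#' color space, carrying the source-to-canonical homography.
#'
#' @slot homography 3x3 matrix mapping source `(x=col, y=row)` homogeneous
#'   coordinates to canonical coordinates.
#' @exportClass RectifiedStrip
setClass("RectifiedStrip", contains = "StripImage",
         representation(homography = "matrix"))

setValidity("RectifiedStrip", function(object) {
  msg <- character()
  if (!all(dim(object@homography) == c(3L, 3L)) ||
      abs(det(object@homography)) < 1e-12)
    msg <- c(msg, "homography must be an invertible 3x3 matrix")
  if (object@colorSpace != "linear")
    msg <- c(msg, "rectified strips are linear color space")
  if (length(msg)) msg else TRUE
})

#' ReferenceLadder: measured reference-line intensities vs nominal signals
#'
#' The per-image multi-point calibration ladder: measured background-
#' corrected intensities \eqn{I_k} paired with the nominal signals
#' \eqn{R_k}, plus an outlier mask from the robust residual screen.
#'
#' @slot intensity measured \eqn{I_k}, length 5.
#' @slot nominal nominal \eqn{R_k}, length 5, strictly increasing.
#' @slot outlier logical length 5; `TRUE` marks points excluded from fits.
#' @exportClass ReferenceLadder
setClass("ReferenceLadder", representation(
  intensity = "numeric", nominal = "numeric", outlier = "logical"))

setValidity("ReferenceLadder", function(object) {
  msg <- character()
  if (length(object@intensity) != length(object@nominal) ||
      length(object@outlier) != length(object@nominal))
    msg <- c(msg, "intensity, nominal and outlier must have equal length")
  if (any(diff(object@nominal) <= 0))
    msg <- c(msg, "nominal signals must be strictly increasing")
  if (sum(!object@outlier) < 2L)
    msg <- c(msg, "ladder unusable: fewer than 2 non-outlier points")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: intensity-to-signal mapping S = g(I)
#'
#' Polynomial least-squares calibration \eqn{g(I) = a_0 + a_1 I + a_2 I^2}
#' fitted from a [ReferenceLadder-class]; `a2 = 0` for the default linear
#' fit. `g` is guaranteed strictly increasing over the intensity range of
#' the ladder it was fitted on.
#'
#' @slot a0,a1,a2 polynomial coefficients.
#' @slot residRMS root-mean-square fit residual (signal units).
#' @slot iRange intensity range `(min, max)` of the ladder points used.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", representation(
  a0 = "numeric", a1 = "numeric", a2 = "numeric",
  residRMS = "numeric", iRange = "numeric"))

#' ConcentrationModel: linear signal-to-concentration regression
#'
#' Concentration (ng/mL) `= alpha * predictor + beta`, where the predictor
#' is the standardized test-line signal \eqn{S_T} (`mode = "ST"`) or the
#' control-normalized ratio \eqn{S_{T|C} = S_T / S_C}
#' (`mode = "ST_over_SC"`, the default elsewhere). Estimates outside
#' `[rangeLow, rangeHigh]` are censored, not extrapolated.
#'
#' @slot mode `"ST"` or `"ST_over_SC"`.
#' @slot alpha,beta regression coefficients.
#' @slot rangeLow,rangeHigh reportable range (ng/mL), default 5 and 100.
#' @slot residRMS root-mean-square calibration residual (ng/mL).
#' @exportClass ConcentrationModel
setClass("ConcentrationModel", representation(
  mode = "character", alpha = "numeric", beta = "numeric",
  rangeLow = "numeric", rangeHigh = "numeric", residRMS = "numeric"))

setValidity("ConcentrationModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("ST", "ST_over_SC"))
    msg <- c(msg, "mode must be 'ST' or 'ST_over_SC'")
  if (object@alpha == 0) msg <- c(msg, "alpha must be nonzero")
  if (object@rangeLow >= object@rangeHigh)
    msg <- c(msg, "rangeLow must be below rangeHigh")
  if (length(msg)) msg else TRUE
})

#' PhotometricTransform: learned cross-device alignment
#'
#' Maps captures from a source device into a reference device's linear
#' space by (i) sRGB gamma linearization, (ii) neutral-zone white-balance
#' gains, (iii) division by a fitted 2-D polynomial shading field, and
#' (iv) a 3x3 color correction matrix with a global intensity scale.
#'
#' @slot wbGains three positive white-balance gains.
#' @slot shadingCoeffs six 2-D polynomial coefficients (normalized to a
#'   mean-one field at application time).
#' @slot ccm invertible 3x3 color correction matrix.
#' @slot intensityScale positive global scale factored out of the matrix.
#' @slot gamma source encoding expected at application time (`"srgb"`).
#' @exportClass PhotometricTransform
setClass("PhotometricTransform", representation(
  wbGains = "numeric", shadingCoeffs = "numeric", ccm = "matrix",
  intensityScale = "numeric", gamma = "character"))

setValidity("PhotometricTransform", function(object) {
  msg <- character()
  if (length(object@wbGains) != 3L || any(object@wbGains <= 0))
    msg <- c(msg, "wbGains must be 3 positive values")
  if (length(object@shadingCoeffs) != 6L)
    msg <- c(msg, "shadingCoeffs must have 6 coefficients")
  if (!all(dim(object@ccm) == c(3L, 3L)) || abs(det(object@ccm)) < 1e-10)
    msg <- c(msg, "ccm must be an invertible 3x3 matrix")
  if (object@intensityScale <= 0) msg <- c(msg, "intensityScale must be > 0")
  if (length(msg)) msg else TRUE
})
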