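#' Construct a strip layout
#'
#' The default layout is a 600 x 120 px canonical strip with the control
#' line at 0.15 of the length, the test line at 0.30, five reference lines
#' at 0.50–0.90 (step 0.10), nominal reference signals
#' \eqn{R_k = (10, 20, 40, 60, 80)} signal units, a line width of 0.02 of
#' the length, and a neutral substrate zone near the far end.
#'
#' @param width,height canonical frame size in pixels.
#' @param lineCenters named fractions of length for `C`, `T`, `ref1`..`ref5`.
#' @param lineWidthFrac line width as a fraction of length.
#' @param neutralZone `(top, left, bottom, right)` fractions.
#' @param nominalSignals strictly increasing \eqn{R_k}, length 5.
#' @return A [StripLayout-class] object.
#' @examples
#' layout <- StripLayout()
#' lineWindows(layout)
#' @export
StripLayout <- function(width = 600L, height = 120L,
                        lineCenters = c(C = 0.15, T = 0.30, ref1 = 0.50,
                                        ref2 = 0.60, ref3 = 0.70,
                                        ref4 = 0.80, ref5 = 0.90),
                        lineWidthFrac = 0.02,
                        neutralZone = c(0.10, 0.94, 0.90, 0.99),
                        nominalSignals = c(10, 20, 40, 60, 80)) {
  new("StripLayout", width = as.integer(width), height = as.integer(height),
      lineCenters = lineCenters, lineWidthFrac = lineWidthFrac,
      neutralZone = neutralZone, nominalSignals = nominalSignals)
}

#' Construct a dose-response model
#'
#' Defaults emulate a test line whose readout is close to linear over the
#' 5–100 ng/mL measuring range (linear fit R^2 about 0.99) while
#' saturating well beyond it.
#'
#' @param dMax density gain at saturation.
#' @param kHalf half-saturation concentration (ng/mL).
#' @param floor residual zero-analyte density.
#' @return A [DoseResponse-class] object.
#' @export
DoseResponse <- function(dMax = 1.0, kHalf = 250, floor = 0.02) {
  new("DoseResponse", dMax = dMax, kHalf = kHalf, floor = floor)
}

#' Construct a device model
#'
#' @param wbGains three positive per-channel white-balance gains; the
#'   render pipeline applies their inverse as the device tint.
#' @param shadingCoeffs six 2-D polynomial coefficients
#'   `(1, u, v, u^2, uv, v^2)` of the multiplicative shading field.
#' @param colorMatrix invertible 3x3 channel-mixing matrix.
#' @param intensityScale positive global scale.
#' @param gamma `"srgb"` or `"none"`.
#' @param noiseSd additive Gaussian noise sd in `[0, 1]` units
#'   (default 0.004, about one 8-bit digital number).
#' @return A [DeviceModel-class] object.
#' @export
DeviceModel <- function(wbGains = c(1, 1, 1),
                        shadingCoeffs = c(1, 0, 0, 0, 0, 0),
                        colorMatrix = diag(3),
                        intensityScale = 1,
                        gamma = "srgb",
                        noiseSd = 0.004) {
  new("DeviceModel", wbGains = wbGains, shadingCoeffs = shadingCoeffs,
      colorMatrix = colorMatrix, intensityScale = intensityScale,
      gamma = gamma, noiseSd = noiseSd)
}

#' The identity (distortion-free, noise-free) device
#'
#' Renders the ideal linear-space strip untouched: unit gains, flat
#' shading, identity color matrix, no gamma encoding and no noise.
#'
#' @return A [DeviceModel-class] object.
#' @export
identityDevice <- function() DeviceModel(gamma = "none", noiseSd = 0)

#' Construct a StripImage
#'
#' @param pixels H x W x 3 array in `[0, 1]`.
#' @param colorSpace `"srgb"` or `"linear"`.
#' @return A [StripImage-class] object.
#' @export
StripImage <- function(pixels, colorSpace = c("srgb", "linear")) {
  new("StripImage", pixels = pixels, colorSpace = match.arg(colorSpace))
}

#' @describeIn StripImage pixel array accessor.
#' @param x a `StripImage`.
#' @export
pixels <- function(x) x@pixels

#' @describeIn StripImage color-space accessor.
#' @export
colorSpace <- function(x) x@colorSpace

#' @describeIn rectify source-to-canonical homography accessor.
#' @export
homography <- function(x) x@homography

#' Read / write strip images as 8-bit PNG
#'
#' PNG files are treated as sRGB-encoded on read unless `colorSpace` says
#' otherwise. Writing quantizes to 8 bits.
#'
#' @param path file path.
#' @param colorSpace color-space tag to attach on read.
#' @return `readStripImage` returns a [StripImage-class];
#'   `writeStripImage` returns `path` invisibly.
#' @export
readStripImage <- function(path, colorSpace = "srgb") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  StripImage(px, colorSpace)
}

#' @rdname readStripImage
#' @param img a [StripImage-class].
#' @export
writeStripImage <- function(img, path) {
  stopifnot(is(img, "StripImage"))
  png::writePNG(img@pixels, path)
  invisible(path)
}

setMethod("show", "StripLayout", function(object) {
  cat("StripLayout:", object@width, "x", object@height, "px canonical frame\n")
  cat("  line centers (frac of length):\n")
  print(round(object@lineCenters, 3))
  cat("  line width:", object@lineWidthFrac, "| nominal signals:",
      paste(object@nominalSignals, collapse = ", "), "\n")
})

setMethod("show", "StripImage", function(object) {
  d <- dim(object@pixels)
  cat(class(object), ":", d[1], "x", d[2], "px,", object@colorSpace,
      "color space\n")
})

setMethod("show", "DoseResponse", function(object) {
  cat("DoseResponse: d(c) =", object@floor, "+", object@dMax,
      "* c / (", object@kHalf, "+ c )\n")
})

setMethod("show", "DeviceModel", function(object) {
  cat("DeviceModel: gamma =", object@gamma,
      "| noise sd =", object@noiseSd,
      "| intensity scale =", object@intensityScale, "\n")
  cat("  wb gains:", paste(round(object@wbGains, 3), collapse = ", "), "\n")
})

setMethod("show", "ReferenceLadder", function(object) {
  cat("ReferenceLadder (", sum(!object@outlier), "of",
      length(object@nominal), "points kept )\n")
  print(data.frame(I = object@intensity, R = object@nominal,
                   outlier = object@outlier))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: S = g(I) = %.6g + %.6g I", object@a0, object@a1))
  if (object@a2 != 0) cat(sprintf(" + %.6g I^2", object@a2))
  cat(sprintf("   (resid RMS %.3g)\n", object@residRMS))
})

setMethod("show", "ConcentrationModel", function(object) {
  pred <- if (object@mode == "ST") "S_T" else "S_T/S_C"
  cat(sprintf("ConcentrationModel: conc = %.6g * %s + %.6g  [%g, %g] ng/mL\n",
              object@alpha, pred, object@beta,
              object@rangeLow, object@rangeHigh))
})

setMethod("show", "PhotometricTransform", function(object) {
  cat("PhotometricTransform: gamma =", object@gamma,
      "| wb gains:", paste(round(object@wbGains, 4), collapse = ", "),
      "| intensity scale:", round(object@intensityScale, 4), "\n")
  cat("  ccm:\n"); print(round(object@ccm, 4))
})
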