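## Shared fixtures, built once per test run and cached: the default
## layout, a set of distorted capture devices, and a concentration model
## calibrated from an 8-level x 3-replicate synthetic reference panel.

.fixtures <- new.env(parent = emptyenv())

fixLayout <- function() StripLayout()

## A realistically distorted phone camera: warm tint, corner vignetting,
## mild channel mixing, slightly hot exposure, sRGB output.
phoneDevice <- function(noiseSd = 0.004) {
  DeviceModel(
    wbGains = c(1.2, 1.0, 0.9),
    shadingCoeffs = c(1.05, 0.04, -0.02, -0.3, 0.02, -0.12),
    colorMatrix = matrix(c(0.94, 0.04, 0.02,
                           0.04, 0.92, 0.04,
                           0.02, 0.05, 0.93), 3, byrow = TRUE),
    intensityScale = 1.08, gamma = "srgb", noiseSd = noiseSd)
}

## The reference phone: undistorted sRGB capture.
referenceDevice <- function(noiseSd = 0.004) {
  DeviceModel(gamma = "srgb", noiseSd = noiseSd)
}

## Five distinct device models for cross-device classification checks.
testDevices <- function() {
  list(identity = identityDevice(),
       tint = DeviceModel(wbGains = c(1.2, 1, 0.9), gamma = "srgb", noiseSd = 0),
       vignette = DeviceModel(shadingCoeffs = c(1.05, 0.04, -0.02, -0.3, 0.02, -0.12),
                              gamma = "srgb", noiseSd = 0),
       mixed = DeviceModel(colorMatrix = matrix(c(0.94, 0.04, 0.02,
                                                  0.04, 0.92, 0.04,
                                                  0.02, 0.05, 0.93), 3, byrow = TRUE),
                           gamma = "srgb", noiseSd = 0),
       bright = DeviceModel(intensityScale = 1.15, gamma = "srgb", noiseSd = 0))
}

## Reference-panel design: 8 dilution levels spanning the measuring
## range, 3 replicates each.
panelLevels <- function() data.frame(conc = c(5, 10, 20, 30, 40, 60, 80, 100), n = 3)

## Concentration model fitted once from the synthetic reference panel
## captured by the (noisy) reference device.
fittedModel <- function() {
  if (is.null(.fixtures$cm)) {
    panel <- generateValidationPanel(panelLevels(), layout = fixLayout(),
                                     device = referenceDevice(), seed = 11)
    .fixtures$cm <- fitConcentrationFromPanel(panel, defaultConfig(fixLayout()))
  }
  .fixtures$cm
}

fittedConfig <- function(transform = NULL) {
  defaultConfig(fixLayout(), fittedModel(), transform)
}

## Photometric transform learned from three paired captures, cached.
fittedTransform <- function(noiseSd = 0.004) {
  key <- paste0("tr", noiseSd)
  if (is.null(.fixtures[[key]])) {
    pairs <- lapply(c(10, 40, 80), function(cc)
      makePairedCaptures(fixLayout(), cc, deviceA = phoneDevice(noiseSd),
                         deviceB = referenceDevice(noiseSd), seed = cc))
    .fixtures[[key]] <- fitPhotometricTransform(
      lapply(pairs, function(p) asRectified(p$imageA)),
      lapply(pairs, function(p) asRectified(p$imageB)), fixLayout())
  }
  .fixtures[[key]]
}
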