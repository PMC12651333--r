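## Cross-device photometric alignment: learn a transform that maps one
## device's captures into a reference device's linear space, as
## (i) sRGB linearization, (ii) neutral-zone white balance,
## (iii) polynomial shading correction, (iv) 3x3 color correction matrix
## with a global intensity scale. Each sub-fit is linear and they are
## fitted sequentially in that order.

#' sRGB transfer functions
#'
#' Standard sRGB electro-optical transfer (decode) and its inverse
#' (encode); the round trip is exact to well below 1e-7.
#'
#' @param x a [StripImage-class], pixel array or numeric vector.
#' @param warn warn when linearizing an already-linear image (then a
#'   no-op).
#' @return Same shape as the input; for a `StripImage`, the color-space
#'   tag is updated.
#' @examples
#' srgbLinearize(0.5)           # 0.2140...
#' srgbEncode(srgbLinearize(0.73)) - 0.73
#' @export
srgbLinearize <- function(x, warn = TRUE) {
  if (is(x, "StripImage")) {
    if (x@colorSpace == "linear") {
      if (warn) warning("image is already linear; returning unchanged")
      return(x)
    }
    return(StripImage(srgbLinearize(x@pixels), "linear"))
  }
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgbLinearize
#' @export
srgbEncode <- function(x) {
  if (is(x, "StripImage")) {
    if (x@colorSpace == "srgb") return(x)
    return(StripImage(clip01(srgbEncode(x@pixels)), "srgb"))
  }
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

## Pixel rows of the neutral zone of an image, as an n x 3 matrix.
neutralZonePixels <- function(px, zone) {
  d <- dim(px)
  rows <- max(1L, floor(zone[1] * d[1]) + 1L):min(d[1], ceiling(zone[3] * d[1]))
  cols <- max(1L, floor(zone[2] * d[2]) + 1L):min(d[2], ceiling(zone[4] * d[2]))
  matrix(px[rows, cols, ], length(rows) * length(cols), 3)
}

#' White-balance gains from the cassette's neutral zone
#'
#' Per-channel gains \eqn{(\bar m / m_R, \bar m / m_G, \bar m / m_B)}
#' where \eqn{m_X} is the median of channel X over the neutral zone and
#' \eqn{\bar m} their mean; applying the gains equalizes the zone's
#' channel medians.
#'
#' @param img linear-space [StripImage-class] (or pixel array).
#' @param zone `(top, left, bottom, right)` fractions, e.g.
#'   `StripLayout()@neutralZone` for a rectified strip.
#' @return Numeric length-3 gains.
#' @export
whiteBalanceFromNeutral <- function(img, zone) {
  px <- if (is(img, "StripImage")) img@pixels else img
  nz <- neutralZonePixels(px, zone)
  if (nrow(nz) < 100L) stop("neutral zone must contain at least 100 pixels")
  m <- apply(nz, 2, stats::median)
  if (any(m <= 0.01)) stop("neutral zone too dark for white balance")
  mean(m) / m
}

#' @rdname whiteBalanceFromNeutral
#' @param gains length-3 gains to apply per channel.
#' @export
applyWhiteBalance <- function(img, gains) {
  asImage <- is(img, "StripImage")
  px <- if (asImage) img@pixels else img
  for (ch in 1:3) px[, , ch] <- px[, , ch] * gains[ch]
  px <- clip01(px)
  if (asImage) StripImage(px, img@colorSpace) else px
}

#' Fit the polynomial shading (vignetting) field
#'
#' Least-squares fit of a degree-2 2-D polynomial to the luminance of a
#' white-balanced linear image over a background mask (substrate pixels
#' away from all line windows). The correction divides the image by the
#' fitted field normalized to mean one.
#'
#' @param img linear, white-balanced [StripImage-class] or pixel array.
#' @param mask logical H x W matrix of background pixels (`NULL` uses
#'   all pixels).
#' @return Numeric length-6 coefficients `(1, u, v, u^2, uv, v^2)` in
#'   centred normalized coordinates.
#' @export
fitShading <- function(img, mask = NULL) {
  px <- if (is(img, "StripImage")) img@pixels else img
  lum <- luminance(px)
  H <- nrow(lum); W <- ncol(lum)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  idx <- which(mask, arr.ind = TRUE)
  X <- shadingDesign(idx[, 1], idx[, 2], H, W)
  fit <- stats::lm.fit(X, lum[mask])
  if (fit$rank < ncol(X)) stop("shading fit is rank-deficient")
  unname(fit$coefficients)
}

#' @rdname fitShading
#' @param coeffs length-6 shading coefficients.
#' @param H,W frame size to evaluate on.
#' @return `shadingField` returns the H x W multiplicative field
#'   normalized to mean one.
#' @export
shadingField <- function(coeffs, H, W) {
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  f <- matrix(shadingDesign(rr, cc, H, W) %*% coeffs, H, W)
  if (any(f <= 0)) stop("fitted shading field is not positive")
  f / mean(f)
}

#' @rdname fitShading
#' @export
applyShadingCorrection <- function(img, coeffs) {
  asImage <- is(img, "StripImage")
  px <- if (asImage) img@pixels else img
  d <- dim(px)
  f <- shadingField(coeffs, d[1], d[2])
  px <- clip01(px / array(rep(f, 3), d))
  if (asImage) StripImage(px, img@colorSpace) else px
}

## Background mask of the canonical frame: substrate pixels away from all
## line windows and image borders.
backgroundMask <- function(layout, marginFrac = 0.05) {
  H <- layout@height; W <- layout@width
  mask <- matrix(TRUE, H, W)
  mrow <- max(1L, round(marginFrac * H)); mcol <- max(1L, round(marginFrac * W))
  mask[c(seq_len(mrow), (H - mrow + 1L):H), ] <- FALSE
  mask[, c(seq_len(mcol), (W - mcol + 1L):W)] <- FALSE
  half <- 2 * lineWidthPx(layout)
  for (nm in names(layout@lineCenters)) {
    ctr <- round(layout@lineCenters[[nm]] * W)
    cols <- max(1L, ctr - half):min(W, ctr + half)
    mask[, cols] <- FALSE
  }
  mask
}

#' Fit the 3x3 color correction matrix with intensity scaling
#'
#' Least squares for the matrix `A` minimizing
#' \eqn{\sum_i \| A x_i - y_i \|^2} over paired source/target patch
#' colors, factored as `A = s * M`: the global intensity scale `s` is the
#' ratio of mean target to mean source luminance, so `M` is
#' luminance-neutral. At least 4 pairs spanning all three color
#' dimensions are required.
#'
#' @param src,tgt n x 3 matrices of paired linear RGB patch means.
#' @return List with `ccm` (3x3 `M`), `intensityScale` (`s`), and
#'   `residRMS`.
#' @export
fitCCM <- function(src, tgt) {
  src <- as.matrix(src); tgt <- as.matrix(tgt)
  stopifnot(ncol(src) == 3L, ncol(tgt) == 3L, nrow(src) == nrow(tgt))
  if (nrow(src) < 4L) stop("need at least 4 color pairs")
  if (qr(src)$rank < 3L)
    stop("degenerate colors: pairs do not span three dimensions")
  A <- t(qr.solve(src, tgt))          # tgt ~ src %*% t(A)
  s <- mean(luminance(tgt)) / mean(luminance(src))
  resid <- tgt - src %*% t(A)
  list(ccm = A / s, intensityScale = s,
       residRMS = sqrt(mean(resid^2)))
}

## Patch means used to pair colors across devices: the five reference-line
## windows, the C line and the neutral zone of a rectified strip.
patchMeans <- function(px, layout) {
  W <- layout@width; H <- dim(px)[1]
  half <- floor(lineWidthPx(layout) / 2)
  r1 <- floor(0.2 * H) + 1L; r2 <- ceiling(0.8 * H)
  ids <- c("C", paste0("ref", 1:5))
  out <- matrix(0, length(ids) + 1L, 3)
  for (i in seq_along(ids)) {
    ctr <- round(layout@lineCenters[[ids[i]]] * W)
    cols <- (ctr - half):(ctr + half)
    out[i, ] <- vapply(1:3, function(ch) mean(px[r1:r2, cols, ch]), numeric(1))
  }
  out[length(ids) + 1L, ] <- colMeans(neutralZonePixels(px, layout@neutralZone))
  out
}

#' Learn a cross-device photometric transform from paired captures
#'
#' Given rectified canonical strips of the same cassettes captured by a
#' source and a reference device, estimates sequentially: white-balance
#' gains from the source neutral zones (averaged over pairs), the shading
#' field of the white-balanced source background, and the color
#' correction matrix with intensity scale mapping corrected source patch
#' colors (reference-line windows, control line, neutral zone) onto the
#' reference patches.
#'
#' @param sources,targets lists of [RectifiedStrip-class] pairs (same
#'   length, element i of each showing the same cassette).
#' @param layout the common [StripLayout-class].
#' @return A [PhotometricTransform-class].
#' @export
fitPhotometricTransform <- function(sources, targets, layout = StripLayout()) {
  stopifnot(length(sources) == length(targets), length(sources) >= 1L)
  gains <- rowMeans(vapply(sources, function(s)
    whiteBalanceFromNeutral(s, layout@neutralZone), numeric(3)))
  mask <- backgroundMask(layout)
  wbFirst <- applyWhiteBalance(sources[[1]]@pixels, gains)
  shading <- fitShading(wbFirst, mask)
  srcPatches <- do.call(rbind, lapply(sources, function(s) {
    px <- applyShadingCorrection(applyWhiteBalance(s@pixels, gains), shading)
    patchMeans(px, layout)
  }))
  tgtPatches <- do.call(rbind, lapply(targets, function(t)
    patchMeans(t@pixels, layout)))
  ccm <- fitCCM(srcPatches, tgtPatches)
  new("PhotometricTransform", wbGains = gains, shadingCoeffs = shading,
      ccm = ccm$ccm, intensityScale = ccm$intensityScale, gamma = "srgb")
}

#' Identity photometric transform
#'
#' @return A [PhotometricTransform-class] that only linearizes.
#' @export
identityTransform <- function() {
  new("PhotometricTransform", wbGains = c(1, 1, 1),
      shadingCoeffs = c(1, 0, 0, 0, 0, 0), ccm = diag(3),
      intensityScale = 1, gamma = "srgb")
}

#' Align an image into the reference device space
#'
#' Applies the four transform steps in order: sRGB linearization (skipped
#' without warning when the input is already linear, e.g. a rectified
#' strip), white balance, shading correction, then the color correction
#' matrix with intensity scaling. The output is in the reference device's
#' linear space.
#'
#' @param img a [StripImage-class] (sRGB or linear).
#' @param transform a [PhotometricTransform-class].
#' @return A linear-space [StripImage-class] (a [RectifiedStrip-class]
#'   input keeps its class and homography).
#' @export
alignImage <- function(img, transform) {
  stopifnot(is(img, "StripImage"), is(transform, "PhotometricTransform"))
  px <- if (img@colorSpace == "srgb") srgbLinearize(img@pixels) else img@pixels
  px <- applyWhiteBalance(px, transform@wbGains)
  px <- applyShadingCorrection(px, transform@shadingCoeffs)
  px <- applyColorMatrix(px, transform@ccm) * transform@intensityScale
  px <- clip01(px)
  if (is(img, "RectifiedStrip"))
    new("RectifiedStrip", pixels = px, colorSpace = "linear",
        homography = img@homography)
  else StripImage(px, "linear")
}
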