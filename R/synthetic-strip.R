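## Synthetic strip-image generation with exhaustively known ground truth.
## The renderer draws the canonical strip in linear reflectance (white
## nitrocellulose substrate, red dye lines absorbing mostly the green
## channel), warps it into a photographed pose by homography, and applies
## a DeviceModel in the fixed order
##   shading -> color matrix -> intensity scale -> inverse white balance
##   -> gamma encode -> additive noise,
## so that every downstream correction step has a known truth to recover.

## Per-channel absorbance weights of the red AuNP dye relative to the
## green-channel density: the band is red, so green absorbs fully, blue
## strongly, red barely.
.DYE_ABSORBANCE <- c(red = 0.1, green = 1.0, blue = 0.8)

#' Test-line optical density as a function of concentration
#'
#' Saturating (Langmuir-form) dose-response
#' \deqn{d(c) = floor + d_{max} c / (k_{half} + c)}: strictly increasing
#' in `c`, equal to `floor` at zero analyte and approaching
#' `floor + dMax` at saturation.
#'
#' @param conc analyte concentration in ng/mL (vectorized, must be >= 0).
#' @param dr a [DoseResponse-class] object.
#' @return Optical density (absorbance-proxy units).
#' @examples
#' doseResponseDensity(c(0, 50, 100), DoseResponse())
#' @export
doseResponseDensity <- function(conc, dr = DoseResponse()) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  dr@floor + dr@dMax * conc / (dr@kHalf + conc)
}

## Per-line densities of the canonical strip for a given concentration.
lineDensities <- function(layout, conc, dr, cDensity, signalToDensity) {
  c(C = cDensity,
    T = unname(doseResponseDensity(conc, dr)),
    stats::setNames(signalToDensity * layout@nominalSignals, paste0("ref", 1:5)))
}

## Canonical linear-reflectance render: substrate times per-channel
## transmittance 10^(-weight * density(col)). Line edges ramp linearly
## over ~2 px (dye diffuses at the band boundary in a real membrane).
canonicalRender <- function(layout, densities, substrate = 0.75,
                            edgeSoftness = 2) {
  W <- layout@width; H <- layout@height
  dcol <- numeric(W)
  half <- layout@lineWidthFrac * W / 2
  for (nm in names(layout@lineCenters)) {
    ctr <- layout@lineCenters[[nm]] * W
    w <- clip01((half + edgeSoftness / 2 - abs(seq_len(W) - ctr)) / edgeSoftness)
    dcol <- dcol + densities[[nm]] * w
  }
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    trans <- substrate * 10^(-.DYE_ABSORBANCE[ch] * dcol)
    px[, , ch] <- matrix(trans, H, W, byrow = TRUE)
  }
  px
}

## Warp a canonical pixel array into a canvas at the given pose
## (4x2 corners, TL TR BR BL), with 2x2 supersampling for soft edges.
warpToPose <- function(canon, layout, pose, canvas, background) {
  if (!isConvexQuad(pose))
    stop("degenerate pose: corners must form a convex quadrilateral")
  Hc <- canvas[1]; Wc <- canvas[2]
  Hmap <- estimateHomography(canonicalCorners(layout), pose)
  Hinv <- solve(Hmap)
  out <- array(background, c(Hc, Wc, 3))
  rr <- rep(seq_len(Hc), Wc)
  cc <- rep(seq_len(Wc), each = Hc)
  acc <- matrix(0, Hc * Wc, 3)
  inside <- rep(0, Hc * Wc)
  offs <- c(-0.25, 0.25)
  for (dr_ in offs) for (dc_ in offs) {
    src <- applyHomography(Hinv, cbind(rr + dr_, cc + dc_))
    ok <- src[, 1] >= 0.5 & src[, 1] <= layout@height + 0.5 &
          src[, 2] >= 0.5 & src[, 2] <= layout@width + 0.5
    if (any(ok)) {
      acc[ok, ] <- acc[ok, ] + bilinearSample(canon, src[ok, 1], src[ok, 2])
    }
    inside <- inside + as.numeric(ok)
  }
  ## the cassette boundary is a hard physical edge: a pixel belongs to the
  ## strip when most of its subsamples do, and takes the mean of those
  ## subsamples only (interior detail stays antialiased)
  isStrip <- inside >= 2
  out <- matrix(background, Hc * Wc, 3)
  out[isStrip, ] <- acc[isStrip, , drop = FALSE] / inside[isStrip]
  array(out, c(Hc, Wc, 3))
}

## Apply a DeviceModel to a linear pixel array; returns the final
## (possibly gamma-encoded, noisy, clipped) array.
applyDevice <- function(px, device, seed = NULL) {
  d <- dim(px)
  rr <- rep(seq_len(d[1]), d[2])
  cc <- rep(seq_len(d[2]), each = d[1])
  field <- drop(shadingDesign(rr, cc, d[1], d[2]) %*% device@shadingCoeffs)
  px <- px * array(rep(field, 3), d)
  px <- applyColorMatrix(px, device@colorMatrix) * device@intensityScale
  for (ch in 1:3) px[, , ch] <- px[, , ch] / device@wbGains[ch]
  if (device@gamma == "srgb") px <- srgbEncode(px)
  if (device@noiseSd > 0) {
    px <- withSeed(seed, px + array(stats::rnorm(length(px), 0, device@noiseSd), d))
  }
  clip01(px)
}

#' Generate a test pose quadrilateral inside a canvas
#'
#' Builds a strip-shaped quadrilateral centred in the canvas, scaled to
#' fit, rotated, and optionally perspective-tilted (the top edge is
#' shrunk relative to the bottom edge, as when the camera looks down at
#' an angle).
#'
#' @param layout a [StripLayout-class].
#' @param canvas `(height, width)` of the photograph in pixels.
#' @param rotation rotation in degrees (positive = clockwise on screen).
#' @param perspective top-edge shrink fraction in `[0, 0.3]`.
#' @param scale strip length as a fraction of the fitting size.
#' @return 4x2 (row, col) corner matrix, TL TR BR BL.
#' @export
makePose <- function(layout, canvas = c(400, 900), rotation = 0,
                     perspective = 0, scale = 1.05) {
  L <- layout@width * scale; Hh <- layout@height * scale
  ctr <- canvas / 2
  base <- matrix(c(-L / 2, -Hh / 2, L / 2, -Hh / 2,
                   L / 2, Hh / 2, -L / 2, Hh / 2),
                 4, 2, byrow = TRUE)   # (x, y) TL TR BR BL
  base[1, 1] <- base[1, 1] + perspective * L / 2
  base[2, 1] <- base[2, 1] - perspective * L / 2
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  xy <- base %*% t(R)
  q <- cbind(ctr[1] + xy[, 2], ctr[2] + xy[, 1])  # (row, col)
  if (any(q[, 1] < 2 | q[, 1] > canvas[1] - 1 | q[, 2] < 2 | q[, 2] > canvas[2] - 1))
    stop("pose does not fit inside the canvas; reduce scale or rotation")
  orderCorners(q)
}

#' Render a synthetic strip photograph with ground truth
#'
#' Draws the canonical strip (control line at a fixed high density, test
#' line from the dose-response, reference lines from the nominal signals
#' through a fixed linear signal-to-density map), warps it to the
#' requested pose over a darker background, applies the device model and
#' returns the image together with a ground-truth sidecar. Identical
#' inputs and seed give identical pixels.
#'
#' @param layout a [StripLayout-class].
#' @param conc true analyte concentration (ng/mL).
#' @param dr a [DoseResponse-class].
#' @param device a [DeviceModel-class].
#' @param pose 4x2 corner matrix (see [makePose()]), or `NULL` to return
#'   the canonical frame itself (no background).
#' @param canvas photograph size `(height, width)`; ignored when
#'   `pose = NULL`.
#' @param background background reflectance of the cassette surround.
#' @param substrate substrate (membrane) reflectance; kept below 1 so a
#'   moderate illumination gain does not clip.
#' @param cDensity fixed control-line density.
#' @param signalToDensity linear map from nominal signal units to optical
#'   density for the reference lines.
#' @param seed integer seed for the noise draw (`NULL` = use the current
#'   RNG stream).
#' @return A list with elements `image` ([StripImage-class]) and `truth`
#'   (list with `corners`, `concentration`, `lineDensities`, `device`,
#'   `seed`).
#' @examples
#' s <- renderStrip(StripLayout(), conc = 50, device = identityDevice())
#' dim(pixels(s$image))
#' @export
renderStrip <- function(layout = StripLayout(), conc, dr = DoseResponse(),
                        device = DeviceModel(), pose = NULL,
                        canvas = c(400, 900), background = 0.25,
                        substrate = 0.75, cDensity = 0.8,
                        signalToDensity = 0.01, seed = NULL) {
  dens <- lineDensities(layout, conc, dr, cDensity, signalToDensity)
  canon <- canonicalRender(layout, dens, substrate)
  if (is.null(pose)) {
    px <- canon
    corners <- canonicalCorners(layout)
  } else {
    pose <- orderCorners(pose)
    px <- warpToPose(canon, layout, pose, canvas, background)
    corners <- pose
  }
  px <- applyDevice(px, device, seed)
  img <- StripImage(px, if (device@gamma == "srgb") "srgb" else "linear")
  list(image = img,
       truth = list(corners = corners, concentration = conc,
                    lineDensities = dens, device = device, seed = seed))
}

#' Paired captures of one strip under two devices
#'
#' Renders the same canonical strip (identical line densities and
#' substrate) under two device models, as when one cassette is
#' photographed by two phones. The two noise draws are independent; with
#' noise-free devices and equal inputs the captures are pixel-identical.
#'
#' @inheritParams renderStrip
#' @param deviceA,deviceB the two [DeviceModel-class]s.
#' @return List with `imageA`, `imageB` and shared `truth`.
#' @export
makePairedCaptures <- function(layout = StripLayout(), conc,
                               dr = DoseResponse(), deviceA, deviceB,
                               pose = NULL, canvas = c(400, 900),
                               background = 0.25, substrate = 0.75,
                               cDensity = 0.8, signalToDensity = 0.01,
                               seed = NULL) {
  a <- renderStrip(layout, conc, dr, deviceA, pose, canvas, background,
                   substrate, cDensity, signalToDensity, seed)
  b <- renderStrip(layout, conc, dr, deviceB, pose, canvas, background,
                   substrate, cDensity, signalToDensity,
                   if (is.null(seed)) NULL else seed + 500009L)
  list(imageA = a$image, imageB = b$image, truth = a$truth)
}

#' Generate a replicated multi-level validation panel
#'
#' Renders `n` replicate strips at each requested concentration with
#' independent noise, emulating a dilution-series validation study
#' (e.g. eight levels, five replicates per day). Optionally writes each
#' image as PNG with a JSON ground-truth sidecar plus a CSV manifest.
#'
#' @param levels a data.frame with columns `conc` and `n`, or a list of
#'   `c(conc, n)` pairs.
#' @inheritParams renderStrip
#' @param dir output directory (`NULL` = keep in memory only).
#' @param deviceId label written to the manifest.
#' @return Invisibly for written panels, otherwise a list of
#'   `list(image, truth)` entries, one per replicate, with the manifest
#'   data.frame as attribute `"manifest"`.
#' @export
generateValidationPanel <- function(levels, layout = StripLayout(),
                                    dr = DoseResponse(),
                                    device = DeviceModel(), pose = NULL,
                                    canvas = c(400, 900), seed = 1L,
                                    dir = NULL, deviceId = "device") {
  if (is.list(levels) && !is.data.frame(levels))
    levels <- do.call(rbind, lapply(levels, function(x)
      data.frame(conc = x[1], n = x[2])))
  stopifnot(all(levels$conc >= 0), all(levels$n >= 1))
  out <- vector("list", sum(levels$n))
  manifest <- data.frame(path = character(), concentration_ng_ml = numeric(),
                         seed = integer(), device_id = character())
  k <- 0L
  for (i in seq_len(nrow(levels))) {
    for (j in seq_len(levels$n[i])) {
      k <- k + 1L
      s <- seed + k
      out[[k]] <- renderStrip(layout, levels$conc[i], dr, device, pose,
                              canvas, seed = s)
      path <- sprintf("strip_%03d_c%g.png", k, levels$conc[i])
      manifest <- rbind(manifest, data.frame(
        path = path, concentration_ng_ml = levels$conc[i],
        seed = s, device_id = deviceId))
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (k in seq_along(out)) {
      writeStripImage(out[[k]]$image, file.path(dir, manifest$path[k]))
      tr <- out[[k]]$truth
      jsonlite::write_json(
        list(corners = tr$corners, concentration = tr$concentration,
             lineDensities = as.list(tr$lineDensities), seed = tr$seed),
        file.path(dir, sub("\\.png$", ".truth.json", manifest$path[k])),
        auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(out, "manifest") <- manifest
  invisible(out)
}
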