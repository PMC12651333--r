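## Line-signal extraction: longitudinal absorbance profile on the green
## channel, peak localisation inside expected windows, local background
## correction from flanking windows, and the robustly screened reference
## ladder.

#' Expected line windows of a layout
#'
#' @param layout a [StripLayout-class].
#' @param halfWidthFrac half-width of the search window as a fraction of
#'   the strip length (default 0.03).
#' @return data.frame with rownames `C`, `T`, `ref1`..`ref5` and columns
#'   `center`, `lo`, `hi` (column indices in the canonical frame).
#' @export
lineWindows <- function(layout, halfWidthFrac = 0.03) {
  W <- layout@width
  ctr <- round(layout@lineCenters * W)
  hw <- round(halfWidthFrac * W)
  data.frame(center = ctr, lo = pmax(1, ctr - hw), hi = pmin(W, ctr + hw),
             row.names = names(layout@lineCenters))
}

#' @describeIn lineWindows line width in pixels.
#' @export
lineWidthPx <- function(layout) max(3L, round(layout@lineWidthFrac * layout@width))

#' @describeIn lineWindows default flank gap in pixels (one line width).
#' @export
flankGapPx <- function(layout) lineWidthPx(layout)

#' Longitudinal absorbance profile of a rectified strip
#'
#' For every longitudinal position (column), the absorbance proxy is
#' \eqn{-\log_{10}(\max(\epsilon, m))} where `m` is the 20% trimmed mean
#' of the green channel over the transverse central 60% of the strip
#' height. The trimmed mean resists dust and glare specks; the green
#' channel is the one the red immunocomplex band absorbs most.
#'
#' @param rs a [RectifiedStrip-class] (linear color space).
#' @param layout the matching [StripLayout-class].
#' @param trim trim fraction of the transverse mean.
#' @param eps transmittance floor.
#' @return Numeric vector of length `width(layout)` with attribute
#'   `channel = "green"`.
#' @export
extractProfile <- function(rs, layout = StripLayout(), trim = 0.2,
                           eps = 1e-4) {
  stopifnot(is(rs, "StripImage"))
  H <- dim(rs@pixels)[1]
  r1 <- floor(0.2 * H) + 1L
  r2 <- ceiling(0.8 * H)
  green <- rs@pixels[r1:r2, , 2]
  tm <- apply(green, 2, mean, trim = trim)
  structure(-log10(pmax(eps, tm)), channel = "green")
}

#' Locate a line peak inside an expected window
#'
#' Returns the position of the maximum profile value within the window;
#' exact ties are broken toward the window center. A flat window still
#' returns its center: whether the line is real is decided later by the
#' measured intensity, not here.
#'
#' @param profile numeric profile from [extractProfile()].
#' @param window integer `(lo, hi)` index range (inside the profile).
#' @return Peak column index.
#' @export
locateLine <- function(profile, window) {
  lo <- window[1]; hi <- window[2]
  stopifnot(lo >= 1, hi <= length(profile), lo <= hi)
  idx <- lo:hi
  v <- profile[idx]
  cand <- idx[v >= max(v) - 1e-12]
  center <- floor((lo + hi) / 2)
  cand[which.min(abs(cand - center))]
}

#' Background-corrected line intensity
#'
#' The line window is `peak +/- floor(lineWidth/2)`; the local background
#' is the median of the two flanking windows (each `lineWidth` wide,
#' offset by `flankGap` beyond the line window on both sides); the
#' intensity is the mean profile over the line window minus that
#' background, clamped at zero. Background subtraction makes the measure
#' exactly invariant to adding a constant to the whole profile, i.e. to a
#' global illumination gain in linear space.
#'
#' @param profile numeric profile from [extractProfile()].
#' @param peakPos line peak position from [locateLine()].
#' @param lineWidth line width in pixels.
#' @param flankGap gap between line window and each flank, in pixels.
#' @param forbidden optional list of `(lo, hi)` ranges (other line
#'   windows); a flank overlapping any of them is a configuration error.
#' @return A list of class `"LineMeasurement"`: `peakPos`, `intensity`,
#'   `background`.
#' @export
measureIntensity <- function(profile, peakPos, lineWidth, flankGap,
                             forbidden = NULL) {
  half <- floor(lineWidth / 2)
  lineIdx <- (peakPos - half):(peakPos + half)
  leftIdx <- (peakPos - half - flankGap - lineWidth):(peakPos - half - flankGap - 1L)
  rightIdx <- (peakPos + half + flankGap + 1L):(peakPos + half + flankGap + lineWidth)
  n <- length(profile)
  if (min(leftIdx) < 1L || max(rightIdx) > n)
    stop("flanking windows fall outside the profile")
  if (!is.null(forbidden)) {
    for (fr in forbidden) {
      if (any(leftIdx >= fr[1] & leftIdx <= fr[2]) ||
          any(rightIdx >= fr[1] & rightIdx <= fr[2]))
        stop("configuration error: flank overlaps another line window")
    }
  }
  background <- stats::median(profile[c(leftIdx, rightIdx)])
  intensity <- max(0, mean(profile[lineIdx]) - background)
  structure(list(peakPos = peakPos, intensity = intensity,
                 background = background),
            class = "LineMeasurement")
}

#' Measure all lines of a rectified strip
#'
#' Convenience wrapper: extracts the profile, locates each of C, T and
#' the five reference lines in its expected window and measures its
#' background-corrected intensity, guarding each flank against the other
#' line windows.
#'
#' @param rs a [RectifiedStrip-class].
#' @param layout the matching [StripLayout-class].
#' @return data.frame with rownames `C`, `T`, `ref1`..`ref5` and columns
#'   `peakPos`, `intensity`, `background`.
#' @export
measureStrip <- function(rs, layout = StripLayout()) {
  prof <- extractProfile(rs, layout)
  w <- lineWindows(layout)
  lw <- lineWidthPx(layout)
  gap <- flankGapPx(layout)
  half <- floor(lw / 2)
  ## matched filter for localisation only: a line-width moving average
  ## turns the (noisy) plateau into a peak at the plateau center, so the
  ## measurement window stays centred on the line under pixel noise
  sm <- stats::filter(prof, rep(1 / lw, lw), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  res <- lapply(rownames(w), function(nm) {
    peak <- locateLine(sm, c(w[nm, "lo"], w[nm, "hi"]))
    others <- lapply(setdiff(rownames(w), nm), function(o)
      c(w[o, "center"] - half, w[o, "center"] + half))
    m <- measureIntensity(prof, peak, lw, gap, forbidden = others)
    data.frame(peakPos = m$peakPos, intensity = m$intensity,
               background = m$background)
  })
  out <- do.call(rbind, res)
  rownames(out) <- rownames(w)
  out
}

#' Build the reference ladder with robust outlier screening
#'
#' Pairs the five measured reference-line intensities \eqn{I_k} with the
#' nominal signals \eqn{R_k}, fits a provisional least-squares line of
#' \eqn{R} on \eqn{I}, and masks points whose absolute residual exceeds
#' three times the median absolute residual (with a small numerical
#' floor so an exact line masks nothing). At least two points must
#' survive.
#'
#' @param intensity measured \eqn{I_k}, length 5 (reference-line order).
#' @param nominal nominal \eqn{R_k}, strictly increasing.
#' @return A [ReferenceLadder-class].
#' @export
buildLadder <- function(intensity, nominal) {
  stopifnot(length(intensity) == length(nominal))
  if (stats::sd(intensity) < 1e-12)
    stop("ladder unusable: degenerate fit (identical intensities)")
  fit <- stats::lm.fit(cbind(1, intensity), nominal)
  res <- abs(fit$residuals)
  cut <- 3 * max(stats::median(res), 1e-8)
  outlier <- res > cut
  if (sum(!outlier) < 2L) stop("ladder unusable: fewer than 2 surviving points")
  new("ReferenceLadder", intensity = intensity, nominal = nominal,
      outlier = outlier)
}
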