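## Classical strip localisation and rectification: gradient-magnitude edge
## detection thresholded at the Otsu level, convex hull of the edge pixels,
## vertex decimation to a quadrilateral, and total-least-squares side
## refinement; then a 4-point DLT homography into the canonical frame.

## Reduce a convex hull (n x 2, cyclic order) to a quadrilateral: merge
## near-collinear consecutive hull segments, take the four longest merged
## segments as the sides, and intersect adjacent side lines. Unlike
## vertex decimation this does not clip corners rounded by antialiasing.
hullToQuad <- function(pts, angleTol = 5 * pi / 180) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1], 1L)
  segs <- lapply(seq_len(n), function(i) list(i = i, pts = rbind(pts[i, ], pts[nxt[i], ])))
  segDir <- function(s) {
    v <- s$pts[nrow(s$pts), ] - s$pts[1, ]
    atan2(v[1], v[2])
  }
  ## merge consecutive segments with near-identical direction (cyclic)
  repeat {
    m <- length(segs)
    if (m <= 4L) break
    dirs <- vapply(segs, segDir, numeric(1))
    dd <- abs((dirs - dirs[c(2:m, 1)] + pi) %% (2 * pi) - pi)
    j <- which.min(dd)
    if (dd[j] > angleTol) break
    k <- j %% m + 1L
    segs[[j]]$pts <- rbind(segs[[j]]$pts, segs[[k]]$pts[-1, , drop = FALSE])
    segs[[k]] <- NULL
  }
  if (length(segs) < 4L) return(NULL)
  len <- vapply(segs, function(s)
    sqrt(sum((s$pts[nrow(s$pts), ] - s$pts[1, ])^2)), numeric(1))
  sides <- segs[sort(order(len, decreasing = TRUE)[1:4])]  # keep hull order
  lines <- lapply(sides, function(s) tlsLine(s$pts))
  quad <- matrix(0, 4, 2)
  for (i in 1:4) {
    p <- lineIntersect(lines[[i]], lines[[i %% 4L + 1L]])
    if (is.null(p)) return(NULL)
    quad[i, ] <- p
  }
  quad
}

## Total-least-squares line through points: returns c(nx, ny, d) with
## nx*x + ny*y = d, (nx, ny) unit normal. pts is (row, col).
tlsLine <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  mx <- mean(x); my <- mean(y)
  M <- cbind(x - mx, y - my)
  sv <- svd(M, nu = 0)
  nrm <- sv$v[, 2]
  c(nrm[1], nrm[2], nrm[1] * mx + nrm[2] * my)
}

lineIntersect <- function(l1, l2) {
  A <- rbind(l1[1:2], l2[1:2])
  if (abs(det(A)) < 1e-12) return(NULL)
  xy <- solve(A, c(l1[3], l2[3]))
  c(xy[2], xy[1])  # (row, col)
}

#' Locate the strip quadrilateral in a photograph
#'
#' Edge pixels are those whose luminance gradient magnitude exceeds the
#' Otsu threshold (with an absolute contrast floor); their convex hull is
#' decimated to a quadrilateral, and each side is refined by a
#' total-least-squares line fit to the nearby edge pixels, with corners
#' taken as the intersections of adjacent sides.
#'
#' @param img a [StripImage-class] containing one high-contrast
#'   rectangular strip on a darker background.
#' @param minAreaFrac minimum quadrilateral area as a fraction of the
#'   image (default 0.05); below it detection fails.
#' @param gradientFloor absolute minimum gradient magnitude for a pixel
#'   to count as an edge.
#' @return 4x2 (row, col) corner matrix ordered clockwise TL, TR, BR, BL.
#' @seealso [rectify()], [makePose()]
#' @export
detectStrip <- function(img, minAreaFrac = 0.05, gradientFloor = 0.05) {
  stopifnot(is(img, "StripImage"))
  lum <- luminance(img@pixels)
  H <- nrow(lum); W <- ncol(lum)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (lum[, 3:W] - lum[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (lum[3:H, ] - lum[1:(H - 2), ]) / 2
  gm <- sqrt(gx^2 + gy^2)
  if (max(gm) < gradientFloor) stop("strip not found: no contrast edges")
  thr <- max(otsuThreshold(as.vector(gm)), gradientFloor)
  edge <- which(gm > thr, arr.ind = TRUE)
  if (nrow(edge) < 16L) stop("strip not found: too few edge pixels")
  hull <- edge[grDevices::chull(edge[, 2], edge[, 1]), , drop = FALSE]
  if (nrow(hull) < 4L) stop("strip not found: degenerate edge set")
  quad <- hullToQuad(hull)
  if (is.null(quad) || !isConvexQuad(quad))
    stop("strip not found: edge set does not form a quadrilateral")
  if (polygonArea(quad) < minAreaFrac * H * W)
    stop("strip not found: no 4-gon of sufficient area")
  quad <- orderCorners(quad)
  ## refine each side with a TLS fit to the edge pixels within 3 px of it
  ## (two passes: the second uses the first pass's improved side lines)
  for (pass in 1:2) {
    lines <- vector("list", 4L)
    for (i in 1:4) {
      a <- quad[i, ]; b <- quad[i %% 4L + 1L, ]
      v <- b - a; len <- sqrt(sum(v^2))
      nrm <- c(-v[2], v[1]) / len
      dist <- abs((edge[, 1] - a[1]) * nrm[1] + (edge[, 2] - a[2]) * nrm[2])
      tpar <- ((edge[, 1] - a[1]) * v[1] + (edge[, 2] - a[2]) * v[2]) / len
      near <- dist <= 3 & tpar >= -3 & tpar <= len + 3
      lines[[i]] <- if (sum(near) >= 2L) tlsLine(edge[near, , drop = FALSE])
                    else tlsLine(rbind(a, b))
    }
    refined <- quad
    for (i in 1:4) {
      p <- lineIntersect(lines[[(i - 2L) %% 4L + 1L]], lines[[i]])
      if (!is.null(p)) refined[i, ] <- p
    }
    if (isConvexQuad(refined)) quad <- orderCorners(refined) else break
  }
  quad
}

#' Rectify a detected strip to the canonical frame
#'
#' Estimates the 4-point direct-linear-transform homography mapping the
#' detected corners onto the canonical rectangle, resamples bilinearly,
#' and linearizes (sRGB decode) the result so all downstream measurement
#' happens in linear intensity.
#'
#' @param img a [StripImage-class].
#' @param corners 4x2 (row, col) corner matrix (any cyclic order; it is
#'   reordered TL, TR, BR, BL internally).
#' @param layout target [StripLayout-class].
#' @return A [RectifiedStrip-class] in linear color space whose
#'   `homography` slot maps source to canonical coordinates.
#' @export
rectify <- function(img, corners, layout = StripLayout()) {
  stopifnot(is(img, "StripImage"))
  corners <- orderCorners(as.matrix(corners))
  if (!isConvexQuad(corners))
    stop("corners are collinear or non-convex: cannot rectify")
  canon <- canonicalCorners(layout)
  Hfwd <- estimateHomography(corners, canon)       # source -> canonical
  Hback <- estimateHomography(canon, corners)      # canonical -> source
  Hh <- layout@height; W <- layout@width
  rr <- rep(seq_len(Hh), W)
  cc <- rep(seq_len(W), each = Hh)
  src <- applyHomography(Hback, cbind(rr, cc))
  vals <- bilinearSample(img@pixels, src[, 1], src[, 2])
  px <- array(vals, c(Hh, W, 3))
  if (img@colorSpace == "srgb") px <- srgbLinearize(px)
  new("RectifiedStrip", pixels = clip01(px), colorSpace = "linear",
      homography = Hfwd)
}

#' Wrap a canonical-frame image as a rectified strip
#'
#' For images already in the canonical frame (e.g. straight from the
#' generator or pre-cropped): linearizes if needed and attaches an
#' identity homography, skipping detection.
#'
#' @param img a [StripImage-class] whose pixel dimensions equal the
#'   canonical frame.
#' @return A [RectifiedStrip-class].
#' @export
asRectified <- function(img) {
  stopifnot(is(img, "StripImage"))
  if (is(img, "RectifiedStrip")) return(img)
  px <- if (img@colorSpace == "srgb") srgbLinearize(img@pixels) else img@pixels
  new("RectifiedStrip", pixels = clip01(px), colorSpace = "linear",
      homography = diag(3))
}

#' Quality-control check of a rectified strip
#'
#' Flags overexposure (fraction of pixels at or above 0.99 in any channel
#' exceeding `overexposureFracMax`) and insufficient reaction (control
#' line's background-corrected absorbance below `cMinContrast`).
#'
#' @param rs a [RectifiedStrip-class].
#' @param layout the [StripLayout-class] it was rectified to.
#' @param cMinContrast minimum control-line intensity (absorbance units).
#' @param overexposureFracMax saturated-pixel fraction above which the
#'   overexposure flag is raised.
#' @return A list of class `"QCReport"`: `overexposedFrac`,
#'   `cLinePresent`, `cIntensity` and `flags` (subset of
#'   `"overexposure"`, `"insufficient reaction"`).
#' @export
qcCheck <- function(rs, layout = StripLayout(), cMinContrast = 0.05,
                    overexposureFracMax = 0.05) {
  stopifnot(is(rs, "RectifiedStrip"))
  sat <- apply(rs@pixels >= 0.99, c(1, 2), any)
  overexposedFrac <- mean(sat)
  prof <- extractProfile(rs, layout)
  w <- lineWindows(layout)["C", ]
  peak <- locateLine(prof, c(w$lo, w$hi))
  m <- measureIntensity(prof, peak, lineWidthPx(layout),
                        flankGapPx(layout))
  cLinePresent <- m$intensity >= cMinContrast
  flags <- character()
  if (overexposedFrac > overexposureFracMax) flags <- c(flags, "overexposure")
  if (!cLinePresent) flags <- c(flags, "insufficient reaction")
  structure(list(overexposedFrac = overexposedFrac,
                 cLinePresent = cLinePresent, cIntensity = m$intensity,
                 flags = flags),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: overexposed %.2f%% | C line %s (I_C = %.4f)\n",
              100 * x$overexposedFrac,
              if (x$cLinePresent) "present" else "ABSENT", x$cIntensity))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
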