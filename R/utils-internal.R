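## Internal numerical utilities: seeded evaluation, homography estimation,
## bilinear resampling, Otsu thresholding, polygon helpers.

## Evaluate expr under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## 4-point direct linear transform with Hartley normalization.
## src, dst: n x 2 (row, col) matrices; returns H acting on (x=col, y=row, 1).
estimateHomography <- function(src, dst) {
  stopifnot(nrow(src) >= 4L, nrow(dst) == nrow(src))
  normalise <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    d <- sqrt((x - mx)^2 + (y - my)^2)
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    list(T = matrix(c(s, 0, -s * mx, 0, s, -s * my, 0, 0, 1), 3, byrow = TRUE),
         x = s * (x - mx), y = s * (y - my))
  }
  a <- normalise(src[, 2], src[, 1])
  b <- normalise(dst[, 2], dst[, 1])
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(a$x[i], a$y[i], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, b$x[i] * X)
    A[2 * i, ]     <- c(0, 0, 0, -X, b$y[i] * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("degenerate point configuration: cannot estimate homography")
  H <- solve(b$T) %*% matrix(sv$v[, 9], 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

## Apply homography to (row, col) points; returns n x 2 (row, col).
applyHomography <- function(H, pts) {
  P <- rbind(pts[, 2], pts[, 1], 1)
  Q <- H %*% P
  cbind(Q[2, ] / Q[3, ], Q[1, ] / Q[3, ])
}

## Vectorized bilinear sampling of an H x W x 3 array at real (r, c);
## coordinates are clamped to the image. Returns length(r) x 3.
bilinearSample <- function(px, r, c) {
  H <- dim(px)[1]; W <- dim(px)[2]
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  out <- matrix(0, length(r), 3)
  for (ch in 1:3) {
    p <- px[, , ch]
    out[, ch] <- w00 * p[cbind(r0, c0)]     + w01 * p[cbind(r0, c0 + 1)] +
                 w10 * p[cbind(r0 + 1, c0)] + w11 * p[cbind(r0 + 1, c0 + 1)]
  }
  out
}

## Otsu threshold on a numeric vector (256-bin histogram).
otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigma2 <- (muT * w - mu)^2 / (w * (1 - w))
  sigma2[!is.finite(sigma2)] <- 0
  mids[which.max(sigma2)]
}

## Shoelace area of an (row, col) polygon (absolute value).
polygonArea <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## TRUE if a 4x2 (row, col) quadrilateral (in cyclic order) is strictly convex.
isConvexQuad <- function(q) {
  if (nrow(q) != 4L) return(FALSE)
  cross <- numeric(4)
  for (i in 1:4) {
    a <- q[i, ]; b <- q[i %% 4 + 1, ]; d <- q[(i + 1) %% 4 + 1, ]
    v1 <- b - a; v2 <- d - b
    cross[i] <- v1[2] * v2[1] - v1[1] * v2[2]
  }
  all(cross > 1e-9) || all(cross < -1e-9)
}

## Order a 4x2 (row, col) quadrilateral clockwise (on screen) from top-left.
orderCorners <- function(q) {
  ctr <- colMeans(q)
  ang <- atan2(q[, 1] - ctr[1], q[, 2] - ctr[2])  # y grows downward
  q <- q[order(ang), , drop = FALSE]              # ascending = clockwise on screen
  start <- which.min(q[, 1] + q[, 2])             # top-left-most corner
  q[((seq_len(4) + start - 2L) %% 4L) + 1L, , drop = FALSE]
}

## Canonical-frame corner coordinates (row, col), TL TR BR BL. The strip
## boundary runs along pixel EDGES (0.5 .. n+0.5), so the detected
## physical boundary maps to the frame edge and every canonical pixel
## center lies strictly inside the strip.
canonicalCorners <- function(layout) {
  H <- layout@height + 0.5; W <- layout@width + 0.5
  matrix(c(0.5, 0.5, 0.5, W, H, W, H, 0.5), 4, 2, byrow = TRUE)
}

## Design matrix for the degree-2 2-D polynomial in centred normalized coords.
shadingDesign <- function(r, c, H, W) {
  u <- (c - 1) / (W - 1) - 0.5
  v <- (r - 1) / (H - 1) - 0.5
  cbind(1, u, v, u^2, u * v, v^2)
}

## Rec. 709 luminance of an n x 3 matrix or H x W x 3 array.
luminance <- function(px) {
  if (is.matrix(px)) return(drop(px %*% c(0.2126, 0.7152, 0.0722)))
  0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}

## Apply a 3x3 matrix to every pixel of an H x W x 3 array.
applyColorMatrix <- function(px, M) {
  d <- dim(px)
  flat <- matrix(px, d[1] * d[2], 3) %*% t(M)
  array(flat, d)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
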