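# Projective geometry helpers: homographies, warping, polygon utilities.
# Points are n x 2 matrices of 0-based (x, y) pixel coordinates.

#' Estimate the homography mapping four source points to four target points
#'
#' Solves the standard direct linear system for the 3x3 projective transform
#' `H` with `H[3,3] = 1` such that `dst ~ H src` in homogeneous coordinates.
#'
#' @param src,dst 4 x 2 matrices of (x, y) coordinates.
#' @return A 3 x 3 matrix.
#' @export
homography_from_points <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate point configuration: homography is not identifiable",
         call. = FALSE)
  })
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography matrix.
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(pts[, 1:2, drop = FALSE][, 1:2])
  P <- cbind(pts, 1) %*% t(H)
  P[, 1:2, drop = FALSE] / P[, 3]
}

# Perspective tilt about the vertical image axis through the canvas center.
# A pinhole model with focal length focal_scale * width; positive angles
# rotate the right edge away from the camera.
tilt_homography <- function(tilt_deg, width, height, focal_scale = 1.8) {
  th <- tilt_deg * pi / 180
  f <- focal_scale * width
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  # centered coords: x' = f x cos(th) / (f + x sin(th)), y' = f y / (...)
  P <- matrix(c(f * cos(th), 0, 0,
                0,           f, 0,
                sin(th),     0, f), 3, 3, byrow = TRUE)
  To <- matrix(c(1, 0, cx, 0, 1, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  Ti <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  H <- To %*% P %*% Ti
  H / H[3, 3]
}

# Warp an image through homography H (input -> output) onto an output canvas
# of the given size, sampling the input bilinearly at H^{-1} of each output
# pixel center. Out-of-bounds samples take the fill color.
warp_image <- function(img, H, out_width, out_height, fill = c(0, 0, 0)) {
  Hin <- solve(H)
  xs <- rep(0:(out_width - 1), each = out_height)
  ys <- rep(0:(out_height - 1), times = out_width)
  P <- cbind(xs, ys, 1) %*% t(Hin)
  sx <- P[, 1] / P[, 3]
  sy <- P[, 2] / P[, 3]
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim = c(out_height, out_width, 3))
  inside <- sx >= 0 & sx <= (w - 1) & sy >= 0 & sy <= (h - 1)
  # clamp corner indices so the arithmetic stays in range; masked after
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    i00 <- plane[cbind(y0c + 1, x0c + 1)]
    i10 <- plane[cbind(y0c + 1, x1c + 1)]
    i01 <- plane[cbind(y1c + 1, x0c + 1)]
    i11 <- plane[cbind(y1c + 1, x1c + 1)]
    val <- (1 - fy) * ((1 - fx) * i00 + fx * i10) +
           fy * ((1 - fx) * i01 + fx * i11)
    val[!inside] <- fill[ch]
    out[, , ch] <- matrix(val, out_height, out_width)
  }
  out
}

# Least-squares homography (normalized DLT) for n >= 4 correspondences.
homography_fit_ls <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    Tm <- matrix(c(sc, 0, -sc * mu[1], 0, sc, -sc * mu[2], 0, 0, 1),
                 3, 3, byrow = TRUE)
    list(p = cbind(p, 1) %*% t(Tm), T = Tm)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ns$p[i, ]; u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ]     <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H / H[3, 3]
}

# Distance from point p to segment (a, b); all length-2 (x, y) vectors.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# Area centroid of a simple polygon (n x 2, vertices in order).
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) stop("zero-area polygon", call. = FALSE)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Canonicalize a 4-point quad to order TL, TR, BR, BL (y grows downward).
order_quad <- function(pts) {
  s <- pts[, 1] + pts[, 2]
  d <- pts[, 1] - pts[, 2]
  rbind(
    pts[which.min(s), ],   # top-left
    pts[which.max(d), ],   # top-right
    pts[which.max(s), ],   # bottom-right
    pts[which.min(d), ]    # bottom-left
  )
}
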