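# Geometric resampling primitives shared by capture simulation, registration
# and model preparation. All warps go through one projective bilinear
# resampler; resize uses exact separable weights (area overlap when
# downscaling, bilinear when upscaling) so that same-size resampling is the
# identity bit-for-bit.

#' Resample a grayscale raster to a square size
#'
#' Downscaling uses exact area averaging (each output pixel is the mean of
#' the input area it covers); upscaling uses bilinear interpolation.
#' Resampling to the current size returns the input unchanged.
#'
#' @param img Numeric matrix.
#' @param out_size Output side in pixels.
#' @return Numeric matrix `out_size` x `out_size`.
#' @export
resample_image <- function(img, out_size) {
  m <- unclass(img)
  wr <- .resample_weights(nrow(m), out_size)
  wc <- .resample_weights(ncol(m), out_size)
  wr %*% m %*% t(wc)
}

.resample_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  w <- matrix(0, n_out, n_in)
  f <- n_in / n_out
  if (n_out < n_in) {           # area average: overlap of [i f, (i+1) f)
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * f
      hi <- i * f
      j <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
      ov <- pmin(hi, j + 1) - pmax(lo, j)
      w[i, j + 1] <- ov / f
    }
  } else {                      # bilinear on pixel centres
    for (i in seq_len(n_out)) {
      x <- (i - 0.5) * f - 0.5  # 0-based input centre
      x0 <- max(0, min(n_in - 1, floor(x)))
      x1 <- min(n_in - 1, x0 + 1)
      t1 <- x - x0
      w[i, x0 + 1] <- w[i, x0 + 1] + (1 - t1)
      w[i, x1 + 1] <- w[i, x1 + 1] + t1
    }
  }
  w
}

# Apply a 3x3 homography H mapping OUTPUT (x, y, 1) to INPUT coordinates
# (x = column, y = row, both 1-based pixel centres), sampling bilinearly.
# Points falling outside the input are filled with `fill`.
.warp_projective <- function(img, H, out_dim = dim(img), fill = 255) {
  m <- unclass(img)
  h_in <- nrow(m); w_in <- ncol(m)
  h_out <- out_dim[1]; w_out <- out_dim[2]
  xo <- rep(seq_len(w_out), each = h_out)
  yo <- rep(seq_len(h_out), times = w_out)
  d <- H[3, 1] * xo + H[3, 2] * yo + H[3, 3]
  xi <- (H[1, 1] * xo + H[1, 2] * yo + H[1, 3]) / d
  yi <- (H[2, 1] * xo + H[2, 2] * yo + H[2, 3]) / d
  eps <- 1e-6
  ok <- xi >= 1 - eps & xi <= w_in + eps & yi >= 1 - eps & yi <= h_in + eps
  # clamp so points on the far border interpolate onto the last pixel exactly
  x0 <- pmin(pmax(floor(xi), 1), w_in - 1)
  y0 <- pmin(pmax(floor(yi), 1), h_in - 1)
  tx <- pmin(pmax(xi - x0, 0), 1); ty <- pmin(pmax(yi - y0, 0), 1)
  i00 <- (x0 - 1) * h_in + y0
  v <- (1 - tx) * (1 - ty) * m[i00] +
       tx * (1 - ty) * m[i00 + h_in] +
       (1 - tx) * ty * m[i00 + 1] +
       tx * ty * m[i00 + h_in + 1]
  v[!ok] <- fill
  matrix(v, h_out, w_out)
}

# Homography for an in-plane rotation of the image content by `deg`
# (counterclockwise on screen) about the image centre; returns the inverse
# map (output -> input) used by the resampler.
.rotation_homography <- function(deg, size) {
  th <- -deg * pi / 180  # y runs down: negate so positive deg is ccw on screen
  c0 <- (size + 1) / 2
  # y axis points down, so a visually counterclockwise rotation is R(-th)
  # in math coordinates; the inverse map applies R(th).
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  H <- diag(3)
  H[1:2, 1:2] <- R
  H[1:2, 3] <- c(c0, c0) - R %*% c(c0, c0)
  H
}

# Homography mapping the unit square corners `to` back onto `from`
# (both 4x2 matrices of (x, y)); direct linear transform with h33 = 1.
.homography_from_corners <- function(from, to) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- to[i, 1]; y <- to[i, 2]
    u <- from[i, 1]; v <- from[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -x * v, -y * v)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Affine transform (3x3, last row 0 0 1) mapping three (x, y) points `from`
# onto `to`; errors on collinear points.
.affine_from_points <- function(from, to) {
  M <- cbind(from, 1)
  if (abs(det(M)) < 1e-8 || abs(det(cbind(to, 1))) < 1e-8) {
    stop("degenerate (collinear) point configuration")
  }
  # solve for [a b c; d e f] with to = A %*% [x y 1]'
  coefs <- solve(M, to)          # 3x2: columns are (a, b, c) and (d, e, f)
  rbind(t(coefs), c(0, 0, 1))
}

# Run `expr` under a temporary R RNG seed, restoring global state after.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
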