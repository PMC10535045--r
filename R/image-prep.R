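#' Binarize an entropy image
#'
#' Thresholds a grayscale image into the aggregate (foreground = 1) and
#' background classes. Comparison happens on the foreground-side intensity
#' scale `s`: for the default `polarity = "dark"` (dark bioink on a light
#' film) `s = 255 - intensity`, for `polarity = "light"` `s = intensity`, so
#' inverting an image together with its polarity flag yields the identical
#' result.
#'
#' Methods:
#' * `"otsu"` — threshold maximizing the between-class variance of the
#'   256-bin histogram; ties resolved to the lowest level; foreground is
#'   `s > threshold`. A constant image yields the all-background raster with
#'   the `degenerate` flag set.
#' * `"global"` — fixed level `param`; foreground is `s >= param` (so
#'   `param = 0` marks every pixel foreground).
#' * `"adaptive"` — per-pixel comparison of `s` with the mean of the
#'   surrounding square frame of odd side `param` (default 31), truncated at
#'   the image border; foreground is `s >` local mean.
#'
#' @param image An [aggregate_image()] or numeric matrix on `[0, 255]`.
#' @param method `"otsu"`, `"global"` or `"adaptive"`.
#' @param param Threshold level (global) or odd frame size `>= 3` (adaptive).
#' @param polarity `"dark"` if the aggregate is the darker class.
#' @return A [binary_image()]; its `threshold` attribute is on the `s` scale.
#' @examples
#' img <- aggregate_image(matrix(c(10, 200)[1 + (row(diag(8)) > 4)], 8, 8))
#' binarize(img, "otsu")
#' @export
binarize <- function(image, method = c("otsu", "global", "adaptive"),
                     param = NULL, polarity = c("dark", "light")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  m <- unclass(image)
  if (!is.matrix(m) || !is.numeric(m)) stop("image must be a numeric matrix")
  s <- if (polarity == "dark") 255 - m else m

  if (method == "otsu") {
    if (min(s) == max(s)) {
      return(binary_image(matrix(0L, nrow(s), ncol(s)), threshold = NA_real_,
                          method = "otsu", polarity = polarity,
                          degenerate = TRUE))
    }
    t_s <- otsu_threshold(s)
    px <- (s > t_s) * 1L
    return(binary_image(px, threshold = t_s, method = "otsu",
                        polarity = polarity))
  }

  if (method == "global") {
    if (is.null(param)) stop("global thresholding requires param = level")
    px <- (s >= param) * 1L
    return(binary_image(px, threshold = param, method = "global",
                        polarity = polarity))
  }

  # adaptive
  frame <- if (is.null(param)) 31L else as.integer(param)
  if (frame %% 2 == 0) stop("adaptive frame size must be odd")
  if (frame < 3) stop("adaptive frame size must be >= 3")
  px <- (s > .box_mean(s, frame)) * 1L
  binary_image(px, threshold = NA_real_, method = "adaptive",
               polarity = polarity)
}

#' Otsu threshold of a grayscale matrix
#'
#' Cumulative-moment scan over the 256-bin histogram of the (rounded) values;
#' returns the level `t` in `0..254` maximizing the between-class variance of
#' the split into `{<= t}` and `{> t}`, lowest level on ties.
#'
#' @param s Numeric matrix with values in `[0, 255]`.
#' @return Integer threshold level.
#' @export
otsu_threshold <- function(s) {
  counts <- tabulate(as.integer(round(s)) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu[1:255])^2
  sigma_b <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), -Inf)
  which.max(sigma_b) - 1L  # which.max takes the first (lowest) maximizer
}

.box_mean <- function(s, frame) {
  h <- frame %/% 2
  nr <- nrow(s); nc <- ncol(s)
  # integral image with a zero border
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- apply(apply(s, 2, cumsum), 1, cumsum) |> t()
  r1 <- as.vector(pmax(row(s) - h, 1)); r2 <- as.vector(pmin(row(s) + h, nr))
  c1 <- as.vector(pmax(col(s) - h, 1)); c2 <- as.vector(pmin(col(s) + h, nc))
  tot <- ii[cbind(r2 + 1, c2 + 1)] - ii[cbind(r1, c2 + 1)] -
    ii[cbind(r2 + 1, c1)] + ii[cbind(r1, c1)]
  matrix(tot / ((r2 - r1 + 1) * (c2 - c1 + 1)), nr, nc)
}

#' Fiducial layout specification
#'
#' Three corner glyphs ("+" or "C") mark the top-left, top-right and
#' bottom-left corners of a label; the unmarked bottom-right corner makes the
#' orientation unambiguous.
#'
#' @param markers Named character vector mapping the corners `top_left`,
#'   `top_right`, `bottom_left` to glyphs `"plus"` or `"C"`.
#' @param glyph_size Glyph side in pixels (default 32).
#' @param margin Distance from the image border to the glyph window
#'   (default 24, deep enough that a few degrees of capture tilt cannot
#'   sweep a corner glyph out of frame).
#' @return A `fiducial_spec`.
#' @export
fiducial_spec <- function(markers = c(top_left = "plus", top_right = "C",
                                      bottom_left = "plus"),
                          glyph_size = 32L, margin = 24L) {
  corners <- c("top_left", "top_right", "bottom_left")
  if (!setequal(names(markers), corners)) {
    stop("markers must name exactly the corners top_left, top_right, bottom_left")
  }
  if (!all(markers %in% c("plus", "C"))) stop("glyphs must be 'plus' or 'C'")
  structure(list(markers = markers[corners], glyph_size = as.integer(glyph_size),
                 margin = as.integer(margin)),
            class = "fiducial_spec")
}

#' Glyph raster
#' @param glyph `"plus"` or `"C"`.
#' @param size Side in pixels.
#' @return 0/1 matrix of the glyph.
#' @export
glyph_mask <- function(glyph = c("plus", "C"), size = 24L) {
  glyph <- match.arg(glyph)
  size <- as.integer(size)
  g <- matrix(0L, size, size)
  ctr <- (size + 1) / 2
  arm <- max(2L, round(size / 6))
  if (glyph == "plus") {
    band <- abs(seq_len(size) - ctr) <= arm / 2
    g[band, ] <- 1L
    g[, band] <- 1L
  } else {
    r_out <- size / 2 - 0.5
    r_in <- r_out - arm
    d <- sqrt((row(g) - ctr)^2 + (col(g) - ctr)^2)
    ring <- d <= r_out & d >= r_in
    gap <- col(g) > ctr & abs(row(g) - ctr) <= size / 5  # opening to the right
    g[ring & !gap] <- 1L
  }
  g
}

.corner_window <- function(corner, spec, size) {
  gs <- spec$glyph_size; mg <- spec$margin
  switch(corner,
    top_left = list(rows = mg + seq_len(gs), cols = mg + seq_len(gs)),
    top_right = list(rows = mg + seq_len(gs), cols = size - mg - gs + seq_len(gs)),
    bottom_left = list(rows = size - mg - gs + seq_len(gs), cols = mg + seq_len(gs)),
    bottom_right = list(rows = size - mg - gs + seq_len(gs),
                        cols = size - mg - gs + seq_len(gs)))
}

#' Canonical fiducial centres
#' @param spec A [fiducial_spec()].
#' @param size Image side in pixels.
#' @return Tibble with `corner`, `glyph`, `x`, `y` (1-based pixel centres).
#' @export
fiducial_centers <- function(spec, size) {
  rows <- lapply(names(spec$markers), function(corner) {
    w <- .corner_window(corner, spec, size)
    tibble::tibble(corner = corner, glyph = unname(spec$markers[corner]),
                   x = mean(range(w$cols)), y = mean(range(w$rows)))
  })
  dplyr::bind_rows(rows)
}

#' Stamp fiducial markers onto a binarized label
#'
#' Overwrites the three reserved corner windows with the glyph rasters;
#' every pixel outside those windows is untouched, so stamping is idempotent.
#'
#' @param image A [binary_image()].
#' @param spec A [fiducial_spec()].
#' @return The stamped [binary_image()].
#' @export
place_fiducials <- function(image, spec = fiducial_spec()) {
  px <- unclass(image)
  size <- nrow(px)
  if (ncol(px) != size) stop("fiducial stamping expects a square image")
  if (2 * (spec$margin + spec$glyph_size) > size) {
    stop("glyph_size + margin does not fit inside the image")
  }
  for (corner in names(spec$markers)) {
    w <- .corner_window(corner, spec, size)
    px[w$rows, w$cols] <- glyph_mask(spec$markers[corner], spec$glyph_size)
  }
  binary_image(px, threshold = attr(image, "threshold"),
               method = attr(image, "method"),
               polarity = attr(image, "polarity"))
}

#' Blank the fiducial windows of a label
#'
#' Used before feeding the label to the feature extractor so the derived key
#' depends only on the PUF pattern, not the printed markers.
#'
#' @inheritParams place_fiducials
#' @return The [binary_image()] with all three corner windows set to 0.
#' @export
strip_fiducials <- function(image, spec = fiducial_spec()) {
  px <- unclass(image)
  size <- nrow(px)
  for (corner in names(spec$markers)) {
    w <- .corner_window(corner, spec, size)
    px[w$rows, w$cols] <- 0L
  }
  binary_image(px, threshold = attr(image, "threshold"),
               method = attr(image, "method"),
               polarity = attr(image, "polarity"))
}

#' Simulate a phone capture of a printed label
#'
#' Applies, in order: in-plane rotation about the centre, random perspective
#' displacement of the four corners (up to `perspective_jitter` of the side),
#' Gaussian blur, a linear illumination ramp of relative amplitude
#' `illum_gradient` in a random direction, additive Gaussian sensor noise,
#' and resampling to `out_size`. The rotation and perspective warps are
#' composed into a single homography so the content is resampled once.
#' Deterministic under `rng_seed`; the global RNG state is preserved.
#'
#' @param image A [binary_image()] (rendered as dark ink on a light film) or
#'   an [aggregate_image()].
#' @param rotation_deg Rotation of the content, counterclockwise on screen.
#' @param perspective_jitter Corner displacement as a fraction of the side.
#' @param blur_sigma Gaussian blur width in pixels.
#' @param illum_gradient Relative amplitude of the illumination ramp.
#' @param noise_sd Gaussian noise standard deviation in intensity units.
#' @param out_size Output side in pixels (>= 64).
#' @param rng_seed Seed for the capture's randomness.
#' @return An [aggregate_image()].
#' @export
simulate_capture <- function(image, rotation_deg = 0, perspective_jitter = 0,
                             blur_sigma = 0, illum_gradient = 0, noise_sd = 0,
                             out_size = nrow(image), rng_seed = 1L) {
  stopifnot(perspective_jitter >= 0, blur_sigma >= 0, illum_gradient >= 0,
            noise_sd >= 0, out_size >= 64)
  src <- if (inherits(image, "binary_image")) {
    (1 - unclass(image)) * 255
  } else {
    unclass(image) * 1.0
  }
  n <- nrow(src)
  .with_seed(rng_seed, {
    H <- NULL
    if (rotation_deg != 0) H <- .rotation_homography(rotation_deg, n)
    if (perspective_jitter > 0) {
      base <- cbind(c(1, n, n, 1), c(1, 1, n, n))
      jit <- base + matrix(stats::runif(8, -1, 1) * perspective_jitter * n, 4, 2)
      Hp <- .homography_from_corners(base, jit)
      H <- if (is.null(H)) Hp else H %*% Hp
    }
    out <- if (is.null(H)) src else .warp_projective(src, H, fill = 255)
    if (blur_sigma > 0) {
      out <- EBImage::imageData(EBImage::gblur(EBImage::Image(out),
                                               sigma = blur_sigma))
    }
    if (illum_gradient > 0) {
      psi <- stats::runif(1, 0, 2 * pi)
      u <- (cos(psi) * col(out) + sin(psi) * row(out))
      u <- (u - min(u)) / (max(u) - min(u))
      out <- out * (1 + illum_gradient * (u - 0.5))
    }
    if (noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), 0, noise_sd),
                          nrow(out), ncol(out))
    }
    out <- pmin(pmax(out, 0), 255)
    if (out_size != n) out <- resample_image(out, out_size)
    aggregate_image(round(out))
  })
}

#' Prepare an image for the feature extractor
#'
#' Resamples to `side` x `side` (area average when shrinking, bilinear when
#' enlarging), maps intensities to the canonical `[0, 1]` input range with
#' the aggregate bright (binary foreground -> 1; grayscale is assumed
#' aggregate-dark and inverted), applies a fixed Gaussian stabilization blur
#' (`smooth_sigma`, in pixels at the model scale) so the downstream feature
#' code tolerates sub-pixel registration error of re-captured labels, and
#' replicates the single channel to three. Deterministic, and idempotent on
#' an already prepared raster of the same side (the blur is not re-applied).
#'
#' @param image A [binary_image()], [aggregate_image()], or a model raster.
#' @param side Backbone input side (default 224).
#' @param smooth_sigma Stabilization blur width (default 3; 0 disables).
#' @return A `model_raster`: numeric array `side` x `side` x 3 in `[0, 1]`.
#' @export
prepare_for_model <- function(image, side = 224L, smooth_sigma = 3) {
  if (inherits(image, "model_raster")) {
    ch <- unclass(image)[, , 1]
    smooth_sigma <- 0  # already prepared: keep the operation idempotent
  } else if (inherits(image, "binary_image")) {
    ch <- unclass(image) * 1.0
  } else {
    m <- unclass(image)
    if (!is.matrix(m) || length(m) == 0) stop("empty or non-matrix image")
    ch <- 1 - m / 255  # aggregate-dark grayscale -> bright foreground
  }
  if (length(ch) == 0) stop("empty image")
  ch <- resample_image(ch, side)
  if (smooth_sigma > 0) {
    ch <- EBImage::imageData(EBImage::gblur(EBImage::Image(ch),
                                            sigma = smooth_sigma))
    ch <- pmin(pmax(ch, 0), 1)  # gblur ringing can step just outside [0, 1]
  }
  structure(array(ch, dim = c(side, side, 3)), class = "model_raster")
}
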