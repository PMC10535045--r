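#' Detect fiducial markers in a captured label
#'
#' Normalized template correlation of the corner glyphs against the capture,
#' evaluated at the four candidate 90-degree orientations; the asymmetric
#' three-corner layout (bottom-right unmarked) resolves the orientation
#' uniquely. Each glyph is searched in a window around its expected corner
#' position; the orientation with the highest total correlation wins, and
#' detected centres are mapped back to the original capture frame.
#'
#' @param capture An [aggregate_image()] (dark glyphs on a light background).
#' @param spec The [fiducial_spec()] the label was stamped with.
#' @param min_score Minimum acceptable per-glyph correlation.
#' @param search_slack Half-width of the search window beyond the glyph, in
#'   pixels (default: glyph size + margin).
#' @return A tibble with columns `corner`, `glyph`, `x`, `y`, `score`, plus
#'   attributes `orientation` (degrees) and `spec`.
#' @export
detect_fiducials <- function(capture, spec = fiducial_spec(),
                             min_score = 0.35, search_slack = NULL) {
  img <- unclass(capture)
  size <- nrow(img)
  if (ncol(img) != size) stop("capture must be square")
  if (is.null(search_slack)) search_slack <- spec$glyph_size + spec$margin
  dark <- 255 - img  # glyphs are dark: correlate on the darkness scale
  centers <- fiducial_centers(spec, size)
  templates <- lapply(stats::setNames(nm = c("plus", "C")), function(g) {
    t0 <- glyph_mask(g, spec$glyph_size)
    t0 - mean(t0)
  })

  best <- NULL
  for (orient in c(0L, 90L, 180L, 270L)) {
    rot <- .rot90k(dark, orient %/% 90L)
    dets <- lapply(seq_len(nrow(centers)), function(i) {
      .match_glyph(rot, templates[[centers$glyph[i]]],
                   centers$x[i], centers$y[i], search_slack)
    })
    total <- sum(vapply(dets, function(d) d$score, numeric(1)))
    if (is.null(best) || total > best$total) {
      best <- list(total = total, orientation = orient, dets = dets)
    }
  }

  scores <- vapply(best$dets, function(d) d$score, numeric(1))
  if (any(scores < min_score)) {
    stop(sprintf(
      "fewer than three confident fiducial detections (best orientation %d): %s",
      best$orientation,
      paste(sprintf("%s@%s=%.2f", centers$glyph, centers$corner, scores),
            collapse = ", ")))
  }
  # map detected coordinates from the derotated frame back to the capture
  out <- dplyr::bind_rows(lapply(seq_len(nrow(centers)), function(i) {
    p <- .unrot90k(best$dets[[i]]$x, best$dets[[i]]$y, best$orientation %/% 90L,
                   size)
    tibble::tibble(corner = centers$corner[i], glyph = centers$glyph[i],
                   x = p[1], y = p[2], score = scores[i])
  }))
  attr(out, "orientation") <- best$orientation
  attr(out, "spec") <- spec
  out
}

# Rotate a matrix by k * 90 degrees counterclockwise (exact permutation).
.rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  if (k == 1L) return(t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
  if (k == 2L) return(m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
  t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
}

# Map a point (x, y) in the k*90-degree-derotated frame back to the capture.
.unrot90k <- function(x, y, k, size) {
  k <- k %% 4L
  if (k == 0L) return(c(x, y))
  if (k == 1L) return(c(size + 1 - y, x))       # inverse of ccw rotation
  if (k == 2L) return(c(size + 1 - x, size + 1 - y))
  c(y, size + 1 - x)
}

# Normalized cross-correlation of a zero-mean template over a search window
# centred at (cx, cy); returns the best score and its centre coordinates.
.match_glyph <- function(dark, t0, cx, cy, slack) {
  g <- nrow(t0)
  size <- nrow(dark)
  half <- (g - 1) / 2
  r1 <- max(1, floor(cy - half - slack)); r2 <- min(size, ceiling(cy + half + slack))
  c1 <- max(1, floor(cx - half - slack)); c2 <- min(size, ceiling(cx + half + slack))
  win <- dark[r1:r2, c1:c2, drop = FALSE]
  nr <- nrow(win) - g + 1L
  nc <- ncol(win) - g + 1L
  if (nr < 1 || nc < 1) return(list(score = -Inf, x = cx, y = cy))
  base <- rep(seq_len(nr), times = nc) + (rep(seq_len(nc), each = nr) - 1) * nrow(win)
  off <- as.vector(outer(0:(g - 1), (0:(g - 1)) * nrow(win), "+"))
  patches <- matrix(win[outer(base, off, "+")], length(base), length(off))
  num <- as.vector(patches %*% as.vector(t0))   # t0 is zero-mean
  k <- g * g
  ss <- rowSums(patches^2) - rowSums(patches)^2 / k
  den <- sqrt(pmax(ss, 1e-12) * sum(t0^2))
  score <- num / den
  i <- which.max(score)
  r <- (i - 1) %% nr + 1L
  c <- (i - 1) %/% nr + 1L
  sc <- matrix(score, nr, nc)
  # subpixel refinement: quadratic fit through the peak and its neighbours
  dx <- dy <- 0
  if (r > 1 && r < nr) {
    a <- sc[r - 1, c]; b0 <- sc[r, c]; cc_ <- sc[r + 1, c]
    den2 <- a - 2 * b0 + cc_
    if (den2 < 0) dy <- 0.5 * (a - cc_) / den2
  }
  if (c > 1 && c < nc) {
    a <- sc[r, c - 1]; b0 <- sc[r, c]; cc_ <- sc[r, c + 1]
    den2 <- a - 2 * b0 + cc_
    if (den2 < 0) dx <- 0.5 * (a - cc_) / den2
  }
  list(score = score[i],
       x = c1 + (c - 1) + half + max(-1, min(1, dx)),
       y = r1 + (r - 1) + half + max(-1, min(1, dy)))
}

#' Register a capture to the canonical label frame
#'
#' Solves the affine transform taking the three canonical fiducial centres
#' to the detected ones and resamples the capture onto the canonical grid.
#'
#' @param capture An [aggregate_image()].
#' @param detections Output of [detect_fiducials()] (three non-collinear
#'   points; carries the fiducial spec).
#' @param canonical_size Side of the canonical frame in pixels.
#' @return An [aggregate_image()] of side `canonical_size`.
#' @export
register_capture <- function(capture, detections, canonical_size) {
  spec <- attr(detections, "spec")
  if (is.null(spec)) stop("detections must come from detect_fiducials()")
  canon <- fiducial_centers(spec, canonical_size)
  canon <- canon[match(detections$corner, canon$corner), ]
  A <- .affine_from_points(as.matrix(canon[, c("x", "y")]),
                           as.matrix(detections[, c("x", "y")]))
  out <- .warp_projective(unclass(capture), A,
                          out_dim = c(canonical_size, canonical_size),
                          fill = 255)
  aggregate_image(round(pmin(pmax(out, 0), 255)))
}

#' Bitwise percent match between two bit vectors
#'
#' `100 * (matching positions / length)`; equivalently
#' `100 * (1 - normalized Hamming distance)`. Symmetric in its arguments.
#'
#' @param enrolled,probe Equal-length, equal-stage [bit_vector()]s (the
#'   pipeline compares the full-length biased vectors, not the derived keys,
#'   because Von Neumann pair positions are fragile under capture noise).
#' @param threshold Accept threshold in percent.
#' @return A `match_result` with `device_id`, `percent_match`,
#'   `compared_length`, `decision`, `threshold`.
#' @export
percent_match <- function(enrolled, probe, threshold = 85) {
  if (length(enrolled) != length(probe)) {
    stop(sprintf("bit vector length mismatch: %d vs %d", length(enrolled),
                 length(probe)))
  }
  if (inherits(enrolled, "bit_vector") && inherits(probe, "bit_vector") &&
      bit_stage(enrolled) != bit_stage(probe)) {
    stop("bit vectors must be at the same pipeline stage")
  }
  pct <- 100 * mean(as.integer(enrolled) == as.integer(probe))
  structure(list(device_id = attr(enrolled, "source_id") %||% NA_character_,
                 percent_match = pct, compared_length = length(enrolled),
                 decision = if (pct >= threshold) "accept" else "reject",
                 threshold = threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: %.1f%% over %d bits -> %s (threshold %g%%)\n",
              x$device_id, x$percent_match, x$compared_length, x$decision,
              x$threshold))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.match_result <- function(x, ...) {
  tibble::tibble(device_id = x$device_id, percent_match = x$percent_match,
                 compared_length = x$compared_length, decision = x$decision,
                 threshold = x$threshold)
}

#' Authenticate a captured label against an enrolled device
#'
#' Full validation path: detect the fiducials, register the capture to the
#' canonical frame, re-binarize, strip the fiducial windows, re-run the
#' identical backbone recorded at enrollment, quantize, and score the
#' bitwise percent match of the probe's biased vector against the claimed
#' device's enrolled biased vector.
#'
#' @param capture An [aggregate_image()] (e.g. from [simulate_capture()] or
#'   [read_image()]).
#' @param library A `device_library`.
#' @param claimed_id Device id being claimed.
#' @param threshold Accept threshold in percent (default 85, sitting below
#'   the genuine-match range observed for printed labels).
#' @return A `match_result`.
#' @export
authenticate <- function(capture, library, claimed_id, threshold = 85) {
  row <- which(library$devices$device_id == claimed_id)
  if (length(row) != 1) stop("unknown device id: ", claimed_id)
  det <- detect_fiducials(capture, library$fiducials)
  reg <- register_capture(capture, det, library$canonical_size)
  bin <- binarize(reg, method = library$binarize_method,
                  param = library$binarize_param,
                  polarity = library$polarity)
  probe <- digitize_image(strip_fiducials(bin, library$fiducials),
                          backbone = library$backbone,
                          source_id = claimed_id)
  res <- percent_match(library$devices$biased[[row]], probe$biased,
                       threshold = threshold)
  res$device_id <- claimed_id
  res
}
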