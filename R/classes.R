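#' Construct an aggregate image
#'
#' An `aggregate_image` is the grayscale entropy-source raster: either a
#' rendered DLA cluster or a loaded micrograph. Pixels are stored as a numeric
#' matrix on the 8-bit scale `[0, 255]`, rows indexing image rows.
#'
#' @param pixels Numeric matrix with values in `[0, 255]`.
#' @return An `aggregate_image` object.
#' @export
aggregate_image <- function(pixels) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  structure(unname(pixels), class = c("aggregate_image", "matrix"))
}

#' @export
print.aggregate_image <- function(x, ...) {
  cat(sprintf("<aggregate_image> %d x %d, intensity range [%g, %g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Construct a binary image
#'
#' A thresholded raster with foreground (aggregate) pixels equal to 1. Carries
#' the threshold level, the method that produced it, and the foreground
#' polarity of the source (`"dark"` if the aggregate is the darker class,
#' the default for dark bioink on a light film).
#'
#' @param pixels Integer/logical matrix of 0/1 values.
#' @param threshold Intensity level used (NA for adaptive thresholding).
#' @param method One of `"otsu"`, `"global"`, `"adaptive"`, `"mask"`.
#' @param polarity `"dark"` or `"light"`: which intensity class is foreground.
#' @param degenerate Logical flag set when the source was constant and the
#'   result is all background.
#' @return A `binary_image` object.
#' @export
binary_image <- function(pixels, threshold = NA_real_, method = "mask",
                         polarity = "dark", degenerate = FALSE) {
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  if (any(pixels != 0L & pixels != 1L)) stop("binary image pixels must be 0 or 1")
  structure(unname(pixels),
            threshold = threshold, method = method, polarity = polarity,
            degenerate = degenerate,
            class = c("binary_image", "matrix"))
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf(
    "<binary_image> %d x %d, method=%s, threshold=%s, foreground=%d px (%.1f%%)\n",
    nrow(x), ncol(x), attr(x, "method"), format(attr(x, "threshold")),
    sum(x), 100 * mean(x)))
  invisible(x)
}

#' Construct a bit vector
#'
#' Ordered bit sequence tagged with its pipeline stage: `"biased"` straight
#' from quantization, `"debiased"` after Von Neumann extraction, or `"key"`
#' after key derivation.
#'
#' @param bits Integer vector of 0/1 values.
#' @param stage One of `"biased"`, `"debiased"`, `"key"`.
#' @param source_id Optional device identifier.
#' @return A `bit_vector` object.
#' @export
bit_vector <- function(bits, stage = c("biased", "debiased", "key"),
                       source_id = NULL) {
  stage <- match.arg(stage)
  bits <- as.integer(bits)
  if (length(bits) && any(bits != 0L & bits != 1L)) stop("bits must be 0 or 1")
  structure(bits, stage = stage, source_id = source_id,
            class = "bit_vector")
}

#' @export
print.bit_vector <- function(x, ...) {
  n <- length(x)
  head_bits <- paste(unclass(x)[seq_len(min(n, 32))], collapse = "")
  cat(sprintf("<bit_vector:%s> %d bits%s %s%s\n",
              attr(x, "stage"), n,
              if (is.null(attr(x, "source_id"))) "" else
                paste0(" [", attr(x, "source_id"), "]"),
              head_bits, if (n > 32) "..." else ""))
  invisible(x)
}

#' @export
format.bit_vector <- function(x, ...) paste(unclass(x), collapse = "")

#' Bit-vector stage accessor
#' @param x A `bit_vector`.
#' @return The stage tag, one of `"biased"`, `"debiased"`, `"key"`.
#' @export
bit_stage <- function(x) attr(x, "stage")

#' Encode a key as lowercase hex
#'
#' Bits are packed most-significant-bit first into bytes; the bit length must
#' be a multiple of 8 (always true for 64/128/256-bit keys).
#'
#' @param x A `bit_vector`.
#' @return Lowercase hexadecimal string.
#' @export
bits_to_hex <- function(x) {
  b <- as.integer(x)
  if (length(b) %% 8 != 0) stop("bit length must be a multiple of 8")
  bytes <- vapply(split(b, rep(seq_len(length(b) / 8), each = 8)),
                  function(byte) sum(byte * 2^(7:0)), numeric(1))
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

#' Decode a lowercase hex string into a key bit vector
#' @param hex Hexadecimal string.
#' @param source_id Optional device identifier.
#' @return A `bit_vector` with stage `"key"`.
#' @export
hex_to_bits <- function(hex, source_id = NULL) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
                  base = 16L)
  bits <- unlist(lapply(bytes, function(v) as.integer(intToBits(v)[8:1])))
  bit_vector(bits, stage = "key", source_id = source_id)
}
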