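#' Quantize a feature vector into a biased bit vector
#'
#' The threshold is the mean of the feature values; each feature strictly
#' above the mean maps to 1, features at or below it map to 0. The output has
#' one bit per feature, so a constant vector legally quantizes to all zeros.
#'
#' @param features A `feature_vector` (or numeric vector) of length >= 2.
#' @param source_id Optional device identifier carried on the bits.
#' @return A [bit_vector()] with stage `"biased"`.
#' @examples
#' quantize(c(1, 2, 3))  # threshold 2 -> bits 001
#' @export
quantize <- function(features, source_id = NULL) {
  x <- as.numeric(features)
  if (length(x) < 2) stop("need at least 2 features to quantize")
  eps <- mean(x)
  bit_vector(as.integer(x > eps), stage = "biased", source_id = source_id)
}

#' Von Neumann randomness extraction
#'
#' Consumes the biased sequence as non-overlapping consecutive pairs from the
#' start: the pair (0, 1) emits 1, (1, 0) emits 0, and (0, 0) / (1, 1) are
#' discarded. A trailing unpaired bit is dropped. If the input bits are
#' independent with any fixed bias, the emitted bits are unbiased.
#'
#' @param biased A [bit_vector()] with stage `"biased"`.
#' @return A [bit_vector()] with stage `"debiased"` (variable length, at most
#'   half the input length).
#' @examples
#' von_neumann_extract(bit_vector(c(0, 1, 1, 0, 0, 1, 0, 0)))  # 101
#' @export
von_neumann_extract <- function(biased) {
  if (inherits(biased, "bit_vector") && bit_stage(biased) != "biased") {
    stop("von_neumann_extract expects a stage='biased' bit vector")
  }
  b <- as.integer(biased)
  n2 <- length(b) %/% 2
  first <- b[2 * seq_len(n2) - 1]
  second <- b[2 * seq_len(n2)]
  out <- second[first != second]  # (0,1) -> 1, (1,0) -> 0
  bit_vector(out, stage = "debiased",
             source_id = attr(biased, "source_id"))
}

#' Derive fixed-size keys from a set of debiased vectors
#'
#' The key size is the largest standard length (64, 128 or 256 bits) not
#' exceeding the shortest debiased vector in the set; every key is the
#' leading `key_size` bits of its debiased vector. Devices whose debiased
#' vector is shorter than 64 bits are an error (they cannot be keyed) and
#' are named in the message.
#'
#' @param debiased_set List of [bit_vector()]s with stage `"debiased"`.
#' @return A list with `keys` (list of stage-`"key"` bit vectors) and
#'   `key_size`.
#' @examples
#' d <- lapply(1:3, function(i) bit_vector(rep(0:1, 70), stage = "debiased"))
#' derive_keys(d)$key_size  # 128
#' @export
derive_keys <- function(debiased_set) {
  if (length(debiased_set) == 0) stop("debiased_set must be non-empty")
  lens <- vapply(debiased_set, length, integer(1))
  sizes <- c(64L, 128L, 256L)
  if (min(lens) < 64L) {
    bad <- which(lens < 64L)
    ids <- vapply(seq_along(bad), function(i) {
      id <- attr(debiased_set[[bad[i]]], "source_id")
      if (is.null(id)) paste0("#", bad[i]) else id
    }, character(1))
    stop("debiased vector(s) shorter than the smallest standard key size ",
         "(64 bits): ", paste0(ids, " (", lens[bad], " bits)", collapse = ", "))
  }
  key_size <- max(sizes[sizes <= min(lens)])
  keys <- lapply(debiased_set, function(d) {
    bit_vector(as.integer(d)[seq_len(key_size)], stage = "key",
               source_id = attr(d, "source_id"))
  })
  list(keys = keys, key_size = key_size)
}

#' Digitize one prepared image into its bit-vector stages
#'
#' Convenience composition of [extract_features()], [quantize()] and
#' [von_neumann_extract()] for a single device.
#'
#' @param image A [binary_image()] or [aggregate_image()] (fed through
#'   [prepare_for_model()]) or an already prepared `model_raster`.
#' @param backbone A [backbone_spec()].
#' @param source_id Optional device identifier.
#' @return List with `features`, `biased`, `debiased`.
#' @export
digitize_image <- function(image, backbone = backbone_spec(),
                           source_id = NULL) {
  raster <- if (inherits(image, "model_raster")) image else
    prepare_for_model(image, side = backbone$input_side)
  features <- extract_features(raster, backbone)
  biased <- quantize(features, source_id = source_id)
  list(features = features, biased = biased,
       debiased = von_neumann_extract(biased))
}
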