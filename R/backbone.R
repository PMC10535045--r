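# Deep-hash stage: a convolutional backbone with its classification head
# removed maps a prepared raster to a fixed-length feature vector. The
# default (and only offline) weight backend draws every filter once from a
# seeded Gaussian stream: a fixed random convolutional projection is a valid
# one-way feature map, and it keeps the whole pipeline reproducible with no
# model download. Feature length is architecture-determined (2048 for the
# ResNet50-style registry entry), matching a global-average-pooled final
# convolution.

.pkg_cache <- new.env(parent = emptyenv())

.backbone_registry <- function() {
  list(
    "resnet50-like" = list(
      input_side = 224L, feature_length = 2048L,
      layers = list(
        list(k = 7L, stride = 2L, out = 32L, head = FALSE),
        list(k = 3L, stride = 2L, out = 64L, head = FALSE),
        list(k = 3L, stride = 2L, out = 128L, head = FALSE),
        list(k = 3L, stride = 2L, out = 256L, head = FALSE),
        list(k = 3L, stride = 2L, out = 2048L, head = TRUE))),
    "mobilenet-like" = list(
      input_side = 224L, feature_length = 1280L,
      layers = list(
        list(k = 3L, stride = 2L, out = 16L, head = FALSE),
        list(k = 3L, stride = 2L, out = 32L, head = FALSE),
        list(k = 3L, stride = 2L, out = 64L, head = FALSE),
        list(k = 3L, stride = 2L, out = 128L, head = FALSE),
        list(k = 3L, stride = 2L, out = 1280L, head = TRUE))),
    "inceptionv3-like" = list(
      input_side = 299L, feature_length = 2048L,
      layers = list(
        list(k = 7L, stride = 2L, out = 32L, head = FALSE),
        list(k = 3L, stride = 2L, out = 64L, head = FALSE),
        list(k = 3L, stride = 2L, out = 128L, head = FALSE),
        list(k = 3L, stride = 2L, out = 256L, head = FALSE),
        list(k = 3L, stride = 2L, out = 2048L, head = TRUE))))
}

#' Backbone specification
#'
#' Describes the decapitated convolutional feature extractor: a registry
#' architecture, the weight backend, and the input side. Identical
#' specifications (including `weight_seed`) always produce identical
#' features for identical inputs.
#'
#' @param architecture Registry name: `"resnet50-like"`, `"mobilenet-like"`
#'   or `"inceptionv3-like"`.
#' @param weights `"seeded_random"` (default, offline) or `"pretrained"`.
#'   Pretrained weights require an external model download and are not
#'   bundled; requesting them raises an informative error.
#' @param weight_seed Integer seed for the weight stream.
#' @param input_side Expected input side; defaults to the registry value.
#'   Smaller sides are accepted (the convolution stack is fully
#'   size-agnostic) and are useful for fast screening runs.
#' @return A `backbone_spec` with the architecture-determined
#'   `feature_length`.
#' @examples
#' backbone_spec("resnet50-like")$feature_length  # 2048
#' @export
backbone_spec <- function(architecture = "resnet50-like",
                          weights = c("seeded_random", "pretrained"),
                          weight_seed = 0L, input_side = NULL) {
  reg <- .backbone_registry()
  if (!architecture %in% names(reg)) {
    stop(sprintf("unknown architecture '%s'; registry: %s", architecture,
                 paste(names(reg), collapse = ", ")))
  }
  weights <- match.arg(weights)
  if (weights == "pretrained") {
    stop("pretrained weights are not bundled (they require a network ",
         "download); use weights = 'seeded_random'")
  }
  arch <- reg[[architecture]]
  side <- if (is.null(input_side)) arch$input_side else as.integer(input_side)
  if (side < 32) stop("input_side must be >= 32")
  structure(list(architecture = architecture, weights = weights,
                 weight_seed = as.integer(weight_seed), input_side = side,
                 feature_length = arch$feature_length, layers = arch$layers),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> %s (%s, weight_seed %d), input %d, %d features\n",
              x$architecture, x$weights, x$weight_seed, x$input_side,
              x$feature_length))
  invisible(x)
}

# Instantiate (and cache) the layer weight matrices for a spec. He-scaled
# Gaussian filters drawn from a private stream keyed by weight_seed; the
# caller's RNG state is untouched.
.backbone_weights <- function(spec) {
  key <- paste(spec$architecture, spec$weight_seed, sep = "#")
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  weights <- .with_seed(spec$weight_seed, {
    c_in <- 3L
    lapply(spec$layers, function(ly) {
      fan_in <- ly$k * ly$k * c_in
      w <- matrix(stats::rnorm(fan_in * ly$out, sd = sqrt(2 / fan_in)),
                  fan_in, ly$out)
      c_in <<- ly$out
      w
    })
  })
  .pkg_cache[[key]] <- weights
  weights
}

# im2col patch extraction with zero padding (pad = k %/% 2); rows are output
# positions in column-major order, columns are (dr, dc, channel).
.im2col <- function(x, k, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  p <- k %/% 2
  hp <- h + 2 * p; wp <- w + 2 * p
  xp <- array(0, dim = c(hp, wp, ch))
  xp[p + seq_len(h), p + seq_len(w), ] <- x
  r0 <- seq(1, hp - k + 1, by = stride)
  c0 <- seq(1, wp - k + 1, by = stride)
  base <- rep(r0, times = length(c0)) +
    (rep(c0, each = length(r0)) - 1) * hp
  off <- as.vector(outer(0:(k - 1), (0:(k - 1)) * hp, "+"))
  off <- as.vector(outer(off, (seq_len(ch) - 1) * hp * wp, "+"))
  patches <- matrix(xp[outer(base, off, "+")], length(base), length(off))
  list(patches = patches, h_out = length(r0), w_out = length(c0))
}

# E[max(Z, 0)] for standard normal Z: centring constant of the activation.
.RELU_MEAN <- 1 / sqrt(2 * pi)

#' Extract a deep-hash feature vector
#'
#' Runs the prepared raster through the backbone's convolution stack.
#' Interior layers use instance normalization (per-channel spatial
#' standardization) followed by a mean-centred ReLU, so that the globally
#' averaged response of each channel carries the image-specific deviation of
#' its activation statistics rather than a channel-constant offset; the final
#' (head-removed) convolution is linear and is global-average-pooled into the
#' feature vector.
#'
#' @param raster A `model_raster` from [prepare_for_model()] whose side
#'   equals `spec$input_side`.
#' @param spec A [backbone_spec()].
#' @return A `feature_vector`: numeric vector of length
#'   `spec$feature_length`, with the backbone specification stored as an attribute.
#' @export
extract_features <- function(raster, spec = backbone_spec()) {
  if (!inherits(spec, "backbone_spec")) stop("spec must be a backbone_spec")
  x <- unclass(raster)
  if (length(dim(x)) != 3 || dim(x)[3] != 3) {
    stop("raster must be a side x side x 3 model raster")
  }
  if (dim(x)[1] != spec$input_side || dim(x)[2] != spec$input_side) {
    stop(sprintf("raster side %d does not match spec input_side %d",
                 dim(x)[1], spec$input_side))
  }
  weights <- .backbone_weights(spec)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    im <- .im2col(x, ly$k, ly$stride)
    y <- im$patches %*% weights[[i]]
    if (ly$head) {
      feats <- colMeans(y)  # global average pooling of the final convolution
      return(structure(as.numeric(feats), spec = spec,
                       class = "feature_vector"))
    }
    mu <- colMeans(y)
    sd_ <- sqrt(colMeans(y^2) - mu^2) + 1e-8
    z <- sweep(sweep(y, 2, mu), 2, sd_, "/")
    act <- pmax(z, 0) - .RELU_MEAN
    x <- array(act, dim = c(im$h_out, im$w_out, ly$out))
  }
  stop("backbone has no head layer")  # registry always ends in a head
}

#' @export
print.feature_vector <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<feature_vector> n = %d from %s; mean threshold = %.6g\n",
              length(x), sp$architecture, mean(x)))
  invisible(x)
}

#' Mean-threshold of a feature vector
#'
#' The quantization threshold: the arithmetic mean of the feature values.
#'
#' @param features A `feature_vector` (or numeric vector).
#' @return The scalar threshold.
#' @export
feature_threshold <- function(features) mean(as.numeric(features))

#' Export feature vectors to CSV
#'
#' One row per device, one column per feature, for external auditing.
#'
#' @param features Named list (or list-column) of feature vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  m <- do.call(rbind, lapply(features, as.numeric))
  df <- data.frame(device_id = names(features) %||% seq_along(features), m,
                   check.names = FALSE)
  names(df) <- c("device_id", paste0("x", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
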