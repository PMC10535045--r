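#' Enroll a set of device images into a device library
#'
#' Runs the full digitization pipeline per device: binarization, fiducial
#' stamping (for the printable label), fiducial stripping before feature
#' extraction (so the key depends only on the PUF pattern), decapitated-CNN
#' feature extraction, mean-threshold quantization and Von Neumann
#' extraction, and finally a set-wide key derivation to one standard key
#' size.
#'
#' @param devices A tibble with columns `device_id` and `image` (as from
#'   [simulate_devices()]), or a named list of [aggregate_image()]s.
#' @param backbone A [backbone_spec()].
#' @param binarize_method Thresholding method for [binarize()].
#' @param binarize_param Optional parameter for the thresholding method.
#' @param polarity Foreground polarity of the source images.
#' @param fiducials A [fiducial_spec()] used for the printed label and for
#'   registration at authentication time.
#' @param keep_features Keep per-device feature vectors in the library (for
#'   auditing/export).
#' @return A `device_library`: the per-device tibble (`device_id`, `biased`,
#'   `debiased`, `key` list-columns plus lengths), the pipeline
#'   configuration, and the derived `key_size`.
#' @export
enroll_devices <- function(devices, backbone = backbone_spec(),
                           binarize_method = "otsu", binarize_param = NULL,
                           polarity = "dark", fiducials = fiducial_spec(),
                           keep_features = FALSE) {
  if (is.data.frame(devices)) {
    ids <- devices$device_id
    imgs <- devices$image
  } else {
    imgs <- devices
    ids <- names(devices) %||% sprintf("device-%04d", seq_along(devices))
  }
  canonical_size <- nrow(imgs[[1]])
  rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    bin <- binarize(imgs[[i]], method = binarize_method,
                    param = binarize_param, polarity = polarity)
    label <- place_fiducials(bin, fiducials)
    dig <- digitize_image(strip_fiducials(label, fiducials),
                          backbone = backbone, source_id = ids[i])
    rows[[i]] <- tibble::tibble(
      device_id = ids[i],
      biased = list(dig$biased), debiased = list(dig$debiased),
      biased_len = length(dig$biased), debiased_len = length(dig$debiased),
      features = if (keep_features) list(dig$features) else list(NULL),
      label = list(label))
  }
  tbl <- dplyr::bind_rows(rows)
  kd <- derive_keys(tbl$debiased)
  tbl$key <- kd$keys
  if (!keep_features) tbl$features <- NULL
  structure(list(devices = tbl, backbone = backbone,
                 binarize_method = binarize_method,
                 binarize_param = binarize_param, polarity = polarity,
                 fiducials = fiducials, canonical_size = canonical_size,
                 key_size = kd$key_size),
            class = "device_library")
}

#' @export
print.device_library <- function(x, ...) {
  cat(sprintf(
    "<device_library> %d devices, %d-bit keys, %s backbone (%d-bit biased vectors)\n",
    nrow(x$devices), x$key_size, x$backbone$architecture,
    x$backbone$feature_length))
  invisible(x)
}

#' Number of enrolled devices
#' @param x A `device_library`.
#' @return Integer count.
#' @export
n_devices <- function(x) nrow(x$devices)

#' Remove a device from the library (one-time-use retirement)
#' @param library A `device_library`.
#' @param device_id Device to retire.
#' @return The library without that device.
#' @export
retire_device <- function(library, device_id) {
  if (!device_id %in% library$devices$device_id) {
    stop("unknown device id: ", device_id)
  }
  library$devices <- library$devices[library$devices$device_id != device_id, ]
  library
}

#' Evaluate key quality for an enrolled library
#'
#' Computes per-key bit uniformity, all pairwise normalized inter-device
#' Hamming distances, and the seven NIST results per key (the cumulative
#' sums test counts as two), then aggregates pass proportions.
#'
#' @param library A `device_library`, or a list of equal-length key
#'   [bit_vector()]s.
#' @param alpha Significance level for the pass flags.
#' @param M Block size for the block frequency test (NULL = default).
#' @param m Template length for the approximate entropy test.
#' @return A `library_report` with fields `uniformity` (per-key tibble),
#'   `uniformity_mean`, `uniformity_median`, `inter` (from [inter_hd()]),
#'   `nist` (per key per test tibble) and `proportions` (per-test pass
#'   rates).
#' @export
evaluate_library <- function(library, alpha = 0.01, M = NULL, m = 2L) {
  keys <- if (inherits(library, "device_library")) {
    stats::setNames(library$devices$key, library$devices$device_id)
  } else {
    library
  }
  ids <- vapply(seq_along(keys), function(i) {
    attr(keys[[i]], "source_id") %||% names(keys)[i] %||% paste0("key-", i)
  }, character(1))
  unif <- tibble::tibble(
    device_id = ids,
    uniformity = vapply(keys, bit_uniformity, numeric(1)))
  inter <- inter_hd(keys)
  nist <- dplyr::bind_rows(lapply(seq_along(keys), function(i) {
    dplyr::mutate(nist_battery(keys[[i]], alpha = alpha, M = M, m = m),
                  device_id = ids[i], .before = 1)
  }))
  proportions <- nist |>
    dplyr::group_by(.data$test_name) |>
    dplyr::summarise(n = dplyr::n(), passed = sum(.data$passed),
                     proportion = mean(.data$passed), .groups = "drop")
  structure(list(uniformity = unif,
                 uniformity_mean = mean(unif$uniformity),
                 uniformity_median = stats::median(unif$uniformity),
                 inter = inter, nist = nist, proportions = proportions,
                 alpha = alpha,
                 key_size = length(keys[[1]])),
            class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat(sprintf("<library_report> %d keys of %d bits\n",
              nrow(x$uniformity), x$key_size))
  cat(sprintf("  bit uniformity: mean %.4f, median %.4f (ideal 0.5)\n",
              x$uniformity_mean, x$uniformity_median))
  cat(sprintf("  inter-HD: mean %.4f, sd %.4f over %d pairs (ideal 0.5)\n",
              x$inter$mean, x$inter$sd, x$inter$n_pairs))
  cat(sprintf("  NIST pass proportions (alpha = %g):\n", x$alpha))
  for (i in seq_len(nrow(x$proportions))) {
    cat(sprintf("    %-20s %d/%d\n", x$proportions$test_name[i],
                x$proportions$passed[i], x$proportions$n[i]))
  }
  invisible(x)
}

#' Tidy a library report
#'
#' @param x A `library_report`.
#' @param ... Unused.
#' @return The per-key per-test NIST tibble.
#' @export
tidy.library_report <- function(x, ...) x$nist

#' One-row summary of a library report
#'
#' @param x A `library_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline uniformity, inter-HD and pass
#'   statistics.
#' @export
glance.library_report <- function(x, ...) {
  tibble::tibble(
    n_keys = nrow(x$uniformity), key_size = x$key_size,
    uniformity_mean = x$uniformity_mean,
    uniformity_median = x$uniformity_median,
    inter_hd_mean = x$inter$mean, inter_hd_sd = x$inter$sd,
    n_pairs = x$inter$n_pairs,
    min_pass_proportion = min(x$proportions$proportion))
}

#' Generic tidiers
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write a library report to JSON and CSV
#'
#' The JSON carries the full report (summaries, pairwise distances, per-test
#' rows); the CSV is the flat one-row-per-key-per-test NIST table. Histogram
#' source data (per-key uniformities and pairwise distances) are part of the
#' JSON for external plotting.
#'
#' @param report A `library_report`.
#' @param json_path,csv_path Output paths (NULL to skip either).
#' @return `report`, invisibly.
#' @export
write_library_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = as.list(glance.library_report(report)),
           uniformity = report$uniformity,
           inter_hd_pairs = report$inter$pairs,
           nist = report$nist,
           proportions = report$proportions),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$nist, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Write a device-library manifest as JSON
#'
#' One record per device: `device_id`, the key as lowercase hex and its bit
#' length, the biased/debiased lengths, the biased vector as hex (needed for
#' authentication-time matching), and a SHA-256 of the source image when its
#' file is available.
#'
#' @param library A `device_library`.
#' @param path Output JSON path.
#' @param image_paths Optional named character vector of device image files
#'   used to record content hashes.
#' @return `path`, invisibly.
#' @export
write_device_library <- function(library, path, image_paths = NULL) {
  tbl <- library$devices
  sha <- function(id) {
    if (is.null(image_paths)) return(NA)
    f <- image_paths[id]
    if (is.na(f) || !file.exists(f)) return(NA)
    if (nzchar(Sys.which("sha256sum"))) {
      strsplit(system2("sha256sum", shQuote(f), stdout = TRUE), " ")[[1]][1]
    } else NA
  }
  devices <- lapply(seq_len(nrow(tbl)), function(i) {
    biased <- tbl$biased[[i]]
    pad <- (8 - length(biased) %% 8) %% 8
    list(device_id = tbl$device_id[i],
         key_hex = bits_to_hex(tbl$key[[i]]),
         key_bits = length(tbl$key[[i]]),
         biased_len = length(biased),
         debiased_len = tbl$debiased_len[i],
         biased_hex = bits_to_hex(bit_vector(c(as.integer(biased),
                                               rep(0L, pad)))),
         backbone = library$backbone$architecture,
         image_sha256 = sha(tbl$device_id[i]))
  })
  jsonlite::write_json(
    list(key_size = library$key_size,
         canonical_size = library$canonical_size,
         backbone = library$backbone[c("architecture", "weights",
                                       "weight_seed", "input_side")],
         binarize_method = library$binarize_method,
         binarize_param = library$binarize_param,
         polarity = library$polarity,
         fiducials = list(markers = as.list(library$fiducials$markers),
                          glyph_size = library$fiducials$glyph_size,
                          margin = library$fiducials$margin),
         devices = devices),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a device-library manifest
#'
#' Reconstructs a `device_library` (keys and biased vectors; debiased
#' vectors are not persisted) from the JSON written by
#' [write_device_library()].
#'
#' @param path Manifest path.
#' @return A `device_library`.
#' @export
read_device_library <- function(path) {
  j <- jsonlite::read_json(path)
  bb <- backbone_spec(j$backbone$architecture, j$backbone$weights,
                      j$backbone$weight_seed, j$backbone$input_side)
  fid <- fiducial_spec(unlist(j$fiducials$markers), j$fiducials$glyph_size,
                       j$fiducials$margin)
  rows <- lapply(j$devices, function(d) {
    biased_full <- as.integer(hex_to_bits(d$biased_hex))[seq_len(d$biased_len)]
    tibble::tibble(
      device_id = d$device_id,
      biased = list(bit_vector(biased_full, "biased", d$device_id)),
      debiased = list(NULL),
      biased_len = d$biased_len, debiased_len = d$debiased_len,
      key = list(hex_to_bits(d$key_hex, d$device_id)))
  })
  structure(list(devices = dplyr::bind_rows(rows), backbone = bb,
                 binarize_method = j$binarize_method,
                 binarize_param = j$binarize_param, polarity = j$polarity,
                 fiducials = fid, canonical_size = j$canonical_size,
                 key_size = j$key_size),
            class = "device_library")
}
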