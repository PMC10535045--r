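#' Grow a diffusion-limited aggregation cluster
#'
#' On-lattice DLA emulating the radially branched dendrites formed by
#' drying-induced protein self-assembly. Walkers are launched on a circle
#' just outside the current cluster radius (radius + 5), perform 4-neighbour
#' random walks (unbiased in open space, with an inward convective bias of
#' probability `drift` in the boundary layer around the cluster), attach
#' with probability `stickiness` whenever 8-adjacent to the cluster, and are
#' relaunched (never discarded) if they cross the kill radius at three times
#' the launch radius.
#'
#' All randomness comes from a single Mersenne-Twister stream keyed by
#' `rng_seed`; R's global RNG state is untouched, and identical arguments
#' reproduce the identical occupied set.
#'
#' @param lattice_size Lattice side in sites (>= 64).
#' @param n_particles Number of walkers to attach (>= 1).
#' @param stickiness Attachment probability in (0, 1].
#' @param rng_seed Integer seed for the cluster's RNG stream.
#' @param n_nuclei Number of seed sites; 1 places the seed at the lattice
#'   centre, more are placed uniformly at random (from the same stream) to
#'   mimic multi-centre micrographs.
#' @param drift Inward convective bias: probability that a step inside the
#'   boundary layer around the cluster moves toward the lattice centre
#'   instead of being uniform over the four neighbours. 0 recovers the
#'   classical Witten--Sander model; the default 0.35 emulates the
#'   evaporation-driven flux of a drying droplet, giving the dense radial
#'   dendrites seen in dried protein films (and letting reference-size
#'   clusters of 20000 particles fit a 512 lattice).
#' @return A `dla_cluster` with fields `lattice_size`, `occupied` (two-column
#'   matrix of 1-based row/col sites, seeds first, then attachment order),
#'   `seed_sites`, `rng_seed`, `n_particles`, `stickiness`, `n_nuclei`,
#'   `drift`.
#' @examples
#' cl <- grow_cluster(128, 200, 1.0, rng_seed = 1)
#' cl
#' @export
grow_cluster <- function(lattice_size, n_particles, stickiness = 1.0,
                         rng_seed = 1L, n_nuclei = 1L, drift = 0.35) {
  stopifnot(lattice_size >= 64, n_particles >= 1,
            stickiness > 0, stickiness <= 1, n_nuclei >= 1,
            drift >= 0, drift < 1)
  occ <- .grow_cluster_cpp(as.integer(lattice_size), as.integer(n_particles),
                           as.double(stickiness), as.integer(rng_seed),
                           as.integer(n_nuclei), as.double(drift))
  structure(
    list(lattice_size = as.integer(lattice_size),
         occupied = occ,
         seed_sites = occ[seq_len(n_nuclei), , drop = FALSE],
         rng_seed = as.integer(rng_seed),
         n_particles = as.integer(n_particles),
         stickiness = stickiness,
         n_nuclei = as.integer(n_nuclei),
         drift = drift),
    class = "dla_cluster")
}

#' @export
print.dla_cluster <- function(x, ...) {
  cat(sprintf(
    "<dla_cluster> %d sites on a %d x %d lattice (%d nuclei, stickiness %g, seed %d)\n",
    nrow(x$occupied), x$lattice_size, x$lattice_size, x$n_nuclei,
    x$stickiness, x$rng_seed))
  invisible(x)
}

#' Occupancy mask of a cluster
#' @param cluster A `dla_cluster`.
#' @return A `binary_image` with occupied sites as foreground.
#' @export
cluster_mask <- function(cluster) {
  m <- matrix(0L, cluster$lattice_size, cluster$lattice_size)
  m[cluster$occupied] <- 1L
  binary_image(m, method = "mask")
}

#' Render a cluster as a grayscale entropy image
#'
#' Draws the occupied sites as dark foreground on a light background (the
#' contrast of dark bioink printed on a transparent film), optionally spread
#' with a Gaussian halo to mimic the lateral extent of a height map, then
#' resampled to `out_size` and normalized to the full 8-bit range.
#'
#' @param cluster A `dla_cluster`.
#' @param out_size Output side in pixels (>= 64); default keeps lattice size.
#' @param halo_sigma Gaussian halo width in lattice sites; 0 disables it.
#' @return An [aggregate_image()].
#' @export
render_image <- function(cluster, out_size = cluster$lattice_size,
                         halo_sigma = 0) {
  stopifnot(inherits(cluster, "dla_cluster"), out_size >= 64, halo_sigma >= 0)
  if (nrow(cluster$occupied) == 0) stop("cannot render an empty cluster")
  mask <- matrix(0, cluster$lattice_size, cluster$lattice_size)
  mask[cluster$occupied] <- 1
  if (halo_sigma > 0) {
    mask <- EBImage::imageData(EBImage::gblur(EBImage::Image(mask),
                                              sigma = halo_sigma))
    mask <- mask / max(mask)
  }
  img <- 255 * (1 - mask)  # dark dendrite on light background
  if (out_size != cluster$lattice_size) {
    img <- resample_image(img, out_size)
    img <- (img - min(img)) / (max(img) - min(img)) * 255
  }
  aggregate_image(round(img))
}

#' Box-counting fractal dimension of a binary mask
#'
#' Least-squares slope of log(occupied box count) against log(1/box size)
#' over dyadic box sizes 1, 2, 4, ... up to one eighth of the shorter image
#' side. At least four scales are required.
#'
#' @param mask A `binary_image` (or 0/1 matrix) with >= 2 foreground pixels.
#' @return Estimated dimension (a real number, 2 for a filled plane).
#' @examples
#' sq <- binary_image(matrix(1L, 128, 128))
#' box_counting_dimension(sq)  # ~2
#' @export
box_counting_dimension <- function(mask) {
  m <- unclass(mask)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("mask must contain at least 2 foreground pixels")
  side <- min(dim(m))
  k_max <- floor(log2(side)) - 3  # largest box = side / 8
  if (k_max < 3) stop("fewer than 4 usable scales; image too small")
  sizes <- 2^(0:k_max)
  counts <- vapply(sizes, function(s) {
    length(unique((idx[, 1] - 1) %/% s * 2^30 + (idx[, 2] - 1) %/% s))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[[2]]
}

#' Generate a batch of synthetic PUF devices
#'
#' Grows one cluster per device with consecutive RNG seeds
#' `seed0, seed0 + 1, ...` and renders each to a grayscale image. If
#' `out_dir` is given, images are written as 8-bit PNG with a JSON sidecar
#' recording the growth parameters.
#'
#' @param n_devices Number of devices.
#' @param particles Particles per cluster.
#' @param size Lattice/image side in pixels.
#' @param seed0 Seed of the first device.
#' @param stickiness Attachment probability.
#' @param n_nuclei Seed sites per cluster.
#' @param drift Inward convective bias (see [grow_cluster()]).
#' @param halo_sigma Rendering halo width.
#' @param out_dir Optional output directory.
#' @return A tibble with columns `device_id`, `rng_seed`, `image` (list of
#'   [aggregate_image()]), and `path` when written.
#' @export
simulate_devices <- function(n_devices, particles = 20000, size = 512,
                             seed0 = 1, stickiness = 1.0, n_nuclei = 1,
                             drift = 0.35, halo_sigma = 0, out_dir = NULL) {
  seeds <- seq(seed0, length.out = n_devices)
  rows <- lapply(seeds, function(s) {
    cl <- grow_cluster(size, particles, stickiness, rng_seed = s,
                       n_nuclei = n_nuclei, drift = drift)
    img <- render_image(cl, out_size = size, halo_sigma = halo_sigma)
    id <- sprintf("device-%04d", s)
    path <- NA_character_
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, paste0(id, ".png"))
      write_image(img, path)
      jsonlite::write_json(
        list(device_id = id, lattice_size = size, n_particles = particles,
             stickiness = stickiness, rng_seed = s, n_nuclei = n_nuclei,
             drift = drift, halo_sigma = halo_sigma),
        sub("\\.png$", ".json", path), auto_unbox = TRUE, pretty = TRUE)
    }
    tibble::tibble(device_id = id, rng_seed = s, image = list(img),
                   path = path)
  })
  dplyr::bind_rows(rows)
}

#' Write a grayscale image as 8-bit PNG or TIFF
#' @param image An [aggregate_image()] or `binary_image`.
#' @param path Output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- unclass(image)
  if (inherits(image, "binary_image")) m <- (1 - m) * 255  # foreground dark
  type <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  EBImage::writeImage(EBImage::Image(t(m) / 255), path, type = type,
                      bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit grayscale image
#'
#' Multi-channel inputs are reduced to luminance.
#'
#' @param path PNG or TIFF path.
#' @return An [aggregate_image()] on the `[0, 255]` scale.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) {
    d <- 0.2126 * d[, , 1] + 0.7152 * d[, , 2] + 0.0722 * d[, , 3]
  }
  aggregate_image(round(t(d) * 255))
}
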