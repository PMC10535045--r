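test_that("Otsu separates a bimodal image at the lower mode", {
  m <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  bin <- binarize(aggregate_image(m), "otsu", polarity = "light")
  expect_equal(attr(bin, "threshold"), 10)  # ties resolved to the lowest level
  expect_true(all(px(bin) == (m > 10)))
  # aggregate-dark polarity marks the dark mode as foreground
  bin_d <- binarize(aggregate_image(m), "otsu", polarity = "dark")
  expect_true(all((px(bin_d) == 1) == (m == 10)))
})

test_that("Otsu equals the exhaustive variance-scan oracle on the 4x4 example", {
  m <- matrix(c(12, 14, 200, 202,
                13, 15, 201, 199,
                12, 200, 14, 198,
                201, 13, 199, 15), 4, 4, byrow = TRUE)
  expect_equal(otsu_threshold(m), oracle_otsu(m))
})

test_that("Otsu equals the exhaustive scan on random images", {
  set.seed(101)
  for (i in 1:100) {
    s <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(otsu_threshold(s), oracle_otsu(s))
  }
})

test_that("binarization is polarity-consistent", {
  set.seed(7)
  m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  a <- binarize(aggregate_image(m), "otsu", polarity = "dark")
  b <- binarize(aggregate_image(255 - m), "otsu", polarity = "light")
  expect_identical(px(a), px(b))
  expect_equal(attr(a, "threshold"), attr(b, "threshold"))
})

test_that("degenerate and boundary thresholding cases are defined", {
  const <- aggregate_image(matrix(100, 8, 8))
  bin <- binarize(const, "otsu")
  expect_true(attr(bin, "degenerate"))
  expect_true(all(unclass(bin) == 0))

  m <- aggregate_image(matrix(sample(0:255, 64), 8, 8))
  all_fg <- binarize(m, "global", param = 0)
  expect_true(all(unclass(all_fg) == 1))

  expect_error(binarize(m, "adaptive", param = 10), "odd")
  expect_error(binarize(m, "global"), "param")
})

test_that("adaptive thresholding compares against the local frame mean", {
  m <- matrix(0, 16, 16)
  m[4:12, 4:12] <- 120  # bright block on dark ground (light polarity)
  bin <- binarize(aggregate_image(m), "adaptive", param = 7,
                  polarity = "light")
  expect_equal(unclass(bin)[8, 8], 0)   # deep inside: equals local mean
  expect_equal(unclass(bin)[4, 4], 1)   # block corner exceeds local mean
})

test_that("fiducial stamping yields three components and is idempotent", {
  blank <- binary_image(matrix(0L, 256, 256))
  stamped <- place_fiducials(blank)
  lab <- EBImage::bwlabel(EBImage::Image(unclass(stamped) * 1.0))
  expect_equal(max(lab), 3)
  expect_identical(unclass(place_fiducials(stamped)), unclass(stamped))
  expect_error(place_fiducials(blank, fiducial_spec(glyph_size = 200,
                                                    margin = 60)),
               "fit")
})

test_that("stamping leaves interior PUF pixels unchanged and strips cleanly", {
  set.seed(3)
  px <- matrix(rbinom(256^2, 1, 0.2), 256, 256)
  img <- binary_image(px)
  spec <- fiducial_spec()
  stamped <- place_fiducials(img, spec)
  interior <- rep(TRUE, 256)
  w <- spec$margin + spec$glyph_size
  keep <- unclass(stamped)
  keep[seq_len(w + 1), ] <- NA
  keep[, seq_len(w + 1)] <- NA
  keep[(256 - w):256, ] <- NA
  keep[, (256 - w):256] <- NA
  orig <- unclass(img)
  expect_identical(keep[!is.na(keep)], orig[!is.na(keep)])
  w1 <- spec$margin + seq_len(spec$glyph_size)
  expect_true(all(unclass(strip_fiducials(stamped, spec))[w1, w1] == 0))
})

test_that("zero-parameter capture is the identity on binary content", {
  lib <- fx_lib4()
  lab <- lib$devices$label[[1]]
  cap <- simulate_capture(lab, out_size = 512)
  expect_identical(px(binarize(cap, "otsu")), px(lab))
  cap2 <- simulate_capture(lab, rotation_deg = 2, perspective_jitter = 0.004,
                           blur_sigma = 1, illum_gradient = 0.1, noise_sd = 4,
                           out_size = 512, rng_seed = 5)
  cap3 <- simulate_capture(lab, rotation_deg = 2, perspective_jitter = 0.004,
                           blur_sigma = 1, illum_gradient = 0.1, noise_sd = 4,
                           out_size = 512, rng_seed = 5)
  expect_identical(unclass(cap2), unclass(cap3))
})

test_that("a 90-degree capture equals the exactly rotated input", {
  lib <- fx_lib4()
  lab <- lib$devices$label[[1]]
  cap <- simulate_capture(lab, rotation_deg = 90, out_size = 512)
  rot_ccw <- t(px(lab))[rev(seq_len(512)), ]
  expect_identical(px(binarize(cap, "otsu")), rot_ccw)
})

test_that("prepare_for_model produces canonical rasters", {
  lib <- fx_lib4()
  r <- prepare_for_model(lib$devices$label[[1]], side = 224)
  expect_equal(dim(unclass(r)), c(224, 224, 3))
  expect_identical(unclass(r)[, , 1], unclass(r)[, , 3])
  expect_true(all(unclass(r) >= 0 & unclass(r) <= 1))
  # idempotent on an already prepared raster
  expect_identical(unclass(prepare_for_model(r, side = 224)), unclass(r))
  # uniform image maps to a uniform level
  u <- prepare_for_model(aggregate_image(matrix(128, 64, 64)), side = 224)
  expect_equal(max(unclass(u)) - min(unclass(u)), 0, tolerance = 1e-9)
  expect_error(prepare_for_model(matrix(numeric(0), 0, 0)), "empty")
})
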