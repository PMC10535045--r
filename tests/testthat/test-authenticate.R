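test_that("fiducials are recovered within a pixel on a clean capture", {
  lib <- fx_lib4()
  cap <- simulate_capture(lib$devices$label[[1]], out_size = 512)
  det <- detect_fiducials(cap)
  expect_equal(attr(det, "orientation"), 0L)
  canon <- fiducial_centers(lib$fiducials, 512)
  canon <- canon[match(det$corner, canon$corner), ]
  expect_lte(max(abs(det$x - canon$x)), 1)
  expect_lte(max(abs(det$y - canon$y)), 1)
})

test_that("a 180-degree capture resolves to the 180 orientation", {
  lib <- fx_lib4()
  cap <- simulate_capture(lib$devices$label[[1]], rotation_deg = 180,
                          out_size = 512)
  det <- detect_fiducials(cap)
  expect_equal(attr(det, "orientation"), 180L)
  # detected top-left glyph now sits at the bottom-right of the capture
  tl <- det[det$corner == "top_left", ]
  expect_gt(tl$x, 256)
  expect_gt(tl$y, 256)
})

test_that("fiducials survive blur and noise within 3 px", {
  lib <- fx_lib4()
  cap <- simulate_capture(lib$devices$label[[1]], blur_sigma = 2, noise_sd = 8,
                          out_size = 512, rng_seed = 4)
  det <- detect_fiducials(cap)
  canon <- fiducial_centers(lib$fiducials, 512)
  canon <- canon[match(det$corner, canon$corner), ]
  expect_lte(max(abs(det$x - canon$x)), 3)
  expect_lte(max(abs(det$y - canon$y)), 3)
})

test_that("detection fails loudly when the markers are absent", {
  blank <- aggregate_image(matrix(255, 512, 512))
  expect_error(detect_fiducials(blank), "confident")
})

test_that("registration round-trips identity, rotation and perspective", {
  lib <- fx_lib4()
  lab <- lib$devices$label[[1]]
  m <- px(lab)

  cap0 <- simulate_capture(lab, out_size = 512)
  reg0 <- register_capture(cap0, detect_fiducials(cap0), 512)
  expect_gte(mean(px(binarize(reg0, "otsu")) == m), 0.99)

  cap90 <- simulate_capture(lab, rotation_deg = 90, out_size = 512)
  reg90 <- register_capture(cap90, detect_fiducials(cap90), 512)
  expect_gte(mean(px(binarize(reg90, "otsu")) == m), 0.99)

  capj <- simulate_capture(lab, perspective_jitter = 0.005, out_size = 512,
                           rng_seed = 9)
  regj <- register_capture(capj, detect_fiducials(capj), 512)
  expect_gte(mean(px(binarize(regj, "otsu")) == m), 0.95)

  # stronger projective jitter leaves a residual at the unmarked corner that
  # the 3-point affine cannot remove; agreement degrades gracefully
  for (sd_ in 9:11) {
    capj2 <- simulate_capture(lab, perspective_jitter = 0.02, out_size = 512,
                              rng_seed = sd_)
    regj2 <- register_capture(capj2, detect_fiducials(capj2), 512)
    expect_gte(mean(px(binarize(regj2, "otsu")) == m), 0.80)
  }
})

test_that("registration rejects collinear detections", {
  det <- tibble::tibble(corner = c("top_left", "top_right", "bottom_left"),
                        glyph = c("plus", "C", "plus"),
                        x = c(10, 20, 30), y = c(10, 20, 30), score = 1)
  attr(det, "spec") <- fiducial_spec()
  cap <- aggregate_image(matrix(255, 512, 512))
  expect_error(register_capture(cap, det, 512), "degenerate|collinear")
})

test_that("percent match is exact, symmetric and stage-checked", {
  a <- bit_vector(rep(c(0L, 1L), 1024), "biased", "a")
  expect_equal(percent_match(a, a)$percent_match, 100)
  comp <- bit_vector(1L - as.integer(a), "biased", "b")
  expect_equal(percent_match(a, comp)$percent_match, 0)
  set.seed(31)
  b <- bit_vector(rbinom(2048, 1, 0.5), "biased", "b")
  expect_equal(percent_match(a, b)$percent_match,
               percent_match(b, a)$percent_match)
  hd <- mean(as.integer(a) != as.integer(b))
  expect_equal(percent_match(a, b)$percent_match, 100 - 100 * hd)
  expect_error(percent_match(a, bit_vector(0:1, "biased")), "mismatch")
  expect_error(percent_match(a, bit_vector(rep(0L, 2048), "key")), "stage")
  td <- tidy(percent_match(a, b))
  expect_true(all(c("percent_match", "decision") %in% names(td)))
})

test_that("authenticating the enrolled image itself matches perfectly", {
  lib <- fx_lib4()
  cap <- simulate_capture(lib$devices$label[[2]], out_size = 512)
  res <- authenticate(cap, lib, "device-0002")
  expect_equal(res$percent_match, 100)
  expect_equal(res$decision, "accept")
  expect_error(authenticate(cap, lib, "device-9999"), "unknown")
})

test_that("mild captures authenticate genuinely and cross-claims reject", {
  lib <- fx_lib4()
  cap <- mild_capture(lib$devices$label[[1]], rotation_deg = 3, rng_seed = 17)
  genuine <- authenticate(cap, lib, "device-0001")
  expect_equal(genuine$decision, "accept")
  expect_gt(genuine$percent_match, 85)
  impostor <- authenticate(cap, lib, "device-0003")
  expect_equal(impostor$decision, "reject")
  expect_lt(impostor$percent_match, genuine$percent_match)
})

test_that("device libraries round-trip through the JSON manifest", {
  lib <- fx_lib4()
  path <- withr::local_tempfile(fileext = ".json")
  write_device_library(lib, path)
  back <- read_device_library(path)
  expect_equal(back$key_size, lib$key_size)
  expect_identical(as.integer(back$devices$key[[3]]),
                   as.integer(lib$devices$key[[3]]))
  expect_identical(as.integer(back$devices$biased[[2]]),
                   as.integer(lib$devices$biased[[2]]))
  expect_equal(back$backbone$architecture, lib$backbone$architecture)
  # a re-read library authenticates captures identically
  cap <- mild_capture(lib$devices$label[[1]], rotation_deg = -2, rng_seed = 3)
  expect_equal(authenticate(cap, back, "device-0001")$percent_match,
               authenticate(cap, lib, "device-0001")$percent_match)
  # one-time use: retiring removes the device
  ret <- retire_device(back, "device-0001")
  expect_equal(n_devices(ret), 3)
  expect_error(authenticate(cap, ret, "device-0001"), "unknown")
})

test_that("plot functions return ggplot objects", {
  set.seed(77)
  keys <- lapply(1:6, function(i) bit_vector(rbinom(128, 1, 0.5), "key"))
  rep_ <- evaluate_library(keys)
  expect_s3_class(plot_uniformity(rep_), "ggplot")
  expect_s3_class(autoplot(rep_, "inter_hd"), "ggplot")
  m <- tibble::tibble(percent_match = c(90, 65), genuine = c(TRUE, FALSE))
  expect_s3_class(plot_separation(m), "ggplot")
})
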