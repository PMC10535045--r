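test_that("a single walker attaches adjacent to the only seed", {
  cl <- grow_cluster(256, 1, 1.0, rng_seed = 42)
  expect_equal(nrow(cl$occupied), 2)
  seed <- cl$seed_sites[1, ]
  particle <- cl$occupied[2, ]
  expect_true(max(abs(particle - seed)) == 1)  # 8-adjacent
})

test_that("growth is deterministic under a fixed seed and varies across seeds", {
  a <- grow_cluster(256, 500, 1.0, rng_seed = 7)
  b <- grow_cluster(256, 500, 1.0, rng_seed = 7)
  expect_identical(a$occupied, b$occupied)

  # unclonability premise at simulator level: different seeds differ in
  # >= 10% of occupied sites (5000+ particles)
  big_a <- grow_cluster(256, 5000, 1.0, rng_seed = 1)
  big_b <- grow_cluster(256, 5000, 1.0, rng_seed = 2)
  key_a <- big_a$occupied[, 1] * 1000L + big_a$occupied[, 2]
  key_b <- big_b$occupied[, 1] * 1000L + big_b$occupied[, 2]
  expect_gt(mean(!key_a %in% key_b), 0.10)
})

test_that("clusters satisfy the structural invariants", {
  for (cl in list(grow_cluster(128, 300, 1.0, rng_seed = 5),
                  grow_cluster(128, 300, 0.5, rng_seed = 5),
                  grow_cluster(128, 200, 1.0, rng_seed = 9, n_nuclei = 4))) {
    expect_equal(nrow(cl$occupied), cl$n_particles + cl$n_nuclei)
    expect_equal(nrow(unique(cl$occupied)), nrow(cl$occupied))
    expect_true(oracle_connected(cl))
  }
})

test_that("growth errors when the cluster reaches the lattice boundary", {
  expect_error(grow_cluster(64, 4000, 1.0, rng_seed = 1),
               "boundary.*particles")
})

test_that("box-counting dimension recovers plane and line exactly", {
  sq <- binary_image(matrix(1L, 512, 512))
  expect_equal(box_counting_dimension(sq), 2.0, tolerance = 0.05 / 2)
  ln <- matrix(0L, 512, 512)
  ln[256, ] <- 1L
  expect_equal(box_counting_dimension(binary_image(ln)), 1.0, tolerance = 0.05)
})

test_that("box-counting dimension rejects degenerate inputs", {
  expect_error(box_counting_dimension(binary_image(matrix(0L, 128, 128))),
               "foreground")
  small <- matrix(1L, 32, 32)
  expect_error(box_counting_dimension(binary_image(small)), "scales")
})

test_that("reference-size clusters have DLA-like fractal dimension", {
  # re-estimated over 5 independently grown clusters, not assumed
  dims <- vapply(11:15, function(seed) {
    cl <- grow_cluster(512, 20000, 1.0, rng_seed = seed)
    box_counting_dimension(cluster_mask(cl))
  }, numeric(1))
  expect_true(all(dims >= 1.55 & dims <= 1.85))
})

test_that("rendering draws exactly the occupied sites and is deterministic", {
  cl <- grow_cluster(128, 500, 1.0, rng_seed = 2)
  img <- render_image(cl, out_size = 128, halo_sigma = 0)
  expect_s3_class(img, "aggregate_image")
  expect_equal(sum(unclass(img) == 0), nrow(cl$occupied))
  expect_identical(unclass(render_image(cl, 128, 0)),
                   unclass(render_image(cl, 128, 0)))
  expect_error(render_image(structure(list(occupied = cl$occupied[0, ],
                                           lattice_size = 128L),
                                      class = "dla_cluster")),
               "empty")
})

test_that("Otsu re-binarization of a rendered cluster recovers the mask", {
  cl <- fx_cluster20k()
  img <- render_image(cl)
  bin <- binarize(img, "otsu")
  mask <- unclass(cluster_mask(cl))
  recovered <- sum(unclass(bin) == 1 & mask == 1) / sum(mask)
  expect_gte(recovered, 0.95)
})

test_that("simulate_devices writes PNG images with JSON sidecars", {
  dir <- withr::local_tempdir()
  devs <- simulate_devices(2, particles = 300, size = 128, seed0 = 5,
                           out_dir = dir)
  expect_equal(nrow(devs), 2)
  expect_true(all(file.exists(devs$path)))
  side <- jsonlite::read_json(sub("\\.png$", ".json", devs$path[1]))
  expect_equal(side$rng_seed, 5)
  expect_equal(side$n_particles, 300)
  back <- read_image(devs$path[1])
  expect_equal(unclass(back), unclass(devs$image[[1]]))
})
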