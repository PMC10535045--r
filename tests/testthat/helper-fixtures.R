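# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# one reference-size cluster (the study-scale growth condition)
fx_cluster20k <- function() fx("cluster20k", grow_cluster(512, 20000, 1.0, rng_seed = 3))

# the 54-device study library: DLA seeds 1..54, Otsu, seeded-random
# resnet50-style backbone with weight seed 0
fx_lib54 <- function() fx("lib54", {
  devs <- simulate_devices(54, particles = 20000, size = 512, seed0 = 1)
  enroll_devices(devs, backbone = backbone_spec("resnet50-like",
                                                weight_seed = 0L))
})

# small 4-device library for module-level round trips
fx_lib4 <- function() fx("lib4", {
  devs <- simulate_devices(4, particles = 20000, size = 512, seed0 = 1)
  enroll_devices(devs)
})

# mild-degradation capture preset (cooperative phone capture of a flat label)
mild_capture <- function(label, rotation_deg, rng_seed) {
  simulate_capture(label, rotation_deg = rotation_deg,
                   perspective_jitter = 0.005, blur_sigma = 1,
                   illum_gradient = 0.1, noise_sd = 5,
                   out_size = nrow(label), rng_seed = rng_seed)
}

bitstr <- function(s) as.integer(strsplit(s, "")[[1]])

# pixel values of a binary/aggregate image, stripped of class and metadata
px <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}
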