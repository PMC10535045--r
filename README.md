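# pufkit

Image-based physically unclonable functions (PUFs) from fractal
self-assembly, end to end in R.

An optical PUF uses the intrinsic randomness of a physical structure as an
unforgeable fingerprint. A compelling biological entropy source is the
radially branched dendrite left behind when a protein solution dries — a
diffusion-limited aggregation (DLA) process that never repeats itself. Such
patterns can be printed as labels, photographed with a phone, and checked
against an enrolled key. `pufkit` implements the complete chain for
researchers prototyping such systems:

* **Synthetic entropy source** — an on-lattice DLA simulator
  (`grow_cluster()`, `render_image()`) with seeded, reproducible growth and
  a box-counting dimension estimator, so every downstream stage is testable
  without laboratory imagery.
* **Image preparation** — Otsu / global / adaptive binarization
  (`binarize()`), corner fiducial markers (`place_fiducials()`), and a
  phone-capture degradation model (`simulate_capture()`).
* **Digitization** — a decapitated convolutional feature extractor with
  seeded random weights (`backbone_spec()`, `extract_features()`),
  mean-threshold quantization (`quantize()`), Von Neumann debiasing
  (`von_neumann_extract()`), and standard-size key derivation
  (`derive_keys()`).
* **Key quality** — bit uniformity, pairwise inter-device Hamming distance,
  and six NIST SP 800-22 tests implemented from their closed forms
  (`evaluate_library()`).
* **Authentication** — fiducial detection, affine registration, and bitwise
  percent-match scoring of degraded captures (`authenticate()`).

## The model in brief

A device image is binarized and reduced by a convolutional backbone with
its classification head removed to a feature vector `X = (x_1, ..., x_n)`
(n = 2048 for the ResNet50-style registry entry). Bits are quantized at the
vector's own mean, `ε = (1/n) Σ x_i`, with `b_i = 1 ⇔ x_i > ε`. The biased
bits pass through a Von Neumann extractor (non-overlapping pairs,
01 → 1, 10 → 0, 00/11 discarded), and each device key is the leading 64,
128 or 256 bits — the largest standard size the whole set supports. Key
quality is scored by bit uniformity `(1/n) Σ P_i` (ideal 0.5), mean
normalized inter-device Hamming distance over all `m(m−1)/2` pairs (ideal
0.5), and NIST SP 800-22 statistics. Authentication re-runs the identical
pipeline on a registered capture and reports the bitwise percent match of
the 2048-bit biased vectors.

## Worked example

```r
library(pufkit)

# grow and enroll a synthetic device library (54 devices, seeds 1..54)
devices <- simulate_devices(54, particles = 20000, size = 512, seed0 = 1)
lib <- enroll_devices(devices)
report <- evaluate_library(lib)
report
#> <library_report> 54 keys of 256 bits
#>   bit uniformity: mean 0.4901, median 0.4922 (ideal 0.5)
#>   inter-HD: mean 0.4901, sd 0.0309 over 1431 pairs (ideal 0.5)
#>   NIST pass proportions (alpha = 0.01):
#>     approximate_entropy  54/54
#>     block_frequency      54/54
#>     cumulative_sums_fwd  53/54
#>     cumulative_sums_rev  54/54
#>     frequency            54/54
#>     longest_run          54/54
#>     runs                 54/54
```

Each 2048-feature vector debiases to roughly 500 bits, so the set supports
256-bit keys; uniformity and uniqueness sit at their ideal 0.5, and the
keys behave as random sequences under the NIST battery. Authenticating a
simulated phone capture:

```r
label <- lib$devices$label[[1]]
capture <- simulate_capture(label, rotation_deg = 3, perspective_jitter = 0.005,
                            blur_sigma = 1, illum_gradient = 0.1, noise_sd = 5,
                            out_size = 512, rng_seed = 11)
authenticate(capture, lib, "device-0001")
#> <match_result> device-0001: 90.7% over 2048 bits -> accept (threshold 85%)
authenticate(capture, lib, "device-0002")
#> <match_result> device-0002: 65.8% over 2048 bits -> reject (threshold 85%)
```

Genuine captures score around 88–94%, impostors around 62–72%; the default
85% threshold separates them cleanly. `plot_uniformity()`,
`plot_inter_hd()` and `plot_separation()` draw the corresponding
histograms; `tidy()`/`glance()` return the reports as tibbles.

Command-line wrappers live in `exec/`: `puf-simulate` writes device images
with JSON sidecars, `puf-authenticate` checks a capture against a library
manifest and exits 0/1/2 for accept/reject/error.

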