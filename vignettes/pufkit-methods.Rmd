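---
title: "Digitizing fractal self-assembly into cryptographic keys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing fractal self-assembly into cryptographic keys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An optical physically unclonable function (PUF) turns the intrinsic
randomness of a physical structure into an unforgeable identity. Here the
structure is the radially branched dendrite formed when a protein solution
dries on a surface — a diffusion-limited aggregation (DLA) process whose
outcome is different on every device and practically impossible to
replicate. `pufkit` implements the whole chain: a synthetic entropy source
(so the pipeline is testable without lab imagery), image preparation,
digitization into fixed-length binary keys, key-quality statistics, and
authentication of degraded re-captures.

## The synthetic entropy source

`grow_cluster()` is an on-lattice DLA: walkers on the integer plane take
4-neighbour steps, attach with probability `stickiness` when 8-adjacent to
the cluster, are launched on a circle at cluster radius + 5, and are
relaunched past a kill radius of three times the launch radius. Two choices
deserve explanation.

**Inward drift.** Dried protein dendrites are markedly denser than classical
Witten–Sander clusters. That matters quantitatively: classical 2-D DLA has
mass scaling `N ~ R^1.71`, so 20 000 particles need a radius of roughly 330
sites and cannot fit a 512-site lattice; the reference configuration used
throughout this package (20 000 particles, 512 lattice) would abort at about
13 000 particles. Physically, a drying droplet is not a pure diffusion
field: evaporation drives a convective flux toward the aggregate. We model
this as an inward step bias of probability `drift` (default 0.35) active
only in the boundary layer around the cluster (within the launch radius);
outside it the walk is unbiased, which also lets far-field propagation be
sampled exactly in single jumps (the x/y split of an L-step walk is
Binomial(L, 1/2), each axis displacement a shifted Binomial — a
distribution-preserving shortcut, not an approximation). With the default
drift, all 54 reference devices stay well inside the lattice (max radius
about 204) and the rendered masks have box-counting dimension 1.59–1.62,
inside the generic 2-D DLA band used by the tests (1.55–1.85). Setting
`drift = 0` recovers the classical model for smaller clusters.

**One RNG per call.** Each growth call owns a Mersenne–Twister stream keyed
by `rng_seed`; R's global RNG is never touched, and identical parameters
reproduce identical clusters on any platform.

`render_image()` draws the cluster dark-on-light (the contrast of dark
bioink on a transparent film) with an optional Gaussian halo emulating the
lateral spread of a height map, and `box_counting_dimension()` estimates the
fractal dimension from dyadic box counts over at least four scales.

### What the generator does and does not emulate

The simulator reproduces the features the digitization pipeline actually
consumes: branched planar morphology with device-unique geometry, dark
foreground on light background, and a known ground-truth mask. It does not
model drying kinetics, height information, multi-scale AFM texture, or
illumination structure of real micrographs. Passing tests therefore
demonstrate the *pipeline's* correctness and statistical behaviour on
DLA-class imagery; they do not certify performance on any particular
laboratory image set.

## Image preparation

`binarize()` supports the three thresholding families usually considered
for such images: Otsu (the default; threshold maximizing between-class
variance of the 256-bin histogram, ties resolved to the lowest level, with a
flagged all-background result for constant images), fixed global
thresholding, and adaptive mean thresholding over an odd frame (default 31
pixels). All comparisons happen on the foreground-side intensity scale
(`255 - I` for dark-on-light material), which makes binarization exactly
polarity-symmetric.

Three corner fiducials ("+" and "C" glyphs at top-left, top-right and
bottom-left; bottom-right deliberately empty) make orientation unambiguous.
Defaults are a 32-pixel glyph and a 24-pixel margin: deep enough into the
frame that a few degrees of capture tilt cannot sweep a corner glyph out of
the image. The fiducial windows are stamped onto the printable label but
stripped (`strip_fiducials()`) before feature extraction, so keys depend
only on the PUF pattern.

`simulate_capture()` models a cooperative phone capture: rotation and random
perspective (composed into one homography and resampled once, bilinear),
Gaussian optics blur, a linear illumination ramp in a random direction,
additive sensor noise, and resampling. The "mild" conditions used in the
validation tests are rotations up to about 4 degrees, corner jitter 0.5% of
the side, blur sigma 1 px, a 10% illumination ramp and noise sd 5 on the
8-bit scale.

`prepare_for_model()` produces the backbone's canonical input: resample to
the input side (exact area averaging when shrinking, bilinear when
enlarging), map to [0, 1] with the aggregate bright, apply a fixed Gaussian
stabilization blur (sigma 3 px at the model scale), and replicate to three
channels. The stabilization blur is a deliberate design choice: binary
dendrites are one or two pixels wide, and without it a single-pixel
registration error flips a quarter of the biased bits; with it, genuine
re-captures keep bit agreement above 90% while impostor agreement stays
below about 72%. The blur is part of the canonical representation — applied
identically at enrollment and verification, and skipped when the input is
already a prepared raster so the operation stays idempotent.

## The deep hash

The digitization uses a convolutional feature extractor with its
classification layers removed, reducing each image to a fixed-length
feature vector (2048 features for the ResNet50-style registry entry, 1280
for the MobileNet-style one). Because the network is never trained, the
default backend draws every filter once from a seeded Gaussian stream
("seeded_random" weights): a fixed random convolutional projection is a
perfectly serviceable one-way feature map, fully reproducible offline.
Pretrained weights would require a model download and are deliberately not
bundled; requesting them raises an informative error.

The stack is five stride-2 convolutions. Interior layers apply instance
normalization (per-channel spatial standardization) followed by a ReLU
centred by its expectation under a standard normal input
(`relu(z) − 1/sqrt(2π)`). This combination matters: global average pooling
of plain ReLU activations is dominated by channel-constant offsets shared
by every image, and the quantized bits of different devices would be nearly
identical. After centring, the pooled response of each channel measures the
image-specific deviation of its activation statistics, so different devices
produce nearly independent bit patterns (measured biased-vector distance
about 0.38, key distance about 0.49) while the map remains deterministic.
The final convolution (the "decapitated head") is linear and globally
average-pooled into the feature vector.

## Digitization

* **Quantization** — the threshold is the mean of the feature values; a
  feature strictly above the mean becomes 1, at or below becomes 0. A
  constant vector legally quantizes to all zeros.
* **Von Neumann extraction** — non-overlapping pairs from the start:
  (0,1) → 1, (1,0) → 0, (0,0)/(1,1) discarded, trailing bit dropped. For
  independent input bits of any bias the output is exactly unbiased; the
  pair positions that survive differ from device to device, which also
  decorrelates residual structure between devices' keys.
* **Key derivation** — the key size is the largest of 64/128/256 bits not
  exceeding the shortest debiased vector in the set; keys are leading-bit
  prefixes. Devices that cannot support even 64 bits are reported as
  errors naming the device rather than silently dropped. With 2048-feature
  vectors the debiased lengths concentrate near 512 bits, so 256-bit keys
  derive comfortably.

## Key-quality evaluation

`evaluate_library()` reports per-key bit uniformity (fraction of ones,
ideal 0.5), all `m(m-1)/2` pairwise normalized Hamming distances (ideal
mean 0.5), and seven NIST SP 800-22 results per key: frequency, block
frequency, cumulative sums forward and reverse (two rows, as convention),
runs (with its `|π − 1/2| < 2/√n` prerequisite gate), longest run of ones
(block size 8 in the 128–6272-bit regime with the published category
probabilities), and approximate entropy. The closed forms use base R's
`pnorm`/`pgamma` for erfc and the regularized upper incomplete gamma;
everything else is computed directly and is checked in the test suite
against independently coded oracles to ten significant figures, against the
published worked examples, and for calibration (rejection rates at
α = 0.01 on uniform sequences inside the 99% binomial band).

Numerical notes. α defaults to 0.01 (the customary choice). Block size
defaults to 32 for 256-bit keys and 16 for 128-bit ones (at least 20 where
feasible while keeping 8+ blocks); the approximate-entropy template length
defaults to 2. 128- and 256-bit keys sit below some recommended sequence
lengths for these tests; that is conventional in PUF evaluation, and
results carry notes (and an `applicable` flag for the runs prerequisite)
rather than hard failures. The commonly recommended approximate-entropy bound
`m + 1 < log2 n` is advisory: the statistic is computable beyond it (the
published 10-bit worked example itself exceeds it), so the package only
refuses `m + 1 >= n` and notes under-sampled settings.

## Authentication

Verification composes: fiducial detection (normalized cross-correlation of
the corner glyphs at the four 90-degree candidate orientations, subpixel
peak refinement by quadratic interpolation), 3-point affine registration to
the canonical frame (three fiducials determine an affine map exactly; a
homography is not identifiable from three points), re-binarization,
fiducial stripping, the identical backbone recorded at enrollment, and
bitwise percent match. Matching uses the full-length *biased* vectors
rather than the derived keys: Von Neumann surviving-pair positions are
fragile under capture noise, so keys serve enrollment identity while biased
vectors serve similarity scoring.

The default accept threshold is 85%. On the synthetic study (20 devices,
5 mild captures each) genuine matches fall around 88–94% and impostor
matches around 62–72%, so 85% splits the distributions with margin on both
sides; it is configurable, and the one-time-use option (`retire_device()`)
removes a device after a successful match.

## Problem sizes and reproducibility

The package's reference study uses 54 devices (20 000 particles on a
512-site lattice, device seeds 1..54, backbone weight seed 0), which the
acceptance script re-runs end to end; the authentication study uses 20
devices with 5 captures each. On a single CPU the 54-device enrollment takes
well under a minute and the capture study a few minutes. Every random
component — growth, weights, captures — is seeded explicitly, and no stage
touches the caller's RNG state.

## Known limitations

* The entropy source is a 2-D lattice simulation; real micrographs bring
  texture, height shading and acquisition artifacts the generator does not
  model.
* Seeded-random features are a valid one-way map but are not the pretrained
  backbones a production deployment would use; absolute match percentages
  will differ with other feature maps even though the pipeline properties
  (uniformity, uniqueness, debiasing, separation) are representative.
* The key derivation is prefix truncation, not a salted cryptographic KDF,
  matching the enrollment protocol it implements rather than a general
  key-management standard.
* Registration assumes the label is approximately planar; strong
  perspective beyond the mild preset degrades matching before it degrades
  detection.
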