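---
title: "Detecting bright subnuclear objects in 3D: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bright subnuclear objects in 3D: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromoseg)
```

## The problem

Interphase plant nuclei (notably *Arabidopsis thaliana*) contain compact,
brightly staining heterochromatin domains — chromocenters — that appear as
high-intensity blobs in DNA-dye confocal stacks; DNA-FISH produces similar
punctate signals. Quantifying their number, volume and radial position per
nucleus is a standard readout in nuclear-organization studies. `chromoseg`
takes, per nucleus, a raw 3D grayscale stack and a binary nucleus mask
(produced upstream by a nucleus segmentation tool; mask generation is out
of scope here) and returns a labeled 3D object image plus calibrated
morphometrics.

## The detection model

For every voxel $x$ inside the nucleus mask the package computes a
Laplacian-style local contrast score

$$\delta_x = \frac{1}{s} \sum_{y \in N(s)} (v_x - v_y),$$

where $N(s)$ is the cubic neighborhood of radius $s$ voxels (window side
$2s+1$, center excluded). Neighbors outside the image bounds or outside
the mask are skipped, which makes everything beyond the nuclear envelope
invisible to the filter — a property asserted in the test suite by
randomizing out-of-mask intensities. The enhanced image is smoothed with a
separable 3D Gaussian, and a global adaptive threshold

$$t = \bar{x} + f \cdot \mathrm{sd}$$

is computed from the in-mask voxels of the smoothed enhanced image (mean
and *population* standard deviation). Voxels with values strictly above
$t$ are kept and grouped into connected components (26-connectivity by
default), each component being one detected object.

Because endoreduplication makes large nuclei both bigger and
coarser-textured, both parameters are adjusted automatically once per
nucleus when the calibrated nucleus volume exceeds 50 µm³:
$s \leftarrow \mathrm{round}(2.5\,s)$ and $f \leftarrow f + 1$. A volume
of exactly 50 µm³ counts as small (strict `>`), and both adjustments
trigger together.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `s` | neighborhood radius, voxels | 2 | tune per dataset; auto-scaled ×2.5 above 50 µm³ |
| `f` | threshold factor | 1.5 | tune per dataset; auto +1 above 50 µm³ |
| `sigma` | Gaussian width, voxels | 1.0 | isotropic in voxel space; per-axis values allowed; 0 disables |
| `volume_switch` | adjustment cutoff, µm³ | 50 | strict `>` |
| `connectivity` | component adjacency | 26 | 6 and 18 available |
| `min_volume` | object volume filter, µm³ | 0 (off) | optional post-filter |

The defaults for `s` and `f` are package choices exposed for tuning; the
Gaussian default of 1 voxel is likewise a package choice. Smoothing can be
disabled (`smoothing = FALSE`, or `--no-gaussian` in the CLI script).

### Numerical and design choices

* **Neighborhood geometry.** "Size $s$" is read as the *radius* of a
  cubic raster window, isotropic in voxel space; physical anisotropy
  (dz ≠ dx) is deliberately ignored in the filter, which operates on the
  voxel raster like ImageJ-style neighborhood filters.
* **Normalization.** The sum is divided by $s$, not by the neighbor
  count. The binarization is provably invariant to any affine rescaling
  $aE + b$ ($a > 0$) of the enhanced image, because the threshold is an
  affine-equivariant statistic of the same image — so this choice cannot
  change the segmentation. The test suite asserts this invariance
  bit-exactly on random stacks.
* **Strict threshold.** `enhanced > t` (strict) guarantees a constant
  image yields zero objects (its sd is 0, so t equals the constant).
* **Population sd.** Divisor $N$, fixed so that small hand-checkable
  examples are exact; for real nuclei ($N \sim 10^4$–$10^6$) the
  distinction from the sample sd is negligible.
* **Rounding of the s-adjustment.** Round half up, floored at 1, applied
  exactly once per nucleus.
* **Negative enhanced values** are kept; they lower the mean and widen
  the sd as the data dictate.
* **Smoothing before thresholding.** Threshold statistics are computed on
  the smoothed enhanced image, matching the pipeline order
  enhance → smooth → threshold → binarize → label.

## Morphometrics

Volumes are voxel counts times the calibrated voxel volume. The distance
from each object to the nuclear envelope is the minimum, over the
object's border voxels, of an anisotropic Euclidean distance transform of
the mask (sampling `(dy, dx, dz)` µm; Felzenszwalb–Huttenlocher separable
algorithm). Border voxels are object voxels with at least one 6-neighbor
outside the object, independent of the labeling connectivity — the
stable, standard surface definition. The image boundary counts as
background for the distance transform (the mask is padded by one
background voxel), so masks touching the stack edge still get finite
distances. The per-nucleus figure is the mean of per-object minima.
Distances are reported in µm; a reading of "distance to the nuclear
envelope" as border-to-envelope minimum (not barycenter-based) is used
throughout. On concentric sphere-in-sphere phantoms the recovered
distance matches $R - r$ within one voxel diagonal (asserted in the
tests).

Barycenters are reported in µm using 0-based voxel indices times the
pitch. Tables use `NA` as the missing-value sentinel, e.g. for the mean
object volume of a nucleus with zero detections.

## The phantom generator and what it does (not) show

`phantom_spec()` describes an ellipsoidal nucleus with spherical
chromocenters at three constant intensity levels plus optional Gaussian
texture. The defaults are the package's study conditions, chosen once to
emulate a small Arabidopsis-like nucleus:

* semi-axes 2.2 × 2.5 × 2.0 µm (volume ≈ 46 µm³) at 0.1 µm isotropic
  voxels (image 50 × 56 × 46);
* 6–10 chromocenters per nucleus, radius 0.3–0.5 µm, at least 0.25 µm
  clear of the envelope and 0.2 µm of each other (rejection-sampled;
  infeasible specs error out after bounded attempts);
* intensity levels 10 (background), 90 (nucleoplasm), 200 (chromocenter)
  on the 8-bit scale, no texture by default.

Object intensity is more than twice the nucleoplasm level and radii are
at least 3 voxels, so the defaults constitute the "easy regime" used for
the recovery benchmark: on 100 seeded noiseless phantoms the pipeline
recovers the exact planted count in ≥ 95% of nuclei with mean per-object
volume error ≤ 30% (measured: 100% and ≈ 2% at seed 1; objects are
matched to ground truth by maximal voxel overlap because raster-scan
label order differs from planting order).

The noise benchmark adds salt-and-pepper corruption — exactly
`round(fraction · n_voxels)` distinct voxels, sampled over the whole
image, set to the dtype extremes with equal probability — at 5, 10, 25,
50 and 75%, and scores each segmentation against the planted truth by
voxel overlap: `tp = |pred ∩ truth| / |truth|`, `fn = 1 − tp`,
`fp = |pred \ truth| / |truth|` (fp can exceed 1). A
`reference = "noiseless"` mode instead scores noisy segmentations against
the segmentation of the clean image, mirroring a comparison of noisy
versus raw detections. A master seed spawns per-phantom and
per-noise-draw child seeds by fixed arithmetic, so any subset of the
experiment is reproducible in isolation; the whole results table is
bit-identical across reruns. Fifty phantoms per level are used in the
shipped validation runs, and the mean TP fraction decreases strictly with
the noise level.

What the phantoms do **not** emulate: realistic microscope
point-spread-function blur, Poisson shot noise, intensity gradients,
nonspherical or touching chromocenters, and nucleoli or other
intermediate-intensity structures. Passing the phantom benchmarks
therefore demonstrates correctness of the algorithmics and robustness to
impulse noise, not segmentation accuracy on any particular real dataset —
on real data `s` and `f` must still be tuned and validated against expert
annotation.

At the generator's full published scale the bookkeeping is 1526 phantoms
× (1 noiseless + 5 noise levels) = 9156 images; the shipped validation
runs the identical code at 50–100 phantoms, which completes in about a
minute on one CPU while exercising every code path.

## I/O conventions

Stacks are multi-page grayscale TIFFs (8/16-bit), arrays `(ny, nx, nz)`.
Calibration is read from TIFF x/y resolution tags and the ImageJ-style
`spacing` description field; since the TIFF writer used cannot emit those
tags, stacks written by this package carry their calibration in a
plain-text sidecar `<file>.calibration.tsv`, which `read_stack()` prefers
when present. A per-call override and a warning fallback to 1 µm voxels
complete the precedence chain. Label images are written as 16-bit TIFFs
(0 = background, 1..n = objects; at most 65535 objects). Batch runs are
order-independent (entries are processed in sorted nucleus-id order), a
failing nucleus is skipped and logged without aborting the batch, and
reruns overwrite deterministically.

## Known limitations

* One nucleus per image pair is assumed; fields of view with several
  nuclei must be split upstream.
* The adaptive threshold is global per nucleus; objects in strongly
  shaded regions of a nucleus may be missed at low `f`.
* `fp_fraction` is normalized by the truth volume, so heavily
  over-segmenting runs (e.g. 75% noise) report values above 1 by design.
* The envelope distance is voxel-accurate, not subvoxel: expect errors up
  to one voxel diagonal.
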