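# chromoseg

Automated 3D detection and morphometry of bright subnuclear objects —
chromocenters and DNA-FISH spots — in single-nucleus confocal stacks.

Interphase plant nuclei (e.g. *Arabidopsis thaliana*) contain compact
heterochromatin domains that stain as high-intensity blobs. Given a raw
grayscale stack and a binary nucleus mask per nucleus (masks come from an
upstream nucleus-segmentation tool), `chromoseg` segments those blobs and
quantifies them: object count, calibrated volumes, barycenters, and the
distance from each object's border to the nuclear envelope.

## The method

For every voxel $x$ inside the mask, a Laplacian-style local contrast
score is computed over the cubic neighborhood $N(s)$ of radius $s$ voxels
(center excluded; neighbors outside the image or the mask are skipped):

$$\delta_x = \frac{1}{s} \sum_{y \in N(s)} (v_x - v_y)$$

The enhanced image is smoothed with a 3D Gaussian ($\sigma = 1$ voxel by
default), thresholded at

$$t = \bar{x} + f \cdot \mathrm{sd}$$

(mean and population sd over in-mask voxels, strict `>`), and the
surviving voxels are grouped into 26-connected components, one label per
object. Nuclei larger than 50 µm³ (typical of endoreduplicated tissue)
automatically get $s \leftarrow \mathrm{round}(2.5\,s)$ and
$f \leftarrow f + 1$. Distances to the envelope use an anisotropic
Euclidean distance transform of the mask with the voxel calibration in
µm.

The package also ships a ground-truthed phantom generator (ellipsoidal
nuclei with planted spherical chromocenters) and a salt-and-pepper
noise-robustness benchmark scored by voxel-level TP/FN/FP fractions.

## Worked example

```r
library(chromoseg)

# a synthetic nucleus with known ground truth
gt  <- generate_phantom(phantom_spec(seed = 42))
seg <- segment_nucleus(gt$raw, gt$mask, gt$cal, seg_params())
seg
#> nucleus segmentation: 6 object(s) | nucleus 46.1 um^3 | s_eff=2 f_eff=1.5 t=476.649

res <- summarize_nucleus(seg$labels, gt$mask, gt$cal,
                         nucleus_id = "demo", provenance = seg)
res$summary[, c("nucleus_id", "nucleus_volume", "n_objects",
                "mean_object_volume", "mean_border_distance")]
#>   nucleus_id nucleus_volume n_objects mean_object_volume mean_border_distance
#> 1       demo         46.056         6              0.299            0.6659703

ov <- overlap_stats(seg$labels, gt$truth)
sprintf("TP %.3f  FN %.3f  FP %.3f", ov$tp_fraction, ov$fn_fraction, ov$fp_fraction)
#> "TP 0.984  FN 0.016  FP 0.008"
```

The phantom planted 6 chromocenters; all 6 are recovered, the nucleus
volume is the ellipsoid's 46 µm³, mean object volume is 0.30 µm³, the
mean object sits 0.67 µm from the envelope, and 98.4% of true object
voxels are recovered with 0.8% spillover.

For real data, batch-process paired TIFF directories either from R
(`pair_inputs()` + `run_batch()`) or from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/segment_objects.R", package = "chromoseg"))')" \
    --raw-dir raw/ --mask-dir mask/ --out results/ --s 2 --f 1.5
```

This writes one 16-bit label TIFF per nucleus plus two tab-delimited
tables (`NucAndCcParameters3D.tab`, one row per nucleus;
`CcParameters.tab`, one row per object) and a log of the effective
parameters and threshold per nucleus. `--s` and `--f` should be tuned per
dataset.

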