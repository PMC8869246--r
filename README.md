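# phaseseg

Automated foreground–background segmentation of phase-contrast microscopy
cell images, in R.

## The problem

Confluence — the fraction of the culture surface covered by adherent cells —
is the everyday readout of cell proliferation, and estimating it from a
phase-contrast micrograph means separating cellular foreground from
acellular background. Phase-contrast images are hostile to both manual
annotation and classical edge detection: cell bodies are dark and granular
on a brighter fuzzy background, detached cells leave large diffuse bright
halos, debris specks drift across the field, and illumination is uneven.
`phaseseg` is for cell-culture and bioimage researchers who need a
no-human-input segmentation of such images — for confluence tracking
directly, or to mass-produce binary masks as training labels for neural
segmentation models.

## The method

The image is the only input. With grayscale dilation `d = f ⊕ D` and erosion
`e = f ⊖ D` over a 3×3 structuring element `D`, the pipeline synthesises
edge information morphologically instead of convolutionally:

    E_ext = d − f        (dark side of each transition)
    E_int = f − e        (bright side)
    E_mid = d − e        (morphological gradient)
    E_all = min(E_ext + E_mid + E_int, 255)

The combined edge image is blurred, sharpened with the 3×3 Laplacian kernel,
and binarized with Otsu's threshold — computed on the *edge* image, where
"edge vs non-edge" is a well-conditioned two-class problem, so no threshold
is ever hand-picked. Two branches then build the mask: small-cell contours
are filled solid (components under a 20 px debris floor are dropped), and
cell clusters are located by 9×9 closing/opening with enclosed gaps
classified by intensity — a gap whose mean gray value looks like the
background stays open, one that looks like cell interior is filled. The
union of the branches is the final mask; confluence is its pixel fraction:

    dice = 2|X∩Y| / (|X|+|Y|),  IoU = |X∩Y| / |X∪Y|,  relerr = |Â−A| / A

are the shipped evaluation metrics against reference masks.

Because the laboratory corpora such pipelines are validated on are normally
restricted, the package also ships a seeded synthetic scene generator
(irregular textured cell bodies, diffuse halos, debris, vignetting, noise)
with exact ground truth, plus the three robustness protocols — blur, image
size, illumination — as sweep drivers.

## Worked example

```r
library(phaseseg)

scn <- generate_scene(scene_spec(width = 400, height = 300,
                                 cell_radius_range = c(14, 26), seed = 42))
scn
#> Synthetic scene 400 x 300 (seed 42): 35.34% true confluence

res <- segment_cells(scn$image, seg_config(resize = FALSE))
res
#> Phase-contrast cell segmentation
#>   image          : 400 x 300 px
#>   Otsu threshold : 98
#>   area fraction  : 0.3801 (38.01% confluence)
#>   blobs          : 33 small-cell, 19 cluster

dice(res$mask, scn$truth_mask)                                  # 0.9105
iou(res$mask, scn$truth_mask)                                   # 0.8357
relative_area_error(res$area_fraction, scn$true_area_fraction)  # 0.0756
```

The Otsu threshold (98 here) was found automatically on the sharpened edge
image; the estimated confluence (38.0%) overshoots the true 35.3% by the
few-pixel boundary band the edge operators add, giving a 7.6% relative area
error; dice 0.91 means the mask and the ground truth overlap on 91% of
their average extent. `plot(res)` overlays the mask boundary on the input;
`summary(res)` reports per-region areas and foreground/background mean
intensities.

Real micrographs go through the same call — `segment_cells("img.png")`
resizes to the 800×600 working frame by default and returns the mask,
foreground/background images and confluence; `write_segmentation()` writes
them with a JSON sidecar. A command-line wrapper with `segment`, `eval`,
`sweep` and `synth` subcommands is installed at `inst/cli/phaseseg`.

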