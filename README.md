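# intensify3d

Signal-intensity normalization for large single-channel fluorescence
microscopy image stacks (2-photon, light-sheet), implementing the
Intensify3D procedure, together with a synthetic-sphere validation
framework so the whole pipeline can be exercised and scored without any
real microscopy data.

## Who this is for

Anyone quantifying 3D structures from Z-stacks — soma counting, neurite
reconstruction, threshold-based segmentation, 3D rendering — where
depth-dependent attenuation, lateral illumination gradients, or
plane-to-plane brightness jumps make a single intensity scale meaningless
across the stack.

## The method

Two working assumptions: the *background* intensity distribution should be
identical everywhere (observed differences are artifact), and signal pixels
are sparse while background pixels are numerous, so background quantiles
are estimable on every plane. The user supplies two parameters: the
**maximum background intensity** (MBI, the highest pixel value attributable
to background on a reference plane) and the **spatial filter size** (SFS,
roughly twice the largest signal structure).

Per plane (*XY normalization*): pixels above the propagated MBI are deleted
and re-filled from the local background distribution; a separable 2D
Savitzky–Golay surface of window SFS fitted to the signal-free plane
becomes the background mask *M*; the plane is corrected by division,

&nbsp;&nbsp;&nbsp;&nbsp;*N(x) = I(x) / M(x) · s*,&nbsp;&nbsp; *s* = median of *M* over tissue,

so background gradients flatten while signal-to-background ratios are
preserved exactly. Across the stack (*Z normalization*), each plane is
summarized by 10,000 recorded quantiles of its tissue pixels and harmonized
by one of three monotone maps: upper-quantile scaling, contrast stretch
(10th percentile ↔ upper quantile), or semi-quantile normalization (full
quantile matching below the upper quantile, linear stretch above it). For
light-sheet data an automatic tissue detector (PCA features + 2-cluster
Gaussian-mixture EM or k-means, per plane) restricts everything to tissue
pixels so imaging medium is never "corrected".

The package also ships the validation apparatus: a Gaussian-sphere phantom
generator with four analytic distortion fields (linear in X, linear in X
and Y, logarithmic in Z, combined), and a scoring module (threshold-based
3D object counting against ground truth, greedy matching, per-sphere error
statistics, histogram earth-mover distance).

## Worked example

Generate the desk-scale phantom, distort it with the combined
lateral-plus-depth field, correct the distorted stack, and score both
against the undistorted original:

```r
library(intensify3d)

spec    <- phantom_spec(seed = 1)          # 128 x 128 x 64, 50 spheres
phantom <- generate_phantom(spec)
val     <- sphere_validation("combined_xy_logz", spec, phantom = phantom)

val$reference$cmp$tpr                      # 1  (undistorted baseline)
sprintf("distorted: TPR %.2f FDR %.3f EMD %.4f",
        val$distorted$cmp$tpr, val$distorted$cmp$fdr, val$distorted$emd)
#> "distorted: TPR 0.70 FDR 0.186 EMD 0.0201"
sprintf("corrected: TPR %.2f FDR %.3f EMD %.4f",
        val$corrected$cmp$tpr, val$corrected$cmp$fdr, val$corrected$emd)
#> "corrected: TPR 1.00 FDR 0.000 EMD 0.0077"
round(val$corrected$mae[1:3], 3)   # vs 0.443 / 0.170 / 0.499 distorted
#>          voxel_count       mean_intensity integrated_intensity
#>                0.057                0.013                0.066
```

Reading: the combined distortion hides almost a third of the spheres from
a fixed detection threshold (TPR 0.70) and badly mismeasures the ones it
finds (44% relative error in voxel count). After correction every sphere
is recovered with no false detections, the per-sphere error statistics
drop to a few percent, and the intensity histogram moves close to the
undistorted original.

To normalize a real stack on disk:

```r
cfg <- norm_config(mbi = 450, sfs = 49, reference_plane_index = 32,
                   z_mode = "semi_quantile",
                   tissue = tissue_config("gmm_em"), seed = 1)
run_normalize("raw_planes/", "corrected/", cfg)
# corrected/ now holds the corrected TIFF series, support/ tissue masks,
# quantile_log.txt, plane_records.tsv, and manifest.json
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/intensify3d` (subcommands `normalize`, `phantom`,
`evaluate`).

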