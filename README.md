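# lcpca

Local complex PCA denoising for multi-contrast MRI, in R.

High-resolution quantitative MRI — e.g. a multi-echo MP2RAGE (MP2RAGEME)
acquisition yielding five co-registered images per scan — trades voxel size
against signal-to-noise ratio. Because the contrasts share anatomy, their
joint redundancy can be separated from noise by principal component
analysis over small image patches. `lcpca` implements this for the
*complex* MR signal: working on reconstructed real/imaginary channel pairs
keeps the noise Gaussian (the magnitude alone is Rician-biased at low SNR),
and makes the noise floor of each patch spectrum estimable with a simple,
interpolation-robust linear fit.

## Method

For each contrast, the wrapped phase is unwrapped (quality-guided region
growing, guided by the magnitude) and split by total-variation (ROF)
smoothing into a smooth **global phase** (air cavities, B0; removed) and a
**residual local phase** (anatomy + noise; kept). Real and imaginary
channels

    real_c = m_c * cos(phi_res,c),   imag_c = m_c * sin(phi_res,c)

turn M_c contrasts into M = 2 M_c channels with identical Gaussian noise
statistics.

The channel stack is cut into overlapping N×N×N patches (N = 4). Each
patch's N³×M matrix is column-centered and decomposed by SVD. A straight
line is fitted by least squares to the ⌊M/2⌋ lowest singular values — the
noise floor — and every singular value exceeding (1 + α) times the line at
its rank (α = 0.05) is retained; the rest are removed. Patches are
reconstructed from the retained components and recombined with weights
W = 1/(1 + M_kept). Patch-weighted maps of M_kept and of the noise-line R²
are produced for quality control. Finally magnitudes and phases are
recomputed and the wrapped global phase is reintroduced.

A Marchenko–Pastur (random-matrix) threshold is included as a comparison
method: it matches the linear fit on independent noise but degrades
strongly once interpolation correlates the noise across voxels, which the
linear fit tolerates.

The package also provides a synthetic multi-contrast phantom with known
truth (piecewise-constant structures, thin bright tubes, polynomial global
phase, complex Gaussian noise), the patch-level threshold simulation study
(signal rank 3, SNR 10/20, three interpolation regimes), log-domain T2*
relaxometry (`ln S = ln S0 − TE·R2*`) and region SNR statistics
(mean/std per structure).

## Worked example

```r
library(lcpca)

# patch-level threshold study: rank-3 signal in 4x4x4 patches, 10 channels
ex <- run_threshold_experiment(patch_sim_spec(rank = 3, snr = 20,
                                              reps = 2000, seed = 1))
ex
#> <threshold_experiment> n=4 m=10 rank=3 snr=20 interp=none reps=2000
#> # A tibble: 2 × 3
#>   method     median_kept mean_kept
#>   <chr>            <dbl>     <dbl>
#> 1 linear_fit           3      3.52
#> 2 rmt                  3      3.08

# full pipeline on a synthetic 5-contrast phantom at tissue SNR 10
ph  <- generate_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 2L))
res <- lcpca_denoise(ph$noisy)
res
#> <lcpca_result> 5 contrast(s); mean retained dimension 1.44; mean fit R^2 0.958

snr_improvement(ph$noisy$magnitudes[[2]], res$denoised$magnitudes[[2]],
                ph$structure_masks, label_names = ph$structure_names)
#>            label snr_original snr_denoised improvement
#> 1         tissue     8.741853     24.89695   16.155094
#> 2 nucleus_bright    12.651444     23.16900   10.517552
#> 3   nucleus_dark     5.494251     10.46250    4.968252
#> 4         vessel    14.925751     28.46983   13.544083
```

Both thresholds find the true signal dimension (median 3 of 10 kept), and
denoising raises the region SNR (mean over standard deviation within each
structure) in every structure. The mean retained dimension well below M and
the near-1 fit R² indicate the noise-line model fits the patch spectra.

The same functionality is scriptable through the installed CLI:

```sh
exec/lcpca simulate --rank 3 --snr 20 --reps 10000 --seed 7
exec/lcpca denoise --magnitudes m1.nii.gz,m2.nii.gz --phases p1.nii.gz,p2.nii.gz --out out/
```

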