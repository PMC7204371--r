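# shearfuse

Pixel-level fusion of co-registered multimodal medical images — CT with MR,
MR-T1 with MR-T2, or gray MR with pseudo-colour PET/SPECT maps. Different
modalities image complementary tissue properties (CT resolves bone and
vessel boundaries, MR resolves soft tissue, ECT maps function at low
resolution); fusion composites them into a single image for clinical
reading.

## Method

The pipeline has four stages:

1. **NSST decomposition.** Each source is split by a non-subsampled
   shearlet transform into a low-frequency band `L` and directional
   high-frequency bands `H^{l,k}` (level `l`, orientation `k`), all the same
   size as the input. The transform is built from Meyer-windowed radial and
   angular frequency tilings satisfying a sum-of-squares identity, so it is
   shift-invariant and reconstructs exactly.
2. **High-frequency fusion by a parameter-adaptive PCNN.** Each band pair
   drives a lattice of pulse-coupled neurons, one per coefficient, fed with
   the normalized `|H|`:

       F[n] = S
       L[n] = V_L Σ W · Y[n-1]
       U[n] = e^(-α_f) U[n-1] + F[n] (1 + β L[n])
       Y[n] = 1 if U[n] > E[n-1] else 0
       E[n] = e^(-α_e) E[n-1] + V_E Y[n]
       T[n] = T[n-1] + Y[n]

   All constants (`α_f`, `α_e`, `V_E`, `λ = β V_L`) are computed from band
   statistics (standard deviation, maximum, Otsu threshold), and the link
   strength `β ∈ [0, 1]` is refined by a grid search minimising a two-class
   dispersion objective over the linked-but-unfired neurons. The fused
   coefficient is taken, per pixel, from the source whose neuron fired more
   often over `N = 110` iterations (ties to the first source).
3. **Low-frequency fusion by convolutional sparse coding.** Both low bands
   (mean-removed) are coded over a shared dictionary of 32 unit-norm 8×8
   filters by solving the convolutional basis-pursuit problem
   `argmin_x ½‖Σ_m d_m ⊗ x_m − s‖² + λ Σ_m ‖x_m‖₁` with a Fourier-domain
   ADMM solver. Per pixel, the band with the larger smoothed ℓ1 coefficient
   activity contributes its whole coefficient vector; the fused band is the
   synthesis plus the average DC.
4. **Inverse NSST** of the fused band set yields the fused image. For a
   pseudo-colour second input, only its luminance is fused; chrominance
   passes through unchanged.

Results are scored with six standard indices: entropy (EN), edge-information
retention (Q^AB/F), mutual information (MI), average gradient (AG), spatial
frequency (SF) and standard deviation (SD).

## Worked example

The package ships a synthetic phantom generator emulating complementary
CT-like / MR-like structure (a skull-like ring only in A, a focal lesion
only in B), with ground-truth masks:

```r
library(shearfuse)
pair <- make_gray_pair(seed = 7, size = 256)
res <- fuse_images(pair$modality_a, pair$modality_b, metrics = TRUE)
print(res)
#> Fusion result: 256 x 256 (gray)
#>   gray range before clipping: [-0.0167, 0.9820]
#> Fusion quality metrics
#>   EN      6.9128 bits
#>   Q_ABF   0.6251
#>   MI      4.0324 bits
#>   AG      8.2908
#>   SF     14.3864
#>   SD     56.2284
```

EN/MI are in bits of the 8-bit grey histogram; AG/SF/SD are on the 0–255
intensity scale. Structure retention against the ground-truth masks:

```r
phantom_contrast(pair$modality_a, pair, "ring")    # 0.575 in source A
phantom_contrast(res$fused_gray, pair, "ring")     # 0.456 after fusion
phantom_contrast(pair$modality_b, pair, "lesion")  # 0.264 in source B
phantom_contrast(res$fused_gray, pair, "lesion")   # 0.222 after fusion
```

Both modality-exclusive structures survive fusion with most of their
contrast. A command-line interface is available as `inst/exec/shearfuse`
(subcommands `fuse`, `metrics`, `demo`, `learn-dict`); `demo --seed 7`
reproduces the example above from a shell.

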