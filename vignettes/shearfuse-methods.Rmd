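---
title: "Methods: shearlet-domain multimodal image fusion with a parameter-adaptive PCNN and convolutional sparse coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shearlet-domain multimodal image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in **shearfuse**, the
parameters that matter, the numerical choices behind them, and what the
synthetic test fixtures do and do not demonstrate.

## The fusion model

Two co-registered sources `A` and `B` (gray, `[0, 1]` scale; `B` may be a
pseudo-colour map whose luminance is fused while its chrominance passes
through) are fused in four stages: multiscale decomposition, high-band
fusion, low-band fusion, reconstruction. The design premise is that the
detail content of the two modalities is complementary and is best arbitrated
per orientation band by a neuron model sensitive to local coefficient
activity, while the slowly-varying approximation content is better
arbitrated by a sparse-synthesis activity measure that is robust to small
misregistration.

## Non-subsampled shearlet transform

The transform is constructed entirely in the frequency domain. Radial Meyer
windows partition the plane into a low-pass disc and `L` annuli with smooth
`sin/cos` transitions (the Meyer auxiliary polynomial guarantees
`rise² + fall² = 1`); each annulus is further partitioned into `K_l`
orientation wedges by Meyer angular windows with the same sum-of-squares
property, symmetrised over antipodes so every band of a real image is real.
Because the squared windows tile frequency space exactly, applying each
window once for analysis and once for synthesis reconstructs the input —
perfect reconstruction is a property of the construction, not of a solver
tolerance. On the discrete grid, the windows are additionally averaged with
their index-negated mirrors and the stack renormalised by its sum of
squares; this repairs the Nyquist-row asymmetry of even-sized DFT grids and
keeps both exactness properties to machine precision (the test suite bounds
the round-trip error at `1e-6`; observed error is ~`1e-15`).

Choices a user can make:

* `levels` (default 4) and `directions` (default `16, 16, 8, 8`, finest
  annulus first). These are the conventional settings in shearlet-domain
  fusion work; more directions sharpen orientation selectivity at linear
  cost in time and memory.
* Boundary handling is periodic (FFT-native) and is the one assumption a
  user should keep in mind near image borders.
* Images must be at least `2^(levels + 2)` pixels per side so the coarsest
  annulus is resolved on the frequency grid; smaller inputs raise a sizing
  error naming that minimum.

## Parameter-adaptive PCNN for the high bands

Each high-band pair is fused by the simplified pulse-coupled neuron lattice
described in the README (feed `F = |H|` normalised, 8-neighbour link with
inverse-distance weights and zero centre, exponential decays, dynamic
threshold). All fields start at zero, which gives a defined first step —
every neuron with positive stimulus fires at `n = 1` — and the firing count
`T` accumulated over `N` iterations is the activity measure: the fused
coefficient is the one whose neuron fired more often, ties taken from `A`.

The free parameters are derived from band statistics on the normalised
stimulus: `alpha_f = ln(1/sigma)`, `lambda = (S_max/S' - 1)/6` with `S'` the
Otsu threshold (EBImage), `V_E = exp(-alpha_f) + 1 + 6 lambda`, and
`alpha_e` from the closed form documented in `?compute_adaptive_params`.
Degenerate bands are guarded: `sigma` is floored at `1e-4`, the Otsu
threshold at `1e-4` (a flat band yields `lambda = 0`), and `alpha_e` at
`1e-3` so all decays stay strictly positive.

The link strength `beta` is then refined once per band by a grid search
over `[0, 1]` (step `delta_beta`, default 0.01): at the first iteration
where fired and unfired neurons coexist, the candidate set
`X = {L > 0, Y = 0}` is split by each trial `beta` into neurons that would
stay below threshold versus fire, and the chosen `beta` minimises the
within-class dispersion of the stimulus around the unfired/fired class
means. Ties go to the smaller `beta` (deterministic), and an empty `X`
falls back to the adaptive `lambda` clamped to `[0, 1]`. Two conventions
here were genuinely open and are package decisions: the candidate set is
evaluated on the *previous* firing state (the current one depends on the
`beta` being searched), and the search runs once per band and is then held
fixed — re-running it every iteration changes results negligibly on the
phantoms while multiplying cost.

A further package decision: the two bands of a pair are normalised by their
*common* maximum before driving the networks. Normalising each band by its
own maximum would let an almost-flat band fire as vigorously as a strongly
structured one and corrupt the firing-count comparison.

`N = 110` iterations (conventional for this model family) is enough for the
threshold dynamics to cycle several times; the count map is integer-valued
in `[0, N]`, non-decreasing in `n`, and the compiled implementation is
tested for exact (bit-level) agreement with a literal scalar transcription
of the update equations.

## Convolutional sparse coding for the low band

The low bands are mean-removed and coded over a shared dictionary of
`M = 32` unit-norm `8×8` filters by convolutional basis-pursuit denoising
with sparsity weight `lambda_csr = 0.01` (bands on the `[0, 1]` scale).
The solver is the Fourier-domain ADMM: the quadratic subproblem is solved
exactly per frequency bin via the rank-one Sherman–Morrison identity, the
`l1` subproblem by soft thresholding, with the standard primal/dual
residual stopping rule (`rho = 10 lambda + 0.1`, `max_iter = 200`,
tolerances `1e-4`). Convolution is circular, consistent with the
transform's periodic boundary. The solver tracks the objective at every
iterate and returns the best one seen *including the zero initialisation*,
so the returned objective can never exceed the zero-solution bound
`½‖s‖²`; if the residual criterion is not met a warning is emitted rather
than an error.

Fusion rule: per pixel, the `l1` norm of each band's coefficient vector,
smoothed by a `3×3` box filter, decides which band's entire vector is kept
(ties to `A`); the fused band is the synthesis plus the average of the two
source means. The smoothing window and the ℓ1 activity are package
decisions (the established choose-max convention in CSR fusion); the DC
average is a decision forced by the model coding only zero-mean signals.

Dictionary learning alternates coding with a constrained dictionary update
(ADMM with a conjugate-gradient frequency-domain solve, then projection
onto the zero-padded support and the unit sphere). Two safeguards make the
recorded objective provably non-increasing: coding steps are warm-started
and return best-seen iterates, and a dictionary update that would increase
the data-fit term for the current coefficients is rejected. The shipped
dictionary (`inst/extdata/dict_synthetic_m32.txt`, plain text) was learned
with seed 1 from the transform low bands of four synthetic phantoms at
128×128, 20 alternations; `csr_learn_dictionary()` or the CLI `learn-dict`
subcommand rebuilds it.

## Quality indices

`compute_metrics()` clips to `[0, 1]`, rescales to the 8-bit range, and
reports EN, Q^AB/F, MI, AG, SF and SD with the conventions listed in its
help page (256-bin histograms with `0·log 0 = 0`; MI as the unnormalised
sum `I(F;A) + I(F;B)`; population SD; RMS first differences for SF;
forward-difference interior mean for AG). Q^AB/F uses Sobel strength and
orientation with the standard sigmoid constants
(`Γ_g = 0.9994, κ_g = -15, σ_g = 0.5; Γ_α = 0.9879, κ_α = -22,
σ_α = 0.8`); each sigmoid is normalised by its value at perfect transfer so
that a fused image identical to both sources scores exactly 1 — the raw
sigmoids saturate slightly below 1, which would make the perfect-transfer
property hold only approximately. Pixels where neither source has any edge
contribute no weight; an image pair with no edges at all is scored 1 by
convention. Colour fused images are scored on luminance.

## Synthetic phantoms: what they do and do not show

`make_gray_pair()` builds a CT-like/MR-like pair: a bright skull-like ring
with additive Gaussian noise (sd 0.02) in A; an attenuated ring, smooth
band-limited texture (Gaussian-smoothed white noise), a gentle gradient
and a focal bright lesion in B. The construction guarantees measurable
contracts — ring contrast ≥ 0.3 stronger in A, lesion contrast ≥ 0.2 in B
and ≤ 0.05 in A — with disjoint ground-truth masks, so structure retention
through fusion is a computable quantity rather than a visual judgement.
`make_color_pair()` adds a pseudo-colour hotspot map with nonconstant
chroma for the luminance–chrominance path.

These phantoms exercise every code path (multi-scale detail, smooth
approximation content, modality-exclusive structure, colour passthrough)
but they are not anatomy: they contain no fine cortical texture, no
modality-specific noise physics, no partial-volume effects and no
registration error. Passing the phantom tests demonstrates the mechanics
and the selection behaviour of the method, not clinical image quality on
hospital data.

## Problem sizes and determinism

The test suite runs the transform properties at 64×64 (20 random images),
the neuron-dynamics oracle at 8×8 with `N = 110`, coding checks at 32–64
pixels square, self-fusion at 128×128 and the full pipeline and CLI demo at
the 256×256 working resolution; these sizes keep the whole suite to a few
minutes on one core while still covering the full-resolution path. The
pipeline is deterministic: the only randomness in the package is the seeded
phantom generator and the seeded dictionary initialisation, so identical
inputs, configuration and seed give byte-identical outputs (the CLI demo is
tested for this).

## Known limitations

* Registration is assumed; the method does not align inputs.
* Periodic boundaries can mix opposite borders for structure touching the
  image edge.
* The metric suite scores gray content; chrominance fidelity is enforced
  structurally (bit-exact passthrough) but not scored.
* MI is reported as a plain sum; normalised variants exist and differ by a
  monotone rescaling per image pair.
* DICOM input, batch execution and the comparison fusion algorithms from
  the literature are out of scope.
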