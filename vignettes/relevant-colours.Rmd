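---
title: "Relevant colours of paintings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relevant colours of paintings: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A human observer glancing at a painting does not perceive the thousands of
colours a discernible-colour count reports; they retain a small palette of
"relevant colours" — typically around twenty — that describes the picture's
chromatic content. This package implements the computational side of that
observation as a reproducible pipeline: colourimetric gamut descriptors,
relevant-colour extraction (both from pixel statistics and from observer
selections), palette-based image segmentation with a correlation fidelity
measure, spatial-pyramid complexity metrics, and an independent component
analysis (ICA) of image patches that yields preferred colour directions in an
opponent colour plane.

Because curated painting corpora and human click data are external resources,
the package ships synthetic generators that emulate the statistical structure
those analyses assume — palette-structured images and a clicking observer —
so every stage is testable end to end with known ground truth. All stages are
deterministic given their seeds.

## Colour representation

Images are decoded to sRGB arrays in $[0,1]$ and converted to CIELAB under
the D65 white point and the 2° observer (standard sRGB linearization, the
RGB-to-XYZ primaries matrix, then the CIELAB functions). The white point and
observer are an assumption: image files are treated as standard sRGB because
nothing else about their provenance is knowable from the files alone. The
conversion is implemented in double precision inside the package — the
pipeline bins colours on a *unit* CIELAB grid, so the conversion chain must
round-trip far below 1 JND (it round-trips below $10^{-12}\ \Delta E^*_{ab}$;
the test suite cross-checks absolute agreement with an independent converter
at $\Delta E \le 0.01$).

Derived coordinates:

* polar chroma/hue: $C^*_{ab} = \sqrt{a^{*2} + b^{*2}}$,
  $h_{ab} = \mathrm{atan2}(b^*, a^*)$ in degrees folded to $[0, 360)$.
  Achromatic colours get hue 0 with an explicit flag rather than `NaN`, so
  histograms stay well defined.
* the opponent plane used for colour directions:
  $RG = (R - G)/\sqrt{2}$, $BY = (R + G - 2B)/\sqrt{6}$, applied to sRGB
  channel values as stored (no linearization: the opponent transform is
  defined directly on RGB values). The two rows are orthonormal, which makes
  planting and recovering colour axes exact. The colour angle is
  $\theta = \mathrm{atan2}(BY, RG)$, reported signed, folded to $[0,360)$ for
  colours, or folded to $[0,180)$ for principal axes, which carry no sign.

## Gamut descriptors

**Discernible colours.** Colour space is segmented into half-open unit cells
(`floor()` of each coordinate; boundary colours belong to the lower cell,
which keeps the count deterministic and oracle-checkable). Colours sharing a
cell differ by at most ~1 CIELAB unit and are treated as indiscernible. Two
modes exist because the source method is ambiguous between them: `lab-3d`
(unit cubes over $L^*, a^*, b^*$; the default, following the 3-D lineage of
discernible-colour counting) and `ab-2d` (unit squares over the chromatic
plane only). The 2-D count can never exceed the 3-D count.

**Colour volume.** The default is the volume of the convex hull of the
CIELAB pixel cloud — the standard reading of "gamut volume" as a number — with
an occupied-unit-cube count as an alternative mode for sensitivity analysis.
Degenerate clouds (coplanar or fewer than four distinct colours) report
volume 0 with a flag. The hull is a quickhull implementation in the package;
tests pin it to polytopes of exactly known volume.

**Gamut ellipse.** The $(a^*, b^*)$ scatter is summarized by an ellipse
fitted with the ellipse-constrained direct least-squares conic method (the
numerically stable partitioned formulation), which cannot return a hyperbola,
unlike an unconstrained conic fit. Data are centred and isotropically scaled
before fitting for conditioning. Reported: centre, semi-axes, orientation of
the longer axis against $+a^*$ in $[0, 180)$, area $\pi a b$, and axis ratio.
At least 5 distinct points are required; noise-free sampled ellipses are
recovered to $10^{-6}$ and $\sigma = 0.5$ noise on 1000 points to within 2%.

## Relevant-colour extraction

The computational route reconstructs a palette from the image's CIELAB
histogram with a greedy, density-ranked, maximin scan:

1. histogram the pixels in unit cells and rank occupied cells by count
   (ties broken by lexicographic cell index, so the scan is reproducible);
2. walk down the ranking; accept a cell's mean colour when it
   passes the lightness window and the chroma floor, lies at least
   `delta_e_min` from every accepted colour, and represents at least
   `density_min` of the image's pixels;
3. stop when no candidate remains.

Defaults: `delta_e_min = 15`, `L_range = c(5, 95)`, `chroma_min = 5`,
`density_min = 0.001`. These reflect the constraints the approach is built
on — large colour differences between palette entries, restrictions on
lightness and chroma — with thresholds placed so that colourful
palette-structured images yield palettes in the observed ~15–25 colour
regime.

One design point deserves emphasis: a candidate's *density* is measured as
the pixel mass within `density_radius` (default 7.5 $\Delta E$) of its mean
colour, not as the count of its single unit cell. With per-pixel noise of
$\sigma = 3$ — the package's default synthetic regime — one paint spreads
over hundreds of unit cells and the densest single cell holds only ~$10^{-4}$
of the image, so a literal per-cell threshold would reject every real paint.
Measuring mass in the discernibility neighbourhood assigns the spread back to
the paint it came from, leaves noise-free behaviour unchanged, and keeps the
density threshold meaningful across noise levels.

The subjective route aggregates observer selections: each click is averaged
over the centred 5×5 pixel window (25 pixels) around it, and the window must
lie fully inside the image — border clicks are rejected rather than clipped,
because a selection is supposed to sample the interior of a chromatic area.
Each selection counts as one relevant colour by default, since observers may
legitimately pick similar colours at different locations; optional
single-linkage merging below a $\Delta E$ threshold is available when a
deduplicated palette is wanted.

Agreement between the two routes is measured three ways: the fraction of
subjective colours within a tolerance of some computational colour, the
symmetric counterpart, and the intersection-over-union of the two palettes'
convex-hull areas in $(a^*, b^*)$.

## Palette segmentation and fidelity

Segmentation is a nearest-colour look-up: every pixel is reassigned to the
palette colour minimizing Euclidean $\Delta E^*_{ab}$, with ties going to the
lowest palette index. Distances are computed in CIELAB because the whole
analysis lives there; an RGB-distance mode exists for sensitivity checks.
Fidelity is the Pearson correlation between each RGB plane of the original
and segmented images, and their mean is the headline number. A constant plane
has no defined correlation; it is flagged and excluded from the mean.
Segmentation of an image that uses only palette colours is the identity, and
segmentation is idempotent.

## Complexity metrics

A spatial pyramid of histograms of oriented gradients (HOG) underlies all
four metrics. Conventions, each config-exposed because the lineage fixes none
of them: 3×3 Sobel gradients per RGB channel scaled so a ramp of slope $s$
per pixel has gradient $s$, replicate padding at borders, per-pixel gradient
taken from the channel with the largest magnitude, orientations folded to
$[0, 180)$ into 16 bins weighted by magnitude, recursive 2×2 quartering down
to level 3 (64 sub-images), L1 normalization per histogram.

* **self-similarity**: median over the level-3 sub-images of the histogram
  intersection kernel $\sum_i \min(h_i, g_i)$ against the level-0 histogram;
  in $[0,1]$, and ~1 for self-tiled textures;
* **complexity**: mean gradient magnitude over pixels, on the 0–255
  intensity scale; zero iff the image is constant;
* **anisotropy**: variance of all pooled level-3 histogram values;
* **Birkhoff-like metric**: self-similarity divided by complexity (undefined
  and flagged when complexity is 0).

All four are invariant under 90° rotation (16 bins divide 90° evenly, so the
orientation permutation is exact). Tests compare the pyramid bin-for-bin
against a naive per-pixel reimplementation.

## ICA colour directions

Patches of 8×8×3 pixels are sampled at uniformly random interior positions,
flattened channel-major, centred, and whitened by eigendecomposition of the
sample covariance; directions with negligible eigenvalues are dropped, and an
optional `max_dim` performs standard PCA reduction before ICA (the source
lineage does not state its whitening dimensionality; the package exposes it).
The whitened covariance is the identity to $10^{-6}$ or better by
construction, and the dewhitening map is kept so mixing columns can be
expressed in pixel space.

The decomposition $I = A s$ is estimated by fixed-point ICA with symmetric
decorrelation and the cubic (kurtosis) nonlinearity, delegated to the `ica`
package with a seed-derived orthonormal initial rotation so runs are exactly
reproducible; `tanh` is available by configuration. Columns of $A$ (basis
functions) are ordered by decreasing L2 norm ("energy", stable on ties) and
normalized to unit norm. Non-convergence — e.g. on Gaussian data, where ICA
is not identifiable — is an error, not a silent result.

Each basis is interpreted as $p^2$ points in 3-D colour space; the first
principal component of that cloud is its dominant colour-variation axis. The
axis is projected onto $(RG, BY)$ and its angle folded to $[0, 180)$. Bases
whose projection is negligible relative to their total variation (threshold
`achromatic_tol = 0.05`, a ratio of norms) are flagged achromatic and
excluded from direction histograms, which report them separately. Default
number of components for a full-dimension fit is $3p^2 = 192$ at $p = 8$,
matching the customary basis count for 8×8 colour patches; the planted-angle
validation below uses 16 components over a 16-dimensional whitening, because
the planted sets concentrate their variance in a low-dimensional subspace and
smaller fits are faster and equally identifiable there.

## Synthetic generators: what they emulate, and what they do not

`generate_painting` emulates the one structural assumption every stage makes:
a painting is a small set of discrete paint colours arranged in regions, plus
smooth shading and pixel noise. Specifics: $K$ CIELAB colours
rejection-sampled inside the sRGB gamut at pairwise separation
$\ge$ `delta_e_sep`, with an `rgb_margin = 0.08` headroom from the channel
bounds so that per-pixel noise does not clip a large share of any colour's
pixels (clipped pixels pile up on the gamut boundary and would masquerade as
extra palette entries; the clipped fraction is always recorded); Voronoi
regions over random sites, irregular on purpose so nearest-colour
segmentation faces curved boundaries; every colour guaranteed at least 64
pixels and one fully interior 5×5 window (layouts are resampled until this
holds); Gaussian CIELAB noise; a low-frequency sinusoidal lightness field as
shading. Defaults — $K = 21$, separation 30, noise $\sigma = 3$, shading
amplitude 5 on a 128×128 canvas — put the default tests in the regime where
the subjective palette size of paintings is typically observed (~21 colours).

What passing tests on these images do *not* show: real paintings have
textured brushwork, correlated (non-Gaussian, non-isotropic) pigment noise,
gradients that are themselves meaningful, and palettes that are neither
equally separated nor equally salient. Recovery rates and correlation levels
on synthetic mosaics are therefore upper bounds on real-image behaviour, not
estimates of it.

`simulate_observer` clicks, for each generator colour, on a uniformly random
pixel whose whole 5×5 window lies inside one region of that colour, so the
averaged selection equals the region's colour exactly in the noise-free case.
A chroma-bias exponent lowers the click probability of low-chroma colours,
emulating the empirical scarcity of near-neutral selections. It does not
model spatial salience, scan paths, or inter-observer correlation.

`generate_opponent_patches` plants a single chromatic axis whose opponent
projection sits exactly at a requested angle (the opponent rows are
orthonormal, so the planted angle is exact), modulated by oriented gratings,
mixed with achromatic-gradient distractors and pixel noise. It validates the
whiten–ICA–projection chain: the recovered dominant direction must land
within one 10° histogram bin of the planted angle.

## Numerical choices and degenerate inputs

* Unit-cell binning uses `floor` (half-open cells); all ranking ties are
  broken lexicographically — reproducibility over arbitrariness.
* Quickhull uses a relative tolerance of $10^{-10}$ times the cloud's extent;
  collinear/coplanar clouds are flagged degenerate with volume 0.
* The ellipse fit centres and isotropically scales its input; a conic with no
  ellipse eigensolution is an error, not a silent fallback.
* Nearest-colour ties take the lowest palette index; equal-energy ICA bases
  keep their original order (stable sort).
* Achromatic pixels/axes are always flagged rather than dropped silently:
  hue 0 with a flag, `NA` directions counted in `n_achromatic`.
* Every random operation takes a mandatory seed; nothing depends on hidden
  RNG state, and run manifests record all seeds and parameters.

## Problem sizes

The default corpus and test sizes are chosen for fast, convergent desk-scale
runs: 128×128 canvases (16k pixels comfortably populate a 21-colour palette
and a ~12k-cell CIELAB histogram), 8 paintings per corpus, 5000 patches for
planted-ICA validation (≈26 observations per whitened dimension at
`max_dim = 16`), and 10–20 seeds per stochastic property. These sizes are the
package's own defaults; all are arguments.

## Known limitations

* The computational extraction is a principled reconstruction of a
  density/maximin palette algorithm, not a reimplementation of any specific
  published code; its thresholds are config-exposed for that reason.
* Colour difference is Euclidean $\Delta E^*_{ab}$ throughout; no CIEDE2000.
* The opponent plane is an RGB-linear construction, not a cone-excitation
  space; conclusions about physiological colour coding are out of scope.
* Segmentation is purely colourimetric — no spatial regularization.
* JPEG input needs the optional `jpeg` package; PNG/TIFF are native.
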