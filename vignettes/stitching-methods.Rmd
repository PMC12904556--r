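---
title: "Phase-correct spectral stitching of sequentially sweeping lasers: models and methods"
author: "octstitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-correct spectral stitching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octstitch)
```

## Scope

`octstitch` computationally combines the raw spectra of two or more
sequentially sweeping swept-source lasers in full-field Fourier-domain OCT
into a single high-bandwidth spectrum, and validates every stage against a
forward simulator with exact ground truth. This vignette records the
models, conventions, parameter choices and known limitations; the README
shows the user-facing workflow.

## Signal model and conventions

A camera frame at time $t$ during the sweep of laser $m$ records, after DC
removal,

$$ I_m(x, y, t) \;=\; S_m(k(t))\,\alpha_m(k(t)) \sum_\ell A_\ell(x,y)\,
   \cos\!\big[\,2\,k(t)\,z_\ell + \phi(k(t))\,\big], $$

where $k = 2\pi/\lambda$ is the wavenumber, $k(t)$ the laser's non-linear
sweep (its *chirp*), $S$ the source envelope, $\alpha \in (0,1]$ the
interference contrast, $z_\ell, A_\ell$ the depths and amplitudes of the
scattering layers, and $\phi$ a spectral phase collecting dispersion
mismatch and axial bulk motion.

Units and axis conventions, used everywhere:

* wavelengths in nm; wavenumbers in rad/µm; depths are optical path in
  air, µm;
* the factor 2 in $\cos(2kz)$ is absorbed once into the depth axis:
  spectra sampled at pixel size $\delta k$ over $N$ pixels reconstruct
  onto depth pixels of $\pi/(N\,\delta k)$ and the Nyquist depth is
  $\pi/(2\,\delta k)$ (about 1.15 mm for the default system);
* all spectra are stored with ascending $k$; sweeps recorded with
  decreasing $k$ are conjugated during k-linearization so every laser
  lands on the $e^{+i2kz}$ convention. (The direction of the physical
  sweep is metadata; only a single global axis convention matters.)

The default system mirrors a dual-laser instrument: laser "840" sweeping
805–882 nm over 515 frames and laser "950" sweeping 879–950 nm over 478
frames, in the same direction, with roughly a nanometre of shared
wavelength.

## What the simulator emulates — and what it does not

The generator (`simulateSweep` and the session builders) produces real
frame stacks containing: a parametric monotone chirp (linear, polynomial,
or sinusoidally perturbed, anchored exactly to the nominal sweep
endpoints); rectangular or rounded source envelopes; an amplified
spontaneous emission (ASE) model in which an edge ramp adds an incoherent
background $b(k)$ to the DC level and multiplies the fringe amplitude by a
contrast $\alpha(k) = 1 - (1-\alpha_{\min})\,\mathrm{ramp}(k)$, making
$\alpha$ the literal ground truth of the contrast estimator; discrete
scattering layers with optionally per-pixel random depths (a speckle-like
distributed scatterer); polynomial dispersion phase; per-volume bulk axial
motion ($2k\,\Delta z$) and a constant inter-sweep phase offset applied to
every laser after the first; and additive white Gaussian detector noise.

Two modelling decisions deserve emphasis:

* **Trim margins sit outside the nominal range.** A few frames near the
  sweep start/stop are unreliable in practice (trigger jitter of a
  fraction of a frame) and are discarded. The session simulators interpret
  the nominal wavelength range as the *usable* sweep: the default 8 + 8
  discarded frames are generated *beyond* the nominal endpoints, so after
  trimming the retained sweep spans the nominal wavelengths exactly. This
  keeps the anchored chirp labels physical for every laser and makes the
  recorded ground-truth overlap consistent with what a perfect estimator
  would measure. (Chirp anchoring is affine: the unwrapped mirror phase
  determines $k(t)$ only up to an affine map, which is fixed to the
  nominal endpoints of the retained sweep.)
* **Background reference.** Real pipelines estimate the additive
  background with a dedicated method; the simulator records a sample-free
  sweep per laser (the ASE background plus DC) and
  `subtractBackground(x, reference=)` uses it. Without a reference, the
  per-pixel temporal mean is removed, which leaves the $k$-dependent part
  of $b(k)$ — accurate enough for flat-envelope work but not near
  ASE-shaded sweep ends, which is precisely where the overlap lives.

Not modelled: coherent speckle statistics of dense volumetric scattering,
camera MTF, spatial-coherence effects of the illumination fiber,
polarization, wavelength-dependent water absorption, and lateral sample
motion. Passing tests therefore demonstrate correctness of the
*computational chain* under known ground truth, not robustness to every
artefact of in-vivo data.

## Calibration

**Trimming.** Default 8 frames head and tail ("a few" is all practice
dictates; the margin covers trigger uncertainty). An auto-trim mode
discards leading/trailing frames whose smoothed fringe contrast falls
below a threshold (default 0.8 of the interior level).

**Chirp.** All A-lines of a trimmed, background-subtracted single-mirror
volume are averaged; the analytic signal (one-sided FFT construction)
yields the unwrapped phase $\psi(t) = 2k(t)z_0 + \text{const}$, rescaled
affinely to the nominal endpoints. The phase is fitted with a degree-9
polynomial over the interior only (the analytic signal of a finite fringe
rings over the first/last dozen frames) and the fit is extrapolated to the
edges. `calibrateSession` estimates the chirp at every calibration depth
and averages the curves with weights $z_n^2$, since the additive phase
error maps to $k$ as $\varepsilon/(2z_0)$. Recovery error is below
$10^{-3}$ of the sweep span for smooth chirps with up to ~10%
non-linearity, and the estimate is invariant to the mirror depth.

**k-linearization.** The common pixel size is
$\delta k = \text{span of the first laser}/(N_1 - 1)$ after trimming; all
other lasers are resampled to it, each grid anchored at its nominal lower
wavenumber. Resampling evaluates the analytic signal at the frame
positions where the chirp crosses each uniform grid point, after 16×
band-limited (FFT zero-padding) upsampling followed by cubic-spline
evaluation — interpolation error for tone-like fringes is negligible
(instantaneous-frequency flatness of a regridded mirror fringe is < 1%,
and a fixed depth produces the same fringe frequency in both lasers to
< 0.5%). Requested grids implying more than 4× upsampling of the native
sampling are rejected.

**Contrast.** $\Gamma_m(k)$ is the lateral sum of analytic-signal
magnitudes (scattering mode; a raw-|I| variant is available behind a
flag), or the magnitude of a depth-windowed single-surface reflection
(reflecting mode, with a Tukey-tapered pass band and a guard that rejects
two unresolved surfaces in one window). $\alpha_m = \Gamma_m/\Gamma_{m,\max}$,
floored at $\varepsilon = 0.05$ so the subsequent division is always safe.
In `calibrateSession` the contrast is estimated and applied on the
k-linearized spectra, where a mirror is a sharp depth peak; on raw chirped
frames the mirror peak smears and the isolation window becomes ill-posed.

**Overlap.** K-linearized mirror spectra of the two lasers are zero-padded
side by side to length $N_m + N_{m+1}$, cross-correlated via the
convolution theorem with the transform-domain product zero-padded 99× its
length (0.01-px correlation grid), normalized by the regularized magnitude
$\max(|R|, 10^{-3}\max|R|)$, and the real parts summed over depths:
$\rho_0(l) = \sum_n \cos(2(l-\kappa)\,\delta k\,z_n)$ peaks only at the
true overlap when the $z_n$ are not integer multiples of one another
(near-harmonic sets draw a warning; the default depth generator nudges
them apart). The argmax is restricted to $[0.25, 4]\times\kappa_{\rm nom}$
(from the nominal ranges) to exclude periodic aliases, ties break toward
$\kappa_{\rm nom}$, and a boundary argmax is flagged unreliable. Recovery
is exact to < 0.02 px noiseless and < 0.1 px at 5% noise; fractional
overlaps are never rounded during estimation.

The overlap convention: $\kappa$ = number of shared uniform-grid pixels,
so the stitched length is $N_m + N_{m+1} - \kappa$ (with the blend
spanning $\lceil\kappa\rceil$ integer pixels and the fractional part
applied by the Fourier shift theorem; the combined grid stays inside the
measured span).

## Reconstruction

Per volume and laser: trim → background subtraction → k-linearization with
the stored chirp → contrast division. The residual spectral phase
$\phi(k)$ is handled in three layers, mirroring its Taylor expansion around
the center wavenumber:

* **orders ≥ 2** (in-volume motion + dispersion mismatch):
  `correctMotionPhase` fits a polynomial in the normalized offset
  $u = (k-k_0)/k_{\rm half}$ by minimizing the energy-normalized sharpness
  $S = \sum|U|^{\gamma}/E^{\gamma/2}$, $\gamma = 1.4$, with a coarse scan
  over the quadratic term seeding a Nelder–Mead simplex (golden-section in
  1-D). This polynomial-phase optimizer is the package's own design for
  removing the $O(\Delta k^2)$ terms; no claim is made that it reproduces
  any particular published motion-correction algorithm internally.
* **order 1** (bulk displacement between volumes): `registerVolumes`
  estimates each volume's axial shift against the first volume of the
  first laser — same-grid pairs by the exact cross-spectrum phase slope
  (coarse transform peak, then a magnitude-weighted least-squares fit of
  the derotated interior phase; spectrum edges are excluded because
  regridding leaves ringing there), cross-laser pairs by subpixel
  correlation of mean-centered magnitude A-scans, which is insensitive to
  disjoint $k$ supports. Decorrelated volumes (centered normalized peak
  < 0.2) are excluded with a warning. Registration is transitive to
  < 0.02 µm.
* **order 0** (inter-sweep phase jump): `searchPhaseOffsets` grid-searches
  $\phi \in [0, 2\pi)$ (64 values, then a continuous refinement of the
  metric around the best grid point) per lateral bin of default 25 × 25
  pixels (edge bins truncated), minimizing $S$ of the zero-padded local
  stitched reconstruction. The stitch is linear in $e^{i\phi}$, so the two
  fixed transforms $U_A$, $U_B$ are precomputed once per bin and each
  trial phase costs one vector combination. Bins without signal energy are
  filled from their neighbors and flagged. Per-bin energy normalization
  makes the metric a concentration measure independent of local
  brightness.

**Numerical choice — metric padding.** The sharpness metric samples
$|U|^{1.4}$ on a discrete depth grid; at 4× zero-padding this quadrature
is coarse enough to bias the metric's minimum by up to ~0.15 rad for
sparse specular content (one or two discrete layers in a bin), while at 8×
the bias drops below 0.01 rad. The package therefore defaults to
`pad_factor = 8` for the phase search; 4× remains available and is
adequate for distributed, tissue-like bins. With the default, recovered
offsets stay within $\pi/32$ of truth across random two-layer scenes
(95th percentile within $\pi/16$ at 5% noise), including the hardest case
of an offset near $\pi$, where the stitched main lobe splits in two.

Stitching composes the three-piece spectrum (lower laser alone, linear
blend $[1-w]a + w\,e^{i\phi}b$ with $w(k) = (k-(N_m-\kappa))/\kappa$
evaluated at pixel centers, upper laser alone), optionally applies a Tukey
window (ratio 0.5 by default when enabled), and inverse transforms with
orthonormal scaling (unapodized energy is conserved exactly). Multi-laser
chains stitch pairwise along ascending $k$.

## Diagnostics

`theoreticalResolution` returns $1.21\pi/\Delta k_0$. `psfReport` measures
the −6 dB (intensity) full width at half maximum of the magnitude by
linear interpolation of the half-maximum crossings on a ≥16×-padded
response (dB convention: $10\log_{10}$ of intensity, equivalently
$20\log_{10}$ of magnitude — the −6 dB width is the magnitude half-maximum
width), and reports the highest local maximum on each side of the main
lobe, excluding the lobe down to its first nulls, within ±15 FWHM. The
depth axis is treated as circular; windows whose maximum is below 5% of
the global peak are rejected as peak-free. `errorSensitivitySweep`
re-stitches an idealized dual-laser scenario with a controlled phase,
overlap or amplitude error and tabulates the degradation: a $\pi/4$ phase
error raises the one-sided sidelobe by ≈3 dB and the degradation grows
monotonically to a split main lobe at $\pi$; a 0.5 px overlap error is
invisible at shallow depths but costs ≈5 dB at 850 µm (the phase mismatch
it induces is $2z\,\Delta\kappa\,\delta k$, linear in depth); an
uncorrected amplitude step at the seam raises out-of-lobe energy relative
to the blended stitch while trading first-lobe level for main-lobe width.

## Problem sizes and defaults used in the shipped checks

The test-suite and the acceptance script run the generator at its default
study conditions: the dual-laser system above; polynomial chirps with 4–5%
quadratic (plus a small cubic on the second laser) — a realistic few-percent
non-linearity for this class of source; ASE edge fraction 0.08 with
contrast floor 0.75 and background level 0.5 where ASE is exercised; six
log-spaced calibration depths over 10–80% of the Nyquist depth with seeded
jitter; 2 × 2 lateral pixels for calibration sessions (all A-lines are
averaged anyway) and up to 40 × 40 for distributed-phantom contrast
checks; detector noise 0 (noiseless ground-truth closure) or 5% where a
noise tolerance is asserted. Simulations complete in seconds; nothing in
the defaults depends on the execution host.

## Known limitations

* Absolute wavenumber calibration is affine-anchored to the nominal sweep
  endpoints; a systematic error in the quoted endpoints rescales the depth
  axis (real deployments would calibrate depth against a known-thickness
  target).
* The contrast estimators degrade at the extreme 1–2% of the spectrum
  edges (finite-support ringing); quantitative statements exclude those
  pixels, and trimming exists precisely to discard unreliable edges.
* The sharpness-based phase search can in principle hit near-degenerate
  $\pm\phi$ minima for bins dominated by a single specular layer; the
  per-bin independence means neighbors disagree loudly in that case, and
  an optional median filter across bins is available for noisy data.
* Registration assumes a common dominant structure across volumes;
  decorrelated volumes are dropped rather than force-registered.
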