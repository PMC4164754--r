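---
title: "Regularization-free Young's modulus reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularization-free Young's modulus reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Quasi-static ultrasound elastography infers tissue stiffness from the
deformation induced by gentle external compression. Conventional strain
images conflate stiffness with the local stress, which is unknown and
non-uniform; the resulting artifacts (notably target hardening — apparent
stiffening with depth as stress decays) can mislead interpretation.
`elastofem` reconstructs a *relative Young's modulus* map — the intrinsic
mechanical contrast — from a pair of radiofrequency (RF) ultrasound frames
without any regularization parameter and without measuring force or
displacement boundary conditions, which is what makes the method usable
with a freehand scan.

The pipeline has four stages:

1. **Speckle tracking** (`track()`): displacements between the pre- and
   post-compression RF frames, accurate axially (RF phase), noisy
   laterally.
2. **Bicubic B-spline motion model** (`fit_axial()`, `derive_lateral()`):
   the axial control parameters are least-squares fitted to the tracked
   axial field; the lateral parameters are *derived* from plane-strain
   incompressibility rather than from the noisy lateral estimates.
3. **FEM direct inversion** (`reconstruct_modulus()`): a one-element-thick
   ring around the region of interest (ROI) is assigned unit Young's
   modulus (the *modulus boundary condition*); the nodal forces the ring
   exerts on the ROI anchor an overdetermined linear system whose unknowns
   are the per-element relative moduli.
4. **Evaluation** (`mean_relative_error()`, `rmse_relative()`,
   `roi_statistics()`, `run_study()`).

A full synthetic validation stack (plane-strain FEM forward solver,
circular-inclusion phantoms, convolution-PSF RF synthesis) generates the
study data.

# Displacement model

The displacement fields are tensor-product uniform cubic B-splines
(free-form deformation). With knot spacings $h_x, h_y$ and control grids
$a_{j,i}$ (axial) and $b_{j,i}$ (lateral),

$$V(x,y) = \sum_{m=0}^{3}\sum_{n=0}^{3} B_m(p)\,B_n(q)\,a_{j+n,\,i+m},
\qquad U(x,y) \text{ likewise with } b,$$

where $i = \lfloor x/h_x \rfloor$, $p = x/h_x - i$ (and similarly $j, q$),
and $B_0\ldots B_3$ are the uniform cubic basis polynomials. Strains are
the analytic derivatives of the spline, never finite differences.

The axial parameters minimize
$\sum_{\text{valid}} (V(x,y) - V_0(x,y))^2$ over the tracked grid, masked
points excluded. Lateral tracking has no phase to work with and is an
order of magnitude noisier, so the lateral parameters are instead the
least-squares solution of the plane-strain incompressibility constraint
$\varepsilon_{xx} + \varepsilon_{yy} = 0$, i.e. they minimize
$\sum (\partial U/\partial x + \partial V/\partial y)^2$ on a grid at
quarter-knot resolution.

**Gauge.** Incompressibility determines only $\partial U/\partial x$, so
$U$ is undefined up to an additive function of depth. The gauge is fixed
by appending rows that pin the mean of $U$ along each grid row to zero
(`gauge_weight`, default 1). Because the pure gauge directions do not
enter the strain rows at all, any positive weight selects the same
minimum-residual solution. A caveat worth stating plainly: a
depth-dependent lateral offset is a *simple shear*, which the elastic
operator genuinely senses, so the reconstruction is only invariant to
gauge differences at the scale at which the gauge is actually ambiguous
once a convention is fixed (of order a micron here; measured sensitivity
is roughly 15% of the image per 0.01 mm of smooth offset). The test
suite verifies sub-1% stability at the micron scale. Different gauge
*conventions* applied consistently, e.g. zero row means versus a pinned
edge column, differ by exactly such a micron-scale field on this data.

**Defaults.** Knot spacings 4.75 mm (lateral) × 4.82 mm (axial); tracking
window 2.2 × 1.8 mm²; estimation-grid stride 25% of the window per axis.

# Speckle tracking

The tracker is normalized cross-correlation (NCC) block matching with two
steps, computed for all windows simultaneously via integral images:

1. integer-offset search on the *envelope* (analytic-signal magnitude),
   which is free of RF phase ambiguity and yields a robust integer
   displacement;
2. RF-domain NCC constrained to ±2 samples / ±1 line of the envelope
   peak, followed by subsample refinement — a cosine fit at the measured
   carrier frequency axially (the RF correlation oscillates at the
   carrier, so a parabola has a sawtooth bias of a few tenths of a
   sample), replaced wherever applicable by the phase of the complex
   cross-correlation $\hat\delta = -\arg(C)/(2\pi \hat f_0)$, and a
   parabola laterally.

Estimates with peak correlation below 0.3 or further than 0.1 mm from
their 3 × 3 neighborhood median (half-wavelength peak hops) are masked
out; masked points are excluded from the spline fit. On the study
conditions at 2% strain the tracked error standard deviations are
≈ 1.8 µm axially and ≈ 11 µm laterally — the order-of-magnitude asymmetry
that motivates the derived lateral field.

# FEM core and forward simulation

Bilinear quadrilateral elements in plane strain with selective reduced
integration: the deviatoric (shear) part uses the 2 × 2 Gauss rule, the
volumetric ($\lambda$) part the 1-point rule. At the near-incompressible
Poisson ratio 0.495 used for soft tissue ($\lambda/\mu = 99$), the fully
integrated quad locks volumetrically; selective reduced integration is
the standard remedy and is applied consistently in the forward solver and
the inversion operators. Element stiffness is linear in the Young's
modulus, $K_e(E) = E\,K_e(1)$, the property the inversion exploits.

The synthetic phantom is a 38 × 38 mm block with two 6.5 mm circular
inclusions (75 kPa in a 25 kPa background, contrast 3) placed side by
side at mid-depth, centers (13, 19) and (25, 19) mm — a symmetric layout
chosen once as representative of two-target phantoms. Compression is
applied between perfect-slip surfaces: prescribed axial displacement on
top, axially fixed bottom, free lateral motion, one lateral dof pinned at
the bottom center to remove the rigid mode. The forward mesh is uniform
at `height/320` ≈ 0.119 mm, four times finer than the inversion elements;
refining it further moves the headline metrics by under 0.2 percentage
points (convergence is re-checked in the test suite). Because the
prescribed-displacement problem is linear, one factorization serves all
applied strains by scaling.

# RF synthesis

Point scatterers (200 /mm², uniformly placed, standard-normal amplitudes
— beyond the fully-developed-speckle threshold) are advected by the
bilinear interpolant of the FEM solution and imaged with a separable
point-spread function: axially a Gaussian-envelope cosine at 6 MHz with
50% −3 dB fractional bandwidth; laterally a Gaussian whose FWHM is
$\lambda \cdot F\# = 0.128$ mm at the 19 mm focus (depth-independent).
Scatterers are deposited on a 4× oversampled grid with bilinear weights,
which preserves subsample echo phase, then the frame is decimated to the
32 MHz / 0.12 mm-pitch imaging grid (320 lines, 38 mm depth). White
Gaussian noise sets the SNR (30 dB in the study).

What this stand-in reproduces: speckle statistics (Rayleigh-like
envelope), strain- and lateral-motion-induced decorrelation, subsample
phase fidelity — the properties the tracker must survive. What it does
not: diffraction (depth-dependent beam width away from focus),
apodization, elevation focusing, attenuation, and reverberation. Passing
tests therefore demonstrate robustness to idealized speckle
decorrelation and additive noise, not to the full physics of a clinical
scanner.

# Inversion

Let the ROI be a rectangle meshed with 0.48 × 0.48 mm quadrilaterals, and
surround it by a one-element ring assigned relative modulus 1. With the
displacement field evaluated analytically from the spline model at every
mesh node, the ring's nodal forces are $f = K_{\text{ring}} d$; Newton's
third law gives the loads on the ROI interface as $-f$, and strictly
interior ROI nodes carry zero (no body forces). Since
$K_e(E) = E K_e(1)$, nodal forces are linear in the element moduli:
$D E = K(E) d$ with $D$ a $2N_{\text{node}} \times N_{\text{element}}$
matrix whose column $e$ scatters $K_e(1) d_e$. The moduli solve the
overdetermined system by least squares, with no regularization of any
kind; negative solutions are reported as-is with a warning (only rendered
images are clipped).

## Why the operator needs an explicit pressure

The package implements two element formulations for the inversion.

The **penalty** formulation uses the full near-incompressible plane-strain
stiffness in the columns of $D$. It is exact — recovery to machine
precision — when the displacement input is an equilibrium solution of the
same mesh, and that exactness is the defining correctness oracle of the
method. But its volumetric term weights equations by
$\lambda \approx 99\mu$, while the physical volumetric strain at
$\nu = 0.495$ is only ~3% of the strain scale. Any input that is not
mesh-consistent — displacements interpolated from a finer mesh, or a
spline field whose derived lateral component is divergence-free *by
construction* — feeds the $\lambda$ rows inconsistencies comparable to or
larger than the signal, and the least squares collapses (measured mean
errors of −40% to −85% on the study phantom; a white displacement noise
of only $10^{-4}$ mm suffices, which is the hypersensitivity this class
of direct inversions is known for).

The **mixed** formulation (the default) is the incompressible-limit
statement of the same equations: stress is split as
$\sigma = 2\mu\,\varepsilon_{\text{dev}} - p I$ with
$\mu = E/(2(1+\nu))$, the deviatoric part populates the modulus columns,
and the hydrostatic pressure $p$ — which the displacement data cannot
carry — joins the unknown vector as a bilinear nodal field over the
ROI+ring mesh (interior nodes). The ring anchor is assembled in the same
deviatoric-plus-pressure form. The system remains linear, overdetermined
and regularization-free; the extra unknowns are a physical field, not a
penalty. On the study phantom this formulation reconstructs the
theoretical-displacement pathway to a mean relative error of about −1.5%
(RMSE ≈ 7%) and the full estimated pathway to RMSE ≈ 17–19% at 2% strain
with the smooth reduced-contrast inclusions (≈ 2.3 of a true 3.0)
characteristic of knot-scale smoothing.

Nodal (0.48 mm) pressure resolution is required: the true pressure jumps
across inclusion boundaries, and coarser pressure grids leave
unrepresentable residue that biases the whole image.

## Numerical choices

* Sparse least squares via SuiteSparse QR (`Matrix::qr`); the spline
  normal equations use sparse Cholesky (their conditioning is benign).
* Dof ordering is interleaved $(x_1, y_1, x_2, y_2, \ldots)$, node-major,
  shared bit-for-bit between the ring-force, $D$-matrix and forward
  assembly.
* Scale invariance: scaling all displacements by $c$ rescales $f$ and $D$
  equally, so the reconstruction is independent of the applied strain —
  the mechanism behind the observed stability of modulus images across
  compression levels, asserted exactly in the tests.
* Rank-deficient systems (too-small ROI, degenerate field) raise explicit
  errors; they are never silently regularized.

# The simulation study

`run_study()` reproduces the two-pathway experiment: the *theoretical*
pathway feeds interpolated forward-FEM displacements straight into the
inversion (deterministic, strain-invariant); the *estimated* pathway runs
RF synthesis → tracking → spline fit → inversion at applied strains 0.5,
1.0, 1.5 and 2.0%, reporting the mean relative error and RMSE of the
relative modulus (truth normalized to background 1, reconstruction
anchored by the unit ring) per strain and summarized across strains. The
ROI is a 28.8 × 28.8 mm square (60 × 60 elements) centered in the
phantom, chosen to cover both inclusions with margin while the ring stays
well inside the tracked support.

A known limitation of the estimated pathway: the block-matching tracker's
speckle-decorrelation noise floor does not shrink with the applied
strain, so at 0.5% strain the relative displacement error is several
times larger than at 2%, and its propagation through the
incompressibility derivation (where axial-fit noise integrates along $x$
into the lateral field) biases the low-strain reconstructions upward by
roughly +13%. Across-strain summaries therefore carry a positive bias and
a larger spread than the 2%-strain reconstruction alone. A
gradient-based optical-flow tracker, which this package deliberately does
not attempt to reproduce, would be expected to narrow that gap; the
tracker sits behind the single `track()` interface so it can be swapped.

`run_hardening_study()` emulates the freehand phantom experiment that
motivates modulus imaging: a transducer-wide compressor on a phantom
wider (60.8 mm) than the imaged region, so stress spreads into the
un-imaged wings and axial strain varies with depth. A full-width slip
compression of a laterally bounded 2D block *cannot* show target
hardening — by equilibrium, the mean axial stress over any full-width
band is constant in depth — so the wide-phantom geometry is the honest
2D analogue of the experiment. Under it the strain image varies by
≈ 26% between top and bottom background bands while the modulus image
varies by ≈ 6%, a four-fold suppression.

# Problem sizes and runtime

Defaults are desk-scale: forward mesh 320 × 320 elements (≈ 207k dof, one
sparse Cholesky), inversion 60 × 60 elements plus ring (≈ 7.4k equations,
7.3k unknowns, one sparse QR), RF frames 1580 × 320 samples synthesized
on a 4× oversampled grid, tracking ≈ 5.2k windows × ≈ 350 offsets via
integral images. A single estimated-pathway strain takes on the order of
a minute on one core; the theoretical pathway a few seconds beyond the
forward factorization.

# Limitations

* Relative (contrast) moduli only; absolute calibration would require
  boundary stress, unavailable in vivo.
* Knot-scale smoothing caps the recovered inclusion contrast (≈ 2.3 of
  3.0 here) and blurs interfaces, the analogue of regularization bias in
  iterative schemes, though no regularization parameter exists.
* 2D plane strain; out-of-plane motion is not modelled.
* The tracker and RF synthesizer are documented stand-ins chosen to
  preserve the statistical character of the problem, not to replicate
  any specific scanner or optical-flow implementation.
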