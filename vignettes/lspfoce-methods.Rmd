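---
title: "Models and methods behind pfoce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pfoce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfoce)
```

# The measurement principle

Light-sheet photonic-force OCE maps micro-scale viscoelasticity of soft
hydrogels (shear moduli of roughly 10–1000 Pa — fibrin, collagen,
polyacrylamide, pericellular matrix) by combining two optical systems:

* a **pump**: a weakly focused, power-modulated light sheet whose
  radiation pressure pushes micron-sized probe beads embedded in the
  medium with piconewton-scale harmonic forces, in parallel across the
  sheet's long axis;
* a **probe**: phase-sensitive OCT in a BM-mode acquisition (many frames
  at one slow-axis position), which resolves the resulting sub-nanometre
  bead oscillations interferometrically.

Each bead's complex response (amplitude and phase relative to the drive
waveform), together with the local radiation force, yields the complex
shear modulus of its immediate microenvironment.

This vignette records the models the package implements, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic-data tests do and do not establish.

# Forward optics: light sheet and radiation force

The sheet is modelled as an astigmatic Gaussian beam: intensity FWHM
80 µm (long axis) × 1.4 µm (short axis) at the focus, 120 mW total power,
789 nm, each transverse axis diverging with its own Rayleigh range. The
transverse plane integral equals the beam power at every depth, which
fixes the normalisation absolutely.

The radiation force on a bead (diameter 1.7–1.9 µm, comparable to the
wavelength — the Mie regime) is computed with generalized Lorenz–Mie
theory. Mie partial-wave coefficients $a_n, b_n$ come from the standard
Bohren–Huffman recurrences. The shaped beam enters through beam-shape
coefficients $g_n$ in the **localized approximation**: $g_n$ is the
azimuthal average of the normalised field amplitude on the ring
$\rho_n = (n + \tfrac12)/k$ around the bead axis. The axial
radiation-pressure cross-section is

$$C_{pr,z} = \frac{2\pi}{k^2}\Big[\sum_n \tfrac{n(n+2)}{n+1}
  g_n g_{n+1}\,\mathrm{Re}\big(a_n + a_{n+1}^* - 2 a_n a_{n+1}^*
  + b_n + b_{n+1}^* - 2 b_n b_{n+1}^*\big)
  + \sum_n \tfrac{2n+1}{n(n+1)} g_n^2\,
  \mathrm{Re}\big(a_n + b_n - 2 a_n b_n^*\big)\Big],$$

with $F_z = n_{med} I_{peak} C_{pr,z}/c$. Two limits pin this down: for
$g_n \to 1$ it reduces algebraically to the plane-wave
$Q_{pr} = Q_{ext} - g\,Q_{sca}$ (verified in the tests against an
independent spherical-Bessel implementation), and in the Rayleigh limit
it reproduces the dipole scattering force. Rigorous angular-spectrum
beam-shape coefficients for an astigmatic beam are not implemented; the
localized approximation is expected to carry a band of order ±20% on the
absolute force, and the package's ~3 pN operating point is read with that
band in mind. No aberration model is included: deviations between
simulated and measured profiles in a real instrument are attributed to
system non-idealities that the package does not attempt to model.

Transverse force components are reported only at dipole
(gradient-force) order; they are negligible along the slowly varying
80-µm axis, which is the only transverse direction the analyses use.

# Viscoelastic response and inversion

A sphere of radius $a$ and mass $m$ oscillating at $\omega = 2\pi f$
(20 Hz default) in a medium of density $\rho$ senses

$$\tilde G_{e\!f\!f} = G^*\big[1 - i k^* a - \tfrac19 (k^* a)^2\big],
\qquad k^* = \omega\sqrt{\rho/G^*},$$

with the principal square root ($\mathrm{Re}\,k^* \ge 0$) and an
$e^{+i\omega t}$ time convention — the branch and convention are chosen
so that the purely viscous limit $G^* = i\omega\eta$ reproduces Stokes
drag, and they are recorded here because the closed form leaves them
open. The density is configurable and defaults to 1000 kg/m³ (aqueous
hydrogels). Inversion uses the fixed-point map
$G_{n+1} = \tilde G_{e\!f\!f} / (1 - i k_n a - k_n^2 a^2/9)$: at 20 Hz
and micron radii $|k^* a| \sim 10^{-3}$, so the map is a strong
contraction and converges to machine precision in a handful of
iterations. A damped complex-Newton inversion exists in the test suite
as an independent oracle but is deliberately not the production path.

The inertial term $m\omega^2$ is kept by default although it is ~9
orders of magnitude below the drag term at 20 Hz; disabling it
(`include_inertia = FALSE`) changes nothing at the reported precision.

# Force measurement from bead trajectories

Calibration drops beads into a viscous fluid (10% w/w glycerol–water:
refractive index 1.3469, and as working defaults η = 1.31 mPa·s,
ρ = 1021 kg/m³ at room temperature — configurable, since the authoritative
property table lives outside the package). A space–time (depth × time)
intensity image of each bead is scanned with sliding windows (default
32 time samples × 24 depth pixels, 50% overlap); in each window the
Radon-transform projection angle of maximum variance gives the local
streak slope, i.e. the axial velocity, with parabolic interpolation of
the variance peak refining the estimate below the angular quantum
(default grid 0.25°). Velocities are smoothed with a Savitzky–Golay
filter (order 2, window 11) whose analytic derivative supplies the
acceleration. The 1D equation of motion
$F(z) = m\dot v + 6\pi\eta a v - g\,\tfrac43\pi a^3(\rho_b-\rho_f)$
then yields the force, resampled onto a regular depth grid with
Radon-peak-contrast weights. Per-window quality gates (peak contrast
below 0.2 → quality 0) exclude featureless windows. Repeating the
measurement at lateral segments along the sheet's long axis assembles
the 2D profile $F_{rad}(x, z)$.

# Reconstruction of BM-mode stacks (steps 2–6)

1. **Demodulation.** Per voxel, the temporal phase is unwrapped through
   frame-to-frame complex increments, converted to displacement via
   $d = \varphi\,\lambda_0/(4\pi n_{med})$, and fit by least squares to
   $A\cos(2\pi f_{mod} t) + B\sin(2\pi f_{mod} t) + C$ at the *exact*
   modulation frequency — 20 Hz is not commensurate with 6400 frames at
   425 Hz, so a DFT bin would leak. The fit residual propagates to an
   amplitude standard error per voxel.
2. **Registration.** The per-frame common-mode phase (argument of the
   complex mean over user-supplied static reference voxels, relative to
   the first frame) is subtracted; common-mode removal is exact by
   construction.
3. **Segmentation.** Bead voxels: connected blobs with magnitude SNR at
   or above 28 dB (the stated operating point; the original magnitude
   thresholds are instrument-specific, so the defaults here are
   assumptions exposed in the configuration). Medium-scatter (PT)
   voxels: SNR in (6, 26) dB outside dilated bead regions. Exclusions,
   each with a reason code: blob within 3 voxels of the image edge;
   blob centroids closer than 2 bead diameters; amplitude standard
   error above half the amplitude.
4. **Photothermal reconstruction.** Sheet absorption heats the medium
   and adds a spurious optical-path modulation that accumulates with
   depth. The PT phasor field is fit as a separable rank-1 complex
   surface $u(z)\,l(x)$ by alternating least squares over the PT voxels
   only; $|u(z)|$ is projected onto the monotone non-decreasing cone
   (cumulative heating) after a 5-row running mean — the physical depth
   profile is smooth, and the smoothing matters because depth rows
   containing beads retain few PT voxels. When a coverslip measurement
   is provided the model is rescaled to match it.
5. **Isolation and clustering.** The mechanical phasor is the complex
   difference total − PT. Bead voxels are clustered by 3D connected
   components across (depth, fast axis, slow axis); each bead reports a
   magnitude-weighted centroid, the median voxel amplitude after a
   Rician debias $\sqrt{\max(A^2 - 2\,se^2, 0)}$ (the magnitude of a
   noisy phasor is biased upward by $\sigma^2/A$, a few percent at the
   stiff end of the measurable range), and the circular median of
   voxel phases (minimiser of summed angular distance, ties broken
   toward the circular mean — whether the original per-bead median was
   circular is unstated, and the circular choice is the one that is
   well-defined at the wrap point).
6. **Modulus mapping.** The force at each centroid is bilinearly
   interpolated from $F_{rad}(x,z)$; beads outside the map support are
   flagged and left without moduli.

# Downstream analyses

* **Cell segmentation** by temporal speckle contrast: per-voxel
  sd/mean of OCT magnitude over frames, threshold (default 0.25 —
  there is no universal threshold; a static calibration region
  can be used to set it), morphological closing, largest connected
  component.
* **Distance profiles**: per-bead Euclidean distance to the nearest
  cell-surface voxel (anisotropic voxel sizes respected); 3-µm bins;
  per-bin means with Student-t 95% CIs; optional normalisation by the
  background (≥ 30 µm).
* **Power-law fit** of the pericellular stiffness gradient: degree-1
  least squares of log G′ against log r over r ≤ 30 µm. The log–log
  space is the only reading of a "polynomial fit" that yields a
  dimensionless decay exponent, which is why it is adopted.
* **Displacement statistics**: cumulative bead displacements with the
  mean per-step displacement over all beads (the bulk sample shift)
  removed before accumulation, which cancels rigid translations
  exactly; the signed displacement takes the sign of the dataset-level
  major axis — the component of $(|\Delta x|,|\Delta y|,|\Delta z|)/
  \lVert\Delta r\rVert$ with the largest average over beads and time
  points, zero-norm entries skipped. Beads missing at a time point drop
  out of the bulk estimate for the affected step only. Deformation
  groups (high-negative / low / high-positive) default to a threshold
  at the 67th percentile of |S|, a tercile-like split, because the
  original thresholds are not stated.
* **Shell metrics**: Q95 and mean OCT intensity and fibre volume
  fraction in a 3-µm shell around each bead after bead removal
  (magnitude segmentation + dilation). The conventional threshold condition
  "6 dB ≥ SNR ≥ 14 dB" is internally inconsistent; it is implemented
  as noise floor 6 dB, fibre threshold 14 dB, fraction =
  (≥ 14 dB)/(≥ 6 dB) within the shell, with both the thresholds and the
  denominator convention exposed as parameters. SNR is on the magnitude
  convention, $20\log_{10}$.
* **Distribution width** σ_FWHM: FWHM at half the mode of a Gaussian
  KDE with Silverman bandwidth (the fit family behind the original
  distribution fits is not named; a KDE makes no shape assumption).
* **Hypothesis tests**: two-sided Welch t, Levene (classical,
  mean-centred, via `car::leveneTest`), Spearman rank correlation
  (exact null distribution when untied), Pearson for paired trends.
* **Confocal post-processing**: zero below the per-image 80th
  percentile, normalise the remainder, gamma 0.4.

# Sensitivity, planning, and bead loading

The shot-noise displacement sensitivity is defined as the
single-quadrature standard deviation of the N-sample complex mean of the
per-frame displacement noise:
$\delta z = \lambda_0 / (4\pi n \sqrt{2 N \cdot SNR})$ — 27 pm at
1300 nm, n = 1.34, N = 6400, 28 dB. The amplitude estimator (factor 2/N)
has exactly twice this quadrature noise; the Monte-Carlo calibration
test ties the demodulator to this formula within 5%. The maximum
measurable modulus divides the peak force by $6\pi a$ times 4× the
displacement sensitivity; the factor 4 is the unique amplitude-threshold
constant consistent with both endpoints of the 550–1200 Pa
range (76 pm and 36 pm), and is exposed as a parameter. Whether the
0.95-µm melamine or 0.85-µm polystyrene radius underlies that range is
not stated; 0.95 µm matches both endpoints and is the default. Bead
loading converts a mean edge-to-edge nearest-neighbour spacing to a
volume fraction through the Poisson nearest-neighbour relation
$\bar r_{centre} = 0.554\,n^{-1/3}$.

# The synthetic-data generators, and what passing tests show

`gen_bm_stack` composes the whole forward model: static speckle phase
per voxel, 3×3×3 bead reflectors whose phase follows the true
$G^*$-derived response, a separable depth-cumulative PT phase field, and
per-frame phase noise of $1/\sqrt{SNR}$. Magnitudes are constant in
time; the shot-noise limit enters through phase noise only, which is
the channel the pipeline reads. Defaults are the study conditions:
6400 frames at 425 Hz, 20 Hz modulation, 0.75-µm pixels, 28 dB bead SNR,
16 dB medium scatter, 1300 nm / 1.34. The PT forward model is the same
separable form the reconstruction assumes; a quadratic-depth variant
exists to exercise model mismatch. `gen_trajectory_movie` renders
integrated bead motion with a 1.5-µm Gaussian axial PSF and 20-dB
additive noise. `gen_pericellular_scene` draws beads uniformly around a
spherical cell with
$G'(r) = G_{bg} (r/30\,\mu m)^{\beta}$ inside 30 µm (defaults
β = −0.19, G_bg = 150 Pa, loss ratio 0.4, lognormal CV 0.25 — chosen as
representative of fibrin constructs) — because the scatter is exactly
lognormal, the log–log OLS confidence interval has nominal coverage by
construction, and the 500-replicate coverage test verifies the fit
machinery rather than discovering new statistics. `gen_fibre_volume`
renders cylinder fibres (intensity ∝ thickness) or plants exact shell
occupancies.

What these tests do **not** show: robustness to real OCT speckle
decorrelation, magnitude noise, PT fields that are not separable,
aberrated beams, bead polydispersity, or sample drift beyond a global
per-frame phase. The generators emulate the signal structure the
algorithms assume plus calibrated phase noise; agreement on them
validates the algebra and the noise propagation, not the instrument.

# Problem sizes and numerical defaults

The end-to-end recovery study runs 6-bead scenes on 32×32-voxel slices
(3 slow positions each) at the full 6400 frames, 9 scenes per modulus
group — 54 beads per group at G′ ∈ {50, 200, 500} Pa — sizes chosen to
exercise the full operating point while keeping a complete study in the
minutes range on one core. The force round trip uses 5 lateral segments
of 1.8-s movies; the coverage study uses 500 replicate scenes of 400
beads. Fixed-point inversion tolerance defaults to 1e-12 relative;
ODE integration uses `deSolve::lsoda` with rtol 1e-10 (the bead momentum
relaxation time, ~0.2 µs, makes the equation stiff relative to
second-scale trajectories). Ties and degenerate inputs are handled
explicitly: empty masks are legal empty results, featureless trajectory
images carry zero quality rather than fabricated velocities, all-equal
images threshold to zero with a warning.

# Data formats

BM-mode stacks travel in a single-file binary container: an 8-byte
magic, an 8-byte little-endian header length, a JSON header (dims,
dtype, acquisition metadata per slow-axis group), then interleaved
little-endian (Re, Im) float pairs per group, complex64 by default with
a documented 1e-6 downcast tolerance. Bead records are plain CSV with a
fixed column order in SI units; the loss-ratio column is re-verified as
G″/G′ on read. Configurations are YAML with unknown keys rejected.

# Known limitations

No Basset history or Faxén wall corrections; no nonlinear or
poroelastic constitutive models; no torque or transverse trapping
forces; no raw-spectrum OCT reconstruction or computational defocus
correction (the pipeline starts from reconstructed complex stacks); PT
reconstruction assumes lateral separability; automated fibre
connectivity counting is out of scope (counts are merged from a
user-supplied table).
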