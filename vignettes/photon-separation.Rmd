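---
title: "Separating ballistic and diffusive fluorescence photons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating ballistic and diffusive fluorescence photons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lightsieve)
```

# The image-formation model

A light-sheet microscope illuminates one plane of the sample from the side
(propagation axis `z`, scan axis `x`) and detects fluorescence along the
perpendicular axis `y`. A 3-D stack is acquired plane by plane; the plane at
detection depth `y0` is seen through `y0` micrometers of tissue.

The system response factorizes into the slit-gated illumination sheet
`h_ill`, the widefield detection PSF `h_det`, and an object response
`h_obj(r, y0)` describing what the tissue itself does to the fluorescence on
its way out:

```
h_sys(r, y0) = h_ill(r) · [ h_det ⊛ h_obj(·, y0) ](r)
```

`h_obj` is a mixture over scattering orders `j`. The number of scattering
events over the exit path follows a Poisson law in the optical depth
`µ_sca·y0`, so a fraction `c_0 = exp(−µ_sca y0)` arrives ballistically
(Lambert–Beer) and fractions `c_j = (µ_sca y0)^j e^{−µ_sca y0}/j!` arrive
after `j` deflections. Each deflection draws a Gaussian angle of standard
deviation `1/γ` per transverse axis; in the small-angle regime the
deflections occur uniformly along the exit path (mean-square lever arm
`y0²/3`) and independent events add variances, giving the per-axis lateral
displacement width

```
σ_j(y0) = (y0 / γ) · sqrt(j / 3).
```

In the lateral Fourier plane (`k` in cycles/µm throughout the user API) the
object transfer is the Gaussian mixture

```
H_obj(k, y0) = Σ_j c_j(y0) exp(−2π² σ_j² k²),
```

whose high-frequency limit is the ballistic floor `exp(−µ_sca y0)`. Key
assumptions, stated once: absorption is neglected; the medium is
homogeneous (one `µ_sca`, one `γ` for the whole stack); scattering displaces
photons laterally but adds no axial blur (`H_obj` depends on `k_⊥` only), so
the object kernel is applied as a 2-D `(x, z)` kernel to every `y`-slice of
the detection PSF; and the coherent illumination beam's own scattering is
outside the model — only the detection path is treated.

Two derived quantities deserve a note. The anisotropy factor is the
Langevin function `g = coth(γ) − 1/γ`, which has the required limits (0 for
isotropic scatterers, 1 for pure forward scattering). The truncation order
`j_max` is the smallest integer holding all but `1e−6` of the Poisson mass;
`object_transfer()` renormalizes the truncated mixture so `H_obj(0) = 1`
exactly. The width-law coefficient `1/√3` is exposed as
`sigma_coef` in `scattering_params()` in case a different lever-arm model is
wanted; the Monte-Carlo walk (`simulate_photon_walk()`, exponential free
paths, per-event Gaussian deflection, segment-wise accumulation) validates
the default: single- and double-scatter displacement variances match
`σ_j²` within Monte-Carlo error.

A known, deliberate approximation: conditional on `j`, the exact walk's
displacement is a *scale mixture* of Gaussians (its variance depends on the
random event positions), of which the model keeps only the
variance-matched Gaussian. Distribution-level comparisons therefore agree
in variance and fractions but differ in shape by a few percent
(Kolmogorov–Smirnov distance ~0.02–0.04 against the pooled mixture at
optical depths 0.5–5). This is inherent to the Gaussian-mixture transfer
model, not a sampling artifact.

# Optics

Beams and PSFs are computed by scalar angular-spectrum propagation
(`angular_spectrum_propagate()`), adequate at the moderate apertures used
here. The Gaussian beam's waist is set so its axial intensity FWHM equals
`sheet_fov` (default 300 µm); the Bessel beam comes from a thin annular
pupil (ring NA = `na_ill` = 0.15, fractional width 5%). Confocal line
detection is a unit-height rectangle of width `d_slit` convolved along the
scan axis (1.3 µm in object space for the confocal mode, 50 µm for
widefield; fractional end weights keep the mass scaling exact). The
detection aperture is not dictated by the imaging geometry alone, so the
package defaults to a water-immersion `na_det = 0.8`, `n = 1.33`; both are
plain config fields. Default grids mirror a 40× / 6.5-µm-pixel camera:
lateral pitch 0.1625 µm, plane spacing 0.5 µm.

# Phantoms and the forward simulator

`generate_phantom()` builds a membrane-labelled cell lattice: dart-thrown
cell centers whose target diameter grows from 5–7 µm at the volume center to
10–20 µm at the periphery, a Voronoi partition, and fluorescent shells on
the cell boundaries (plus a bead-cluster variant). The size gradient is not
botanical realism — it reproduces the one feature of real tissue that
stresses the fitting procedure: the object's spatial-frequency content
changes along the detection axis, so the reference normalization never
cancels the object spectrum perfectly.

`simulate_imaging()` evaluates the shift-variant model plane by plane: the
output plane at `y0` is the 3-D convolution of the phantom with
`h_sys(·, y0)` evaluated at the in-focus plane, computed in the lateral
Fourier domain with the analytic `H_obj`. Planes beyond the stack
boundaries are mirrored — the imaged region is treated as interior to a
larger object; without this the reference planes at the stack edge would
see only half the out-of-focus light and their spectra would not cancel in
the normalization. Shot noise is Poisson at a photon budget of 5000 counts
for the brightest voxel with 3 counts r.m.s. Gaussian read noise — typical
of an sCMOS acquisition that fills a fraction of the well depth. What the
simulator does **not** emulate: illumination-side scattering (stripe
artifacts), refractive-index heterogeneity, spatially varying scattering
parameters, depth-dependent absorption. Passing tests therefore demonstrate
internal consistency of model, estimator and deconvolution under the
model's own physics plus a realistic object confound — not performance on
real tissue.

# Contrast and depth spectra

`contrast_coefficient()` computes Q as the ratio of mean spectral magnitude
in the high band (`k_c < k ≤ k_N`) to the low band (`0 < k ≤ k_c`), DC
excluded, with `k_c = 1/d_cell` and `d_cell = 20 µm` (the largest cell
size). There is no upper signal cut; instead each DC-normalized spectrum is
noise-adapted: a flat magnitude floor is mixed in (`sqrt(S² + a²)`) until
the mean over the pure-noise band (beyond 0.9 of Nyquist) reaches `n_l`.
The default `n_l = 0.002` sits just above the shot-noise floor of a
DC-normalized 256²-pixel plane at the default budget
(`~1/sqrt(total counts) ≈ 4·10⁻⁴`); a much larger value would swamp the
object signal and reduce Q to a floor ratio, defeating the metric's purpose
of comparing depths at equal noise.

`normalized_depth_spectrum()` Fourier-transforms every plane, normalizes by
its DC value, optionally removes each plane's white-noise magnitude floor in
quadrature (`debias = TRUE`; keeps deep-plane ratios centered on the true
transfer), smooths over `2b+1 = 5` neighboring planes, divides by the
reference spectrum (mean of the `n_ref = 3` planes nearest the detection
objective, where the traversed tissue is thinnest), and averages over
azimuth into radial bins — plus a wedge around the `k_z` axis for confocal
analysis. Azimuthal averaging uses the mean; any constant factor cancels in
the normalization.

# Fitting the scattering parameters

`fit_scattering_params()` fits `(µ_sca, γ)` jointly across all depths by
weighted nonlinear least squares (Levenberg–Marquardt via `minpack.lm`),
with weights proportional to the azimuthal bin counts. The model prediction
replicates the measurement pipeline — including the plane smoothing window
and the division by the (not exactly unity) reference transfer — so shallow
reference depths introduce no bias. Numerical choices, each of which was a
genuinely open design point:

* **Log-scale residuals** (default): they balance the ballistic plateau
  (spanning two orders of magnitude over depth) against the low-frequency
  Gaussian, and turn the object-spectrum confound — which is approximately
  multiplicative — into an additive nuisance.
* **One free amplitude per depth plane** (`scale_per_depth = TRUE`,
  profiled out analytically): the object's spectral content varies along
  `y0`, multiplying each plane's normalized spectrum by an unknown factor;
  the parameters remain identified by the within-plane shape
  (plateau-to-Gaussian ratio and width).
* **One free amplitude per frequency bin** (`scale_per_freq = TRUE`,
  profiled jointly with the depth scales by alternating weighted sweeps):
  the reference spectrum is measured from only `n_ref` planes, so its
  realization noise — together with any depth-stable part of the object
  confound — enters every depth as a common `k`-dependent factor that no
  amount of depth averaging removes. A separable product of a depth factor
  and a frequency factor cannot imitate the transfer's depth-progressive
  narrowing, so `(µ_sca, γ)` stay identified by the non-separable
  interaction. On graded membrane phantoms at the canonical volume this
  cut the cross-realization scatter of the widefield `µ_sca` from roughly
  ±15% to under 7% (and left the y-invariant texture benchmarks, where
  both nuisance sets are exactly superfluous, unchanged). A low-rank
  smooth-in-`k` nuisance was also evaluated and was uniformly worse in
  the widefield mode; the full per-bin scale is the default for both
  modes.
* **Frequency band**: bins are kept only where the reference spectrum
  exceeds 20× its noise floor (and an absolute floor of `1e−5` for the
  noise-free limit), capped at `0.8 k_N`; beyond that the ratio measures
  noise against noise.
* **Starts and bounds**: a small grid of physically plausible starts is
  screened, then refined within `µ_sca ∈ [0, 500] mm⁻¹`, `γ ∈ [0.5, 500]`.
  A flat transfer is explained equally by `µ_sca = 0` and by `γ` at its
  upper bound (forward scattering at any `µ_sca`); when the optimizer lands
  on the `γ` bound and the scatter-free model fits within 5% of the same
  residual sum, the scatter-free reading is reported.
* **Uncertainty**: percentile intervals from 200 bootstrap resamples of
  depth planes (the objective and weighting are not prescribed by the
  physics, so a resampling interval is more honest than a curvature one).
* **Degenerate input**: spectra from a single depth plane are refused —
  the two parameters are not jointly identifiable from one depth.

## Confocal stacks: the k_z-restricted mode

Confocal line detection gates laterally displaced photons, so the isotropic
mixture no longer describes the azimuthally averaged spectra; the transfer
along the `k_z` axis, however, remains informative. In `confocal_kz` mode
the fit uses only a wedge around the `k_z` axis. Because the slit re-weights
the scattering orders — and out-of-focus illumination structure such as the
Bessel ring system admits displaced photons in a way no simple profile
overlap captures — the package tabulates the system's `k_z` response
numerically: `system_kz_transfer()` pushes a grid of Gaussian blur widths
through the actual `h_ill`/`h_det` and bins the result over exactly the
same wedge and radial bins as the data, so the fitted model mirrors the
measurement statistic at any wedge width. A simpler closed-form
re-weighting by the central illumination profile and a fully injectable
weight hook (`illumination_profile`) are also provided. The default wedge
for confocal fitting is ±22.5°: the wider wedge doubles the number of
independent object modes per frequency bin, which stabilizes the estimates
markedly across phantom realizations, while the wedge-matched table keeps
the model consistent.

**Limitation.** On membrane-lattice phantoms at the canonical volume
(41.6 × 60 × 41.6 µm) the `k_z` wedge contains only a handful of object
modes per frequency bin, and confocal gating makes deep planes' spectra
sensitive to out-of-focus planes with different content. The confocal
estimates are therefore realization-limited in a way the widefield fit is
not: across phantom seeds `µ_sca` scatters by roughly ±5–30% around the
truth, and the per-frequency nuisance scale — which the sparse wedge can
least afford — pulls `γ` systematically low by ~10–15%. Disabling
`scale_per_freq` trades that `γ` bias for substantially worse and
occasionally catastrophic errors on both parameters, and none of the
other estimator variants we examined (plateau-only fits with fixed `γ`,
alternative coherence assumptions in the tabulated response, depth
windows, band cuts, power-domain objectives, smooth low-rank frequency
nuisances) does better overall. The widefield (azimuthally averaged) fit
does not share this limitation — its bins pool hundreds of pixels — and
recovers both parameters within a few percent at the same conditions. For
real confocal data the practical advice is the same as the model's own
logic: treat the `k_z`-restricted coefficients as approximate and prefer
a widefield companion stack for quantitative values.

# Depth-dependent deconvolution

`depth_dependent_deconvolve()` deconvolves the stack once per depth section
(12 sections by default) with a Wiener filter whose system PSF is matched
to the section's depth, then blends the section results with shifted Hann
windows. Raised-cosine windows at 50% overlap form an exact partition of
unity; the first and last windows extend flat so the edges keep total
weight one. The Wiener gain is `conj(H)·SNR/(|H|²·SNR + 1)` with the
signal-to-noise ratio estimated linearly in the radially normalized
frequency, `SNR(k) = A·max(0, 1 − |k|/k_N)`; the filter is evaluated with
mirror padding (enlarged to FFT-friendly sizes) and negative output values
are retained (a `clamp` flag exists for display). A `neighborhood` mode
deconvolves each section only on its blending neighborhood plus one window
span, trading a single large FFT for several small ones at identical
interior output.

The default `A = 10⁴` was calibrated on the canonical simulated stack by
an objective independent of any contrast metric: the affine-matched
mean-squared error between the deconvolved stack and the known phantom
density. Scanning `A ∈ {10², 10³, 10⁴, 10⁵}` gave depth-dependent MSEs of
0.0769, 0.0641, 0.0557 and 0.0657 — a clear optimum at `10⁴`, where the
depth-matched result also beats a single filter frozen at the surface PSF
(MSE 0.0653) and raises Q at every depth. At `10²` the filter is too
conservative to out-resolve the fixed-PSF baseline; at `10⁵` noise
amplification takes over.

When comparing contrast before and after deconvolution, use the raw
coefficient (`n_l = 0`). The noise adaptation in Q exists to compare
acquisitions at different exposures and assumes a *white* noise floor; a
linear deconvolution filter reshapes the noise spectrum, so adapting both
stacks to the same flat floor biases the comparison against the filtered
stack.

# Problem sizes used by the test suite

The canonical end-to-end conditions are the 256 × 120 × 256-voxel
membrane-lattice stack at (0.1625, 0.5, 0.1625) µm pitch — 60 µm of depth,
optical depth 3 at `µ_sca = 50 mm⁻¹` — with the default photon budget.
Module-level properties run on smaller volumes (≈ 64–128 voxels per axis)
and on y-invariant textured volumes whose object spectrum cancels exactly
in the reference normalization; the latter isolate the estimation machinery
from the object confound and are the right substrate for tight tolerances,
while the membrane phantom exercises the confound deliberately.
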