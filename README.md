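# lightsieve

Fluorescence photons collected through tens of micrometers of tissue split
into two populations: **ballistic** photons that reach the detector
unscattered and carry diffraction-limited information, and **diffusive**
photons that scatter one or more times, land in the wrong place on the
camera, and blur the image. In light-sheet microscopy of strongly scattering
samples (plant roots, embryos, spheroids) the diffusive fraction grows
exponentially with the detection depth `y0`, and with it the loss of
contrast and resolution.

`lightsieve` implements an analytic model of this process, a blind procedure
that extracts the material's scattering parameters from an image stack
alone, and a depth-dependent deconvolution that re-weights the two photon
populations — together with the light-sheet optics simulation and synthetic
phantom generator needed to test every stage end to end.

## The model

A photon emitted at depth `y0` (µm) undergoes `j` scattering events with
Poisson probability set by the scattering coefficient `µ_sca` (mm⁻¹):

    c_j(y0) = (µ_sca y0)^j / j! · exp(−µ_sca y0)

`c_0` is the Lambert–Beer law for the surviving ballistic fraction. Each
event deflects the propagation direction by a Gaussian-distributed angle of
width `1/γ` per transverse axis (`γ` is the dimensionless angular-width
material constant; the anisotropy factor is `g = coth γ − 1/γ`). Order-`j`
photons are laterally displaced by a Gaussian of per-axis width
`σ_j = (y0/γ)·√(j/3)`, so the sample itself acts as a depth-dependent
transfer function on each lateral spatial frequency `k` (cycles/µm):

    H_obj(k, y0) = Σ_j c_j(y0) · exp(−2π² σ_j² k²)

— a Gaussian mixture that narrows with depth on top of a constant ballistic
floor `exp(−µ_sca y0)`. Because the floor survives at all frequencies, the
diffusive blur can be undone by deconvolution as long as the ballistic
signal stays above the noise.

The package provides:

* `scattering_params()`, `photon_fraction()`, `object_transfer()`,
  `object_response()`, `simulate_photon_walk()` — the scattering model and
  its Monte-Carlo oracle;
* `optics_config()`, `beam_intensity()`, `illumination_psf()`,
  `detection_psf()`, `system_psf()` — scanned Gaussian/Bessel light-sheet
  optics with widefield or confocal slit detection, by angular-spectrum
  propagation;
* `contrast_coefficient()`, `contrast_profile()`, `spectral_width_map()` —
  the noise-adapted spectral contrast metric Q and directional spectral
  widths;
* `normalized_depth_spectrum()`, `fit_scattering_params()`,
  `system_kz_transfer()` — reference-normalized depth spectra and the blind
  joint fit of `(µ_sca, γ)`, including a k_z-restricted mode for confocally
  detected stacks;
* `deconv_plan()`, `build_wiener()`, `depth_dependent_deconvolve()` —
  sectioned Wiener deconvolution blended with shifted-Hann windows;
* `phantom_spec()`, `generate_phantom()`, `simulate_imaging()`,
  `end_to_end_recovery()` — membrane-lattice / bead phantoms and the
  forward imaging simulator;
* `read_stack()`, `write_stack()`, `read_run_config()` — 32-bit float TIFF
  stacks and YAML run configs, plus a thin CLI at `inst/cli/lightsieve`.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and result
tables are tibbles with `autoplot()` methods.

## Worked example

Simulate a membrane-labelled volume imaged at increasing depth, then
recover the scattering parameters blindly from the stack:

```r
library(lightsieve)

spec   <- phantom_spec(dims_um = c(41.6, 60, 41.6),
                       pitch = c(0.1625, 0.5, 0.1625), rng_seed = 42)
optics <- optics_config("gaussian", d_slit = 50)      # widefield detection
truth  <- scattering_params(mu_sca = 50, gamma = 22.4)

phantom <- generate_phantom(spec)
stack   <- simulate_imaging(phantom, optics, truth, noise_model(5000, 3, 7))
spectra <- normalized_depth_spectrum(stack)
fit     <- fit_scattering_params(spectra, n_boot = 0)
fit
#> <scatter_fit> (widefield) mu_sca = 47.8 /mm, gamma = 23.6 (g_HG = 0.958)
#>   4095 observations over 117 depths; residual norm 50
```

The recovered `µ_sca = 47.8 mm⁻¹` and `γ = 23.6` sit within ~5% of the
generating values: within each depth's normalized spectrum the ratio of
the ballistic plateau to the diffusive Gaussian pins `µ_sca`, and the
Gaussian's progressive narrowing with depth pins `γ` — a joint shape
signature that survives the per-depth and per-frequency nuisance scales
the fit profiles out to stay blind to the object's own spectrum. With the
parameters in hand, sharpen the stack:

```r
plan <- deconv_plan(y_extent = 59.5, n_sections = 12, wiener_A = 1e4)
dec  <- depth_dependent_deconvolve(stack, fit$params, optics, plan)
contrast_relative(contrast_profile(dec, n_l = 0), contrast_profile(stack, n_l = 0))
```

which raises the contrast coefficient Q at every depth. (`n_l = 0` turns
off the white-noise-floor adaptation of Q, which is meant for comparing
acquisitions at different exposures; a linear deconvolution reshapes the
noise spectrum, so filtered stacks are compared on the raw Q.)

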