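---
title: "Models and methods behind holoscat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holoscat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical models, numerical choices and known
limitations of the package, in the spirit of a methods section: what is
computed, under which assumptions, and what passing the test suite does
and does not demonstrate about real data.

## 1. Imaging model

### The scattering-field amplitude

Every quantity in the package reduces to the scattering-field amplitude

$$ \mathrm{SA} \;=\; \frac{|E_s|}{|E_i|} \;=\;
   \alpha\,\frac{|E_\mathrm{sample}-E_\mathrm{bg}|}{|E_\mathrm{bg}|},
   \qquad E_\mathrm{sample}=E_\mathrm{bg}+E_s,\quad
   E_\mathrm{bg}=\alpha E_i . $$

`alpha` is the field transmittance of the sample holder in the forward
(transmission) channel, taken as 1, and the field reflectivity of the
glass--water interface in the backward (epi) channel, whose
normal-incidence Fresnel value $(1.52-1.33)/(1.52+1.33)\approx0.067$
rounds to the configured default 0.07. By the triangle inequality with
$|E_\mathrm{sample}|\le|E_\mathrm{bg}|$ at $\alpha=1$, SA is bounded by
\[0, 2\]; `compute_sa()` treats values above 2 as evidence of an `alpha`
misconfiguration and warns rather than clipping.

### Multiplexed hologram formation

The simulator writes both channels onto one sensor frame as

$$ I \;=\; D \;+\; \bar D \sum_{c\in\{FS,BS\}} \nu_c\,
   \mathrm{Re}\!\left[\tilde E_c\,R_c^\ast\right],
   \qquad D=\sum_c B_c\,|\tilde E_c|^2 , $$

where $\tilde E_c = E_c/\alpha_c$ is the channel field normalized to a
unit background, $R_c$ a unit plane wave at that channel's carrier,
$B_c$ the channel's DC electron budget, and $\bar D$ the spatial mean of
the total DC. Written this way, $\nu_c$ is **exactly** the modulation
depth of channel $c$'s fringe against the frame's total DC intensity,
which is also what the spectral AC/DC visibility estimator
(`estimate_visibility()`, $2\,\overline{|AC|}/\overline{|DC|}$)
measures — so simulated visibilities round-trip through the estimator
for single- and dual-carrier frames alike. Cross terms between the two
object fields and between the two references are omitted; in the
physical instrument they are suppressed by the source's short coherence
length, and the simplification is exact in the shot-noise analyses
because those terms carry no additional photons in this model.

Expected electrons are Poisson-sampled per pixel and quantized by a
linear camera model (100 ke$^-$ full well, 12 bit, gain
$=$ full well$/2^{12}\approx24.41\,e^-$/DN, zero read noise — the
shot-noise-limited regime). The *ideal* rendering mode
(`poisson = FALSE, quantize = FALSE`) skips clipping and sampling so
that linearity-based oracles hold to machine precision.

### Default study conditions

The default `optical_config()` reproduces the reference instrument:
515 nm illumination, medium index 1.33, collection NA 1.33,
magnification 208, 1024×1024 sensor at 500 fps, spatial-frequency
aperture radius 115 px (analytic area
$\mathrm{round}(\pi/4\cdot230^2)=41{,}548$ px). The sensor pixel pitch
is not an independent instrument constant; 9 µm is inferred from the
44 µm field of view at ×208 and kept as a configurable field. Default
scene conditions: fringe visibility 0.25 per channel, forward-channel
budget 20,000 e$^-$/px with the epi illumination stronger by
$1/\alpha_{BS}^2\approx204$, which equalizes the two channels' photon
budgets on the sensor — the condition under which the FS/BS
minimum-detectable-SA ratio equals $1/\alpha_{BS}\approx14$.

Smaller grids used in tests and in the acceptance script keep the same
Fourier *fill fraction* (aperture/Nyquist) as the full sensor, or — for
reconstruction oracles — shrink the collection NA so that the pupil
support sits strictly inside the carrier window. The test geometry
additionally satisfies the off-axis condition (carrier offset ≥ 3×
aperture radius) so the DC autocorrelation term cannot leak into the
carrier lobe; the full-sensor default geometry, like the physical
instrument, satisfies it only approximately, which is irrelevant for
weak scatterers but biases the demodulated field of very strong ones
(see Limitations).

## 2. Reconstruction

`demultiplex()` demodulates the frame with the carrier plane wave
(bringing the $E$-bearing lobe to DC — demodulating with the conjugate
would return $E^\ast$ and flip every phase-sensitive step), applies a
hard circular window of the configured radius, and inverse transforms.
`propagate()` is exact scalar angular-spectrum propagation,
$\exp\!\big(2\pi i z\sqrt{(n/\lambda)^2-f_x^2-f_y^2}\big)$, with
evanescent components zeroed; it is unitary on the propagating band.

`autofocus()` scans a z grid and maximizes a sharpness metric of the
differential field. The default metric is the amplitude kurtosis;
peak-fraction, gradient-energy and Tamura metrics are selectable. The
kurtosis decays monotonically through the depth of field but is not
globally monotone (diffraction rings), so the scan range should bracket
focus within a few micrometres. FS and BS are refocused independently
by default; a shared-z analysis can simply pass one channel's result to
the other.

Phase drift between sample and background acquisitions is modelled as a
global offset plus a linear ramp, fitted by least squares to the wrapped
phase of $E_\mathrm{sample}/E_\mathrm{bg}$ over a sample-free mask
(user-supplied, or automatically the flattest 20% of pixels by
$|{\rm ratio}-1|$). No unwrapping is performed; the fit assumes the
drift stays within $(-\pi,\pi)$ over the mask, the small-drift regime
between consecutive acquisitions. The pipeline route
(`reconstruct_sa()`) first divides the sample field by the spatial mean
of its complex ratio to the background, removing laser-power and global
path-length fluctuations frame by frame.

## 3. Noise calibration

The temporal-noise procedure follows the frame-differential protocol:
consecutive-frame differential SA images
$\alpha|E_{t+1}-E_t|/|E_\mathrm{bg}|$ (499 differentials from 500
frames), per-pixel temporal STD, spatial mean over a 200×200 window.
The analytic shot-noise floor is

$$ \delta SA^{\rm shot} \;=\;
   2\sqrt{\frac{(4-\pi)\,A_\mathrm{aperture}}
               {2\,\nu^2 N_e\,A_\mathrm{sensor}}} , $$

whose $\sqrt{(4-\pi)/2}$ factor is the Rayleigh-distribution STD of the
modulus of a complex Gaussian perturbation and whose leading 2 absorbs
the frame-differencing $\sqrt2$ together with the lobe-amplitude
bookkeeping. The package validates the formula as a whole against
Poisson simulation (agreement within a few percent at 200 frames)
rather than re-deriving each factor. The *per-channel* floor carries an
extra factor $\alpha_c$ from the SA definition; with equal photon
budgets and visibilities the FS/BS floor ratio is therefore
$1/\alpha_{BS}=14.3$, rounding to 14. Absolute floors depend on the
unmeasured $\nu$ and $N_e$ of a given acquisition and are reported per
run, not asserted as constants.

## 4. Particle characterization

Backgrounds: for flowing particles, the mean of frames
$t-200\ldots t-101$ and $t+101\ldots t+200$ (two 100-frame means
averaged); for intracellular particles whose axial jitter randomizes the
scattered phase, the long-time complex mean of the full series.
Detection is local maxima with greedy non-maximum suppression and
intensity-weighted sub-pixel refinement. Cross-sections
$\sigma=\iint SA^2\,dx\,dy$ are estimated either by a radial Gaussian
fit (analytic integral $A^2\pi s^2$, robust to uncorrelated background)
or by direct pixel summation over the detection region (preferred inside
cells where structured background breaks the Gaussian shape);
thresholded pixel-region summation supports a 3×MAD region rule.

The forward model maps $(n, d)$ to $(\sigma_{FS}, \sigma_{BS})$ with the
Mie partial-wave series, integrating the unpolarized angular intensity
over the forward and backward collection caps
($\theta_{\max}=\arcsin(\mathrm{NA}/n_\mathrm{med})$, 90° for the
NA-matched aqueous default). This is a documented modelling choice — a
coherent-PSF image-formation treatment might shift absolute
cross-sections — validated by its Rayleigh limit
($\sigma_{FS}/\sigma_{BS}\to1$, $d^6$ scaling), by the partial-wave
identity $\sigma_{FS}+\sigma_{BS}=\sigma_\mathrm{sca}$ at full capture,
and by exact self-consistency of the inversion. Since measured and model
cross-sections are both normalized to a reference population (151-nm
polystyrene; its refractive index at 515 nm is not tabulated here and
defaults to 1.598, configurable), absolute scale factors cancel.

Inversion minimizes the squared log-distance between measured and model
$(\sigma_{FS},\sigma_{BS})$ over a precomputed grid (default
$n\in[1.34,1.60]$ step 0.002, $d\in[20,1000]$ nm step 2 nm), with
optional Nelder--Mead refinement against the continuous forward model
and Jacobian-propagated uncertainties. Estimates on a bounds edge (e.g.
the physiological constraint $n\in[1.38,1.54]$ for intracellular
particles) are flagged. The $(n,d)\mapsto(\sigma_{FS},\sigma_{BS})$ map
develops near-degenerate ridges at low contrast; a fine grid keeps the
coarse argmin in the right basin.

The bundled two-population ensemble (`simulate_bead_population()`:
204 polystyrene beads at 151 ± 3 nm, 412 silica beads at 203 ± 12 nm)
applies 8% lognormal per-channel measurement noise to the
cross-sections. That level was fixed once, by matching the recovered
silica refractive-index dispersion to the experimentally observed
±0.006 for such bead measurements; the resulting size spread
(≈ ±12–17 nm) is then dominated by the intrinsic diameter variance.
Under these conditions the two populations' forward cross-sections
overlap while the backward ones separate by several pooled standard
deviations, and the inverted population means land within ±0.01 in
refractive index and ±10 nm in diameter. A small upward RI bias
(≈ +0.006 for the high-index population) remains — a curvature effect of
inverting a noisy nonlinear map — and grows roughly quadratically with
the noise level.

## 5. Dynamic maps

The dynamic-imaging chain: per-frame normalization (amplitude by its
spatial mean, phase by its spatial mean), subtraction of the 11×11
local spatial mean from both quadratures (mirror padding at borders;
an impulse retains exactly $120/121$ of its value), per-pixel removal of
the temporal mean, then a zero-phase **brick-wall** discrete-Fourier
band selection per quadrature. The map value is
$\alpha\sqrt{\mathrm{STD}_{re}^2+\mathrm{STD}_{im}^2}$ with population
STDs, so disjoint bands are exactly additive in power (Parseval) and a
coherent perturbation of modulus $A$ at an in-band frequency yields
$A/\sqrt2$. Amplitude-only and phase-only variants are selectable. A
brick-wall filter was chosen over an IIR design because its pass-band
is exactly testable; detrending beyond the temporal mean is
deliberately omitted since the 1 Hz lower band edge already excludes
drift. The default bands are 1–10 Hz (slow, organelle-scale motion) and
100–250 Hz (fast fluctuations, up to Nyquist at 500 fps); the series
must span at least two periods of the slowest band edge.

## 6. Dry mass and fringe heights

Dry-mass surface density is the standard refraction-increment
conversion $\lambda\,\varphi/(2\pi\gamma)$ with $\gamma$ defaulting to
0.18 mL/g (protein average, configurable); totals require an explicit
cell mask, and the map assumes wrap-free phase. The height estimator is
deliberately minimal: it counts thin-film fringe periods along a
profile via zero crossings of the mean-centred, lightly smoothed trace
and converts each full fringe to $\lambda/(2 n_\mathrm{med})$
(≈ 193.6 nm in water at 515 nm). It reports a cumulative height, not a
height map.

## 7. Problem sizes and determinism

Simulated validations use grids from 64² to 256² pixels and stacks of
120–2,500 frames — sizes at which every statistical tolerance in the
test suite (2–10%) is several estimated standard errors wide, chosen as
the package's own test conditions. All stochastic stages derive their
RNG streams from a single scene seed folded with the frame index
(32-bit safe), so any frame, series or ensemble is exactly reproducible
from its configuration and seed, and the caller's RNG state is never
disturbed.

## 8. Known limitations

* **Strong scatterers.** The demodulated field is linear in $E_s$ only
  while the hologram autocorrelation term $|E_s/\alpha|^2$ is
  negligible or spectrally separated. With the full-sensor default
  carriers (offset 2.2× the aperture radius) scatterers with peak
  SA ≳ 0.1 begin to bias their own reconstruction at the percent level.
* **Scalar, aberration-free optics.** No polarization, no vectorial
  high-NA corrections, no aberrations, no tilted epi illumination
  geometry.
* **Camera model.** Linear gain with optional Gaussian read noise only;
  no dark current, fixed-pattern noise or nonlinearity.
* **Forward model vs. image formation.** Cross-sections integrate Mie
  far-field intensity over collection caps; coherent PSF effects on
  $\sigma$ are not modelled (they cancel to first order under the
  reference normalization).
* **Real-data gaps.** The simulator does not emulate out-of-focus
  bead background, cell-internal dynamic background, air-fluctuation
  spectra or stage drift beyond a linear phase ramp — so green tests
  certify the computational chain and its statistical behaviour, not
  instrument-level performance on biological samples.
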