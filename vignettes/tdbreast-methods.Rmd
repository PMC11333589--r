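---
title: "Models and methods behind tdbreast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tdbreast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdbreast)
```

# The measurement this package models

Time-domain diffuse optical spectroscopy (TD-DOS) injects picosecond light
pulses into tissue and histograms the arrival times of re-emitted photons
(a distribution of times of flight, DTOF, built by time-correlated single
photon counting). Because absorption shortens the late tail of the pulse
while scattering delays and broadens it, a single time-resolved curve
separates the absorption coefficient $\mu_a$ from the reduced scattering
coefficient $\mu_s'$ — something a continuous-wave measurement at one
distance cannot do. Scanned over 600–1100 nm in 10 nm steps (51
wavelengths), the technique yields absorption spectra carrying the
signatures of the main breast constituents (water, lipid, collagen, oxy-
and deoxy-hemoglobin) and scattering spectra carrying microstructural
information. Breast composition estimated this way tracks mammographic
density, the proportion of fibro-glandular to adipose tissue that is a
major independent breast-cancer risk factor.

`tdbreast` implements the full analysis chain for such measurements —
forward models, curve fitting, composition retrieval, density indices, and
the configuration-comparison statistics — together with a synthetic cohort
generator that emulates the in vivo measurement protocol, so that every
stage is testable end-to-end without access to measured data.

# Forward model

## Time-resolved diffusion with extrapolated boundaries

Photon transport is modeled by the time-dependent diffusion equation for a
homogeneous medium. Two geometries are supported, matching the two probe
arrangements of the protocol:

* **reflectance**: source and detector on the same surface of a
  semi-infinite medium, separated by $\rho$ (2 or 3 cm);
* **transmittance**: source and detector on opposite faces of an infinite
  slab of thickness $s$ (the mildly compressed breast), with an optional
  lateral offset.

Boundaries are handled with extrapolated boundary conditions implemented by
the method of images: a zero-fluence plane at distance $z_e = 2AD$ outside
the surface, with the isotropic source at depth $z_0 = 1/\mu_s'$. For the
half-space one dipole pair is exact; for the slab an infinite series of
image pairs is summed. The series is truncated adaptively: symmetric pairs
are added until the newest pair changes every channel by less than a
relative $10^{-9}$ (cap 50 pairs, error if not converged). The tests verify
that tightening this tolerance changes nothing above $10^{-6}$ relative for
2–4 cm slabs, and that a very thick slab's injection-side solution
converges to the half-space solution.

Numerical conventions, each configurable:

* $D = 1/(3\mu_s')$, independent of absorption. This makes absorption enter
  the Green's function exactly as $e^{-\mu_a v t}$ (the Beer–Lambert
  factorization), which the tests assert to machine precision.
* Refractive index $n = 1.4$ (tissue-typical; the boundary factor $A$ is
  computed from the internal-reflection approximation
  $r_d = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n$,
  $A = (1+r_d)/(1-r_d) \approx 3.25$ at $n = 1.4$). Published $A(n)$
  approximations differ by a few percent; since an amplitude factor is free
  in every fit and $z_e$ enters the curve shape only weakly, this choice
  does not drive the retrieved parameters.
* Times are in nanoseconds and lengths in centimeters. The default time
  axis is 4096 channels of ~6.1 ps (25 ns span), the grid of a TCSPC board
  running at a 40 MHz repetition rate; $t = 0$ is photon injection, and any
  instrumental delay is carried by the IRF.

An independent steady-state oracle, `cw_reflectance()`, implements the CW
dipole closed form; the time integral of the TD curve must match it within
1%, which pins the overall normalization and the boundary treatment.

## Instrument response and fit window

A measured system never delivers a delta pulse, so the model curve is
convolved with the instrument response function (IRF) before comparison
with data. `convolve_with_irf()` is the discrete causal convolution scaled
by the channel width (computed by zero-padded FFT; the tests compare it to
the $O(N^2)$ double sum at machine precision). The synthetic IRF is a
Gaussian (default FWHM 150 ps) convolved with a 100 ps single-exponential
detector tail, area-normalized — a modeled stand-in for a real measured
IRF, whose shape is configurable.

Each DTOF is fitted only between 80% of the peak on the leading edge and 5%
of the peak on the falling edge. Early channels are dominated by
poorly-diffused light the model does not describe; late channels by noise
and background. The window is computed on the measured counts with a
first-peak tie-break and clamps to the last channel when the histogram
never falls below 5%.

# Inversion

## Standard (single-wavelength) fit

`standard_fit()` adjusts $(\mu_a, \mu_s')$ at one wavelength by minimizing
count-weighted least squares over the fit window,

$$\chi^2 = \sum_{i \in \text{window}} \frac{(A\,m_i(\mu_a,\mu_s') - y_i)^2}{\max(y_i, 1)},$$

the TCSPC-standard Poisson approximation. The multiplicative amplitude $A$
(unknown, wavelength-dependent throughput) is profiled out in closed form
at every step, leaving a 2-parameter bounded Levenberg–Marquardt problem
($\mu_a \in [10^{-4}, 1]$, $\mu_s' \in [1, 50]$ cm$^{-1}$, relative
tolerance $10^{-10}$, cap 500 iterations). DTOFs with fewer than 1000 total
counts are excluded with a reason code rather than fitted.

## Spectrally-constrained fit

`spectral_fit()` fits all 51 DTOFs at once. The Lambert–Beer law

$$\mu_a(\lambda) = \sum_i \varepsilon_i(\lambda)\, C_i + B$$

replaces $\mu_a$, and the empirical Mie power law

$$\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}, \qquad \lambda_0 = 600\ \text{nm}$$

replaces $\mu_s'$, inside the diffusion model, so the free parameters are
the five constituent concentrations (hemoglobins in µM, water/lipid/
collagen in mg/cm³), the spectrally-flat background absorption $B$
(cm$^{-1}$, bounded to $[0, 0.2]$), and the scattering amplitude and power
($a \in [1, 50]$ cm$^{-1}$, $b \in [0, 4]$). The background term absorbs
residual flat absorption from chromophores not in the model and mainly
improves the separation of deoxy-hemoglobin from collagen, which have
similarly unstructured spectra at short wavelengths. Per-wavelength
amplitudes remain free and profiled.

Initialization is data-driven: per-wavelength standard fits, followed by
non-negative linear unmixing of the $\mu_a$ spectrum on the extinction
spectra and a log–log line fit of $\mu_s'$ restricted to 600–900 nm, the
range where the scattering estimate is reliable before absorption–scattering
coupling at long wavelengths distorts it. In practice this lands close
enough that the global refinement converges in a handful of iterations.

## Extinction spectra

The bundled extinction library is **synthetic**: smooth analytic forms
(sums of Gaussians and exponentials) shaped to each chromophore's canonical
near-infrared features — lipid peak at 930 nm, water peak at 970 nm,
deoxy-hemoglobin peak at 760 nm, the broad oxy-hemoglobin maximum near
915 nm, collagen structure near 910/1030 nm rising toward 1180 nm — at
magnitudes giving tissue-realistic $\mu_a$ for typical breast compositions.
Files are named `*_synthetic.csv` and carry their provenance in `#` header
lines. Published extinction compilations disagree, particularly for
collagen, and retrieved *absolute* concentrations always inherit that
choice; making the library explicitly synthetic and swappable decouples
verification of the fitting machinery from spectral provenance. Any
`chromophore_library()` (e.g. read from CSV compilations of measured data)
can be passed to every fitting function. Evaluation is by linear
interpolation only; extrapolation outside 600–1100 nm is an error, because
silently extrapolating sharply-structured spectra corrupts fits.

# Derived quantities

From a fitted composition: total hemoglobin $tHb = C_{HbO_2} + C_{Hb}$,
oxygen saturation $SO_2 = C_{HbO_2}/tHb$ (a fraction; undefined at
$tHb = 0$), and the two density surrogates

$$OI = \frac{[\text{water}]\,[\text{collagen}]\,b}{[\text{lipid}]},
\qquad CI = [\text{collagen}]\cdot b,$$

reported raw and unnormalized. OI is undefined at zero lipid (CI is still
returned).

# The synthetic cohort generator

The generator emulates the in vivo protocol: per subject, two breasts, a
sitting sequence (reflectance at 2 and 3 cm plus compressed cranio-caudal
transmittance) and a supine sequence (outer/lower/inner quadrants at 2 and
3 cm) — 18 acquisitions of 51 DTOFs each, with Poisson counting noise at a
target total count per DTOF (default $10^6$ reflectance, $10^5$
transmittance, emulating a 1 s integration).

## Composition model

Ground-truth compositions are drawn per (position, distance) directly from
truncated normals whose marginals are calibrated to the cohort-level
means/SDs of the supine 3 cm quadrant estimates (water 314/279/228, lipid
602/653/711, collagen 67.2/64.8/52.2 mg/cm³ outer/lower/inner, with their
SDs); 2 cm marginals are scaled by the overall 2 cm : 3 cm ratios, sitting
reflectance reuses the inner-quadrant marginals (sitting probes more
superficial, adipose-like tissue), and transmittance uses position-averaged
marginals. Truncation bounds are moment-matched numerically so the
*post*-truncation mean and SD equal the targets, and values are drawn
through a Gaussian copula so that correlation structure is imposed on the
latent scale while marginals stay exact.

The latent structure is a hierarchical factor model: a subject density
latent $z$ (loading $\alpha$, negative for lipid), a component-specific
subject latent ($\beta$), and a per-position residual ($\gamma$), with
$\alpha^2+\beta^2+\gamma^2 = 1$ and $(\alpha^2, \beta^2) = (0.6, 0.2)$ for
the three tissue constituents; a small jitter ($\tau = 0.15$) decorrelates
breasts and distances. This gives quadrant-to-quadrant correlations of
$\approx 0.78$ within a subject and left–right correlations near 0.98.
Transmittance loads on the subject-level latents only — the compressed
whole-breast measurement averages over position structure — which makes its
coupling to any single reflectance configuration $\approx 0.87$, the
strongest in the system, as befits a whole-organ average.

Quantities with no printed per-configuration values are plausible,
trend-faithful defaults, not reproductions: $tHb \sim N(15, 5)$ µM
truncated above 2, $SO_2 \sim N(0.75, 0.08)$ in $[0.4, 1]$,
$a \sim N(12, 3)$ cm$^{-1}$; compression reduces transmittance $tHb$ by
×0.7 (breast blood volume drops under compression) and raises transmittance
$a$ by ×1.2. The scattering power is tied to composition,
$b = 1.6 - 1.2\,[\text{lipid}]/1000 + \text{noise}$, clamped to
$[0.2, 1.6]$, reproducing the strong negative lipid–$b$ coupling of
adipose tissue; a $-0.12$ offset at 3 cm makes the net depth effect on $b$
negative (the lipid-mediated term alone would push it slightly positive,
contrary to what is observed in vivo). Compressed transmittance thickness
is drawn from an 11–37 mm range with a ×0.85 compression factor, mildly
anti-correlated with density (large breasts tend to be more adipose).
Dense subjects ($z > 1$) get strongly attenuated transmittance counts,
reproducing the transmittance SNR failures seen for the densest breasts.

## What passing tests do and do not show

The generator draws from the same forward model the fits invert, so
round-trip tests demonstrate the *correctness of the inversion machinery*
(and its noise behavior), not robustness to model mismatch. Real tissue is
heterogeneous (chest wall under the supine breast, skin, glandular
structure), real IRFs drift and have afterpulsing, real extinction spectra
differ from the synthetic library, and the diffusion approximation itself
degrades where $\mu_a$ approaches $\mu_s'$ (near the 970 nm water peak in
dense breasts). None of these effects is in the generator, by design
(homogeneous truth, modeled IRF, shared library); conclusions about real
data transfer only to the extent these idealizations hold.

# Statistics layer

Configuration comparisons operate on a tidy parameter table (one row per
subject × breast × configuration):

* `pearson_with_p()` — Pearson $r$ with the exact two-sided $t$-transform
  p-value on $n-2$ degrees of freedom (errors on constant input).
* `wilcoxon_signed_rank()` — matched-pairs signed-rank statistic on the
  nonzero differences with midranks for ties; for $n \le 25$ the two-sided
  p-value is exact over all $2^n$ sign assignments (computed by a sign-flip
  convolution on a half-integer lattice, identical to full enumeration and
  verified against a brute-force oracle in the tests); above, a normal
  approximation with tie-corrected variance, no continuity correction.
* `bonferroni_adjust()` — $\min(1, m\,p)$ with configurable family size;
  raw p-values are always reported alongside, since Bonferroni is
  conservative for correlated tests on small samples.
* `configuration_correlations()` — the 7 parameters × 4 reflectance
  configurations transmittance-validation table (breast-averaged, supine
  positions averaged; family $m = 28$ by default).
* `paired_config_comparison()` — Wilcoxon on breast-averaged subject pairs
  between two configurations (unpaired subjects dropped with a warning).
* `density_ranking()` — subjects ordered by OI in a reference column
  (default supine / right breast / outer quadrants / 3 cm), Spearman rank
  concordance of every (parameter, configuration) column against that
  ordering (Kendall available), lipid ranked with inverted polarity since
  it falls with density.

Breast-averaging precedes subject-level tests throughout (configurable
off).

# Problem sizes and reproducibility

The test-suite and acceptance computations use a 1024-channel, 25 ps (or
512-channel, 50 ps) time axis and, where a full spectrum is not needed, a
thinned 26-wavelength grid; these sizes keep each spectral fit around a
second while leaving fit-window, convolution and image-series behavior
fully exercised. Cohort-level checks use 200–1000 subjects at the truth
level (the statistics layer consumes parameter tables regardless of
whether they come from fits or from generator truth; the fit pipeline
itself is validated end-to-end on individual acquisitions). Every
stochastic step takes an explicit seed, generator records are bit-identical
under the same seed, and the fits themselves are deterministic given data.

# Known limitations

* Homogeneous-medium models only: no layered or heterogeneous inversion,
  no chest-wall correction, no Monte Carlo reference.
* No uncertainty quantification on fitted parameters beyond convergence
  diagnostics and the objective value.
* Absolute concentrations depend on the extinction library; with the
  bundled synthetic spectra they are internally consistent but not
  comparable across libraries.
* The session container is a plain-text bundle (JSON manifest +
  per-acquisition CSV), chosen for inspectability and portability; it is
  not space-efficient for very large studies.
* No timing-shift parameter is fitted by default ($t_0$ is fixed by the
  IRF); real measurements with drifting timing would need one.
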