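---
title: "Deconvoluting deep-UV resonance Raman spectra of cells"
author: "duvdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting deep-UV resonance Raman spectra of cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duvdecon)
```

## The model

Under deep-ultraviolet excitation (~248.6 nm) the Raman scattering of
aromatic rings is resonantly enhanced by up to four orders of magnitude,
so the spectrum of a bacterial cell is dominated by eight molecules: the
five nucleobases (adenine, cytosine, guanine, thymine, uracil) and the
three aromatic amino acids (phenylalanine, tryptophan, tyrosine). The
central model of this package treats a measured cellular spectrum
$I_{\mathrm{cell}}(\nu)$ as a scalable linear combination of
molecular-standard spectra,

$$
I_{\mathrm{fit}}(\nu) \;=\; a\,S_A(\nu) + c\,S_C(\nu) + g\,S_G(\nu) +
t\,S_T(\nu) + u\,S_U(\nu) + f\,S_{\mathrm{Phe}}(\nu) +
w\,S_{\mathrm{Trp}}(\nu) + y\,S_{\mathrm{Tyr}}(\nu),
$$

with only the non-negative scale coefficients varied, fitted by least
squares over the 800–1800 cm$^{-1}$ organic fingerprint window
(`unmix()`). Goodness of fit is the raw sum of squared residuals
($\chi^2$) with $\mathrm{dof} = n_{\mathrm{channels}} -
n_{\mathrm{components}}$. The scientific questions the machinery
addresses are

* **model complexity** — which tier of nucleic-acid standards (free
  nucleobases, nucleoside triphosphates, or single-stranded 10-mer
  oligomers) best describes a cellular spectrum, ranked by $\chi^2$
  (`compare_standard_sets()`); and
* **the unexplained residual** — the share of measured intensity that no
  linear combination of the standards accounts for
  (`residual_fraction()`), interpreted as the spectral signature of
  everything a mixture of parts is not: non-resonant cell mass and the
  structural organization of the molecules.

### Coefficients, uncertainties and correlations

With design matrix $X$ (one column per standard on the target's axis) the
non-negative solution is computed by a Lawson–Hanson active-set solver
written for this package; the unconstrained solution solves the normal
equations and is used for oracle comparisons. Coefficient standard errors
are $\sqrt{\hat\sigma^2 (X_F^\top X_F)^{-1}}$ over the free (unbound)
components with $\hat\sigma^2 = \chi^2/\mathrm{dof}$. When the target
carries a channelwise replicate standard deviation (after
`average_replicates()`), that measurement uncertainty is propagated
through the least-squares operator and combined with the fit error in
quadrature; both terms are retained separately in the fit object because
the appropriate combination rule is a modelling choice, not a datum.

The three aromatic amino acids share a dominant ring-stretching mode near
1600 cm$^{-1}$ and are nearly collinear at 25 cm$^{-1}$ resolution;
their individual coefficients are not separately interpretable.
`coefficient_correlations()` reports connected groups of components whose
estimate correlations exceed a threshold (default $|r| > 0.9$) together
with pooled coefficients, so such groups can be treated as a single
"total AAA" component.

Relative integrated intensities are reported as $c_i \int |S_i| / \int
|I_{\mathrm{target}}|$. Absolute integrals are used deliberately: after
linear-baseline subtraction the *signed* integral of a spectrum over the
fitted window is zero by construction (ordinary least squares with an
intercept forces zero-sum residuals), so signed normalization would be
degenerate. For the same reason the residual fraction is $\int
|\mathrm{residual}| / \int |I_{\mathrm{target}}|$.

## The preprocessing chain

`preprocess_spectra()` applies, in a fixed order, the standard processing
chain for replicate DUV Raman point spectra (e.g. 25 points of a 5×5
acquisition array):

1. **Cosmic-ray removal.** CCD spikes are single-channel, single-exposure
   events, so they are detected per wavenumber channel as outliers of the
   across-replicate distribution: robust $z$ (median/MAD) above 5. MAD is
   used because the spike itself must not inflate the scale estimate; 5
   is conservative at 25 replicates (measured false-positive rate
   ~0.05% of clean cells at 1% noise). Flagged values are replaced by
   the mean of the two spectrally adjacent channels of the same
   replicate.
2. **Laser-intensity correction.** Division by the normalized
   laser-power factor recorded per replicate.
3. **Wavenumber recalibration.** The atmospheric N$_2$ line is located
   within ±30 cm$^{-1}$ of 2330 cm$^{-1}$ on the replicate mean, its apex
   refined by a 3-point parabola (sub-channel accuracy without assuming a
   line shape), and the whole axis rigidly shifted so the apex lands at
   2330 cm$^{-1}$. This must precede cropping: the N$_2$ line lies far
   outside the fingerprint window, and the pipeline enforces that order.
4. **Atmospheric subtraction.** The N$_2$ (~2331) and O$_2$ (~1550
   cm$^{-1}$) lines are each fitted as a single pseudo-Voigt plus a local
   cubic offset within ±25 cm$^{-1}$ and the fitted peak (only) is
   subtracted. The peak center is searched within ±2 cm$^{-1}$ (the axis
   is already calibrated) and the width is pinned to the 25 cm$^{-1}$
   instrument resolution by default. These constraints matter: the O$_2$
   line sits between the cytosine mode at ~1523 and the amino-acid modes
   at ~1590–1610 cm$^{-1}$, and a fit with free center, free width and
   only a linear offset absorbs real signal, biasing the O$_2$ amplitude
   by tens of percent against generator truth; the constrained fit is
   accurate to a few percent. The fit is solved by profiled linear least
   squares over a small (center, width) grid, which is deterministic and
   cannot fail to converge on well-formed windows; degenerate windows are
   flagged and passed through unmodified.
5. **Fingerprint crop** to the closed interval [800, 1800] cm$^{-1}$.
6. **Linear baseline subtraction.** A single ordinary-least-squares line
   over the full cropped range, per replicate. No anchor points, no
   iterative or polynomial variants — one global line, which makes the
   operation idempotent and exactly linear. Output may be negative.
7. **Replicate averaging**, keeping the channelwise standard deviation
   for uncertainty propagation.
8. **Guanine normalization.** The spectrum is scaled so the guanine
   ~1460 cm$^{-1}$ peak is 1. "Peak intensity" is taken as the window
   maximum over [1440, 1480] cm$^{-1}$ (apex convention); the window mean
   is selectable (`guanine_stat = "mean"`) since the phrase "mean
   intensity of the guanine peak" admits both readings.

Standards entering a fit against a pipeline-processed target should be
passed through `preprocess_library()`, which applies the same crop and
baseline subtraction to every member. Because OLS is linear, a target
that is a linear combination of raw standards is exactly the same linear
combination of the processed standards — coefficients are unchanged and
the reconstruction identity is preserved — while omitting this step
biases the fit (the target's baseline-induced negative tails cannot be
reproduced by strictly positive standard peaks).

## Molecular standards

`builtin_peak_table()` encodes the dominant vibrational modes of the
eight standards in all three complexity tiers; `standard_library()`
synthesizes unit-height pseudo-Voigt lines (FWHM 25 cm$^{-1}$, the
instrument's true spectral resolution; $\eta = 0.5$) on any axis, or
wraps user-supplied measured spectra. The nucleobase→nucleotide
dominant-mode shifts implied by the table are +31 (adenine), +11
(cytosine), +34 (guanine) and +4 cm$^{-1}$ (thymine and uracil); note the
cytosine table difference is 11 while the accompanying prose of the
source table rounds it to ~12 — the package reports the table-derived
value. Secondary modes are not tabulated with measured heights anywhere
we can transcribe from; the optional `extended` table adds a few
text-described features (guanine composite 1540–1555, Phe/Tyr ring
~1000, cytosine shoulder ~1350, ssDNA-C ~1574 cm$^{-1}$) with placeholder
heights of 0.3 and is off by default to avoid inventing intensities.

Measured standards co-dissolved with a Na$_2$SO$_4$ internal standard are
anchored by `prepare_measured_standard()`: the ~981 cm$^{-1}$ sulfate
band is fitted, the spectrum scaled to unit sulfate area, and the band
subtracted, making spectra acquired at different laser powers
concentration-comparable.

## The composition budget

`cell_budget()` encodes the macromolecular composition of an average
exponentially growing *E. coli* cell (40-minute doubling, ~1000 fg wet
mass, 0.9 µm$^3$): per-class masses and the aromatic (DUV-resonant) unit
counts for protein, RNA, DNA and the metabolite pool. Two modes are
provided. In *transcribed* mode the tabulated per-unit counts are taken
as given, guaranteeing fidelity to the reference budget. In *derived*
mode counts are recomputed from first principles — $n = m/\bar m_{res}
\cdot N_A \cdot x_{arom}$ for macromolecules and $n = C V N_A$ for
metabolites — exercising the arithmetic. Mean residue masses (protein
108.2, RNA 340, DNA 327 Da) are calibrated so derived class totals match
the tabulated ones, since the underlying compilation does not print
residue masses.

Three internal inconsistencies of the reference budget are surfaced
rather than hidden:

* the tabulated metabolite subtotal (36.4 × 10⁶) exceeds the sum of its
  own rows (35.0 × 10⁶); `budget_summary()` reports both and a
  consistency flag;
* the metabolite counts imply a concentration-conversion volume of
  ~1.113 fL, not the nominal 0.9 µm$^3$; the implied volume is the
  default, the nominal one is selectable;
* the tabulated aromatic-amino-acid metabolite concentrations (2.00,
  1.33, 3.22 mM) are two orders of magnitude too large for their own
  tabulated counts (0.012, 0.0008, 0.019 × 10⁶ — tens of thousands of
  molecules per cell); derived mode therefore keeps the transcribed AAA
  counts. The protein-sequestered AAA share computes to ~99.95%, not
  the sometimes-quoted 99.4%, and is reported as computed.

`budget_summary()` reproduces the headline figures (≈224 million
DUV-resonant units per cell; 77% of nucleobases in nucleic acids; 71% /
29% nucleotide/amino-acid split), `mixture_recipe()` allocates a 1.00 mM
total across the 13 components of an artificial cell-mimic mixture in
proportion to residue counts, and `cells_per_spot()` computes the ~370
cells interrogated per 68 µm laser spot from the deposition geometry.

## The synthetic generator

No raw spectra are deposited with the source study, so `generate_target()`
provides seeded acquisitions with the statistical structure the analysis
assumes: 25 replicate points on a 400–2400 cm$^{-1}$ axis at 2 cm$^{-1}$
spacing; true spectra as weighted sums of tier standards; additive
Gaussian detector noise (default σ = 1% of the dominant peak);
Poisson-count cosmic-ray spikes (default 0.2 per replicate, amplitudes
10–100× the noise sd); a rigid axis miscalibration drawn in ±12
cm$^{-1}$; atmospheric N$_2$/O$_2$ lines (0.5× and 0.2× the dominant
peak); and a broad unmodeled background.

Two generator choices deserve explanation:

* **Sampling, not resampling.** A miscalibrated instrument samples the
  true spectrum at mislabelled wavenumbers; the generator therefore
  evaluates its analytic line model at the shifted positions rather than
  interpolating a gridded truth, so recalibration can in principle be
  exact and measured recovery errors reflect the pipeline, not the
  generator.
* **The background is the model's orthogonal complement.** The broad
  background starts as a Gaussian bump (center 1300, FWHM 600
  cm$^{-1}$ — featureless by design, as a residual with no defined peaks)
  and is projected orthogonal, over the fingerprint window, to the span
  of a linear baseline and the generating standards. Any component
  inside that span would be silently absorbed by the baseline stage or
  the fit coefficients — it is not operationally "unmodeled", and
  including it would make the configured background fraction
  unrecoverable by any analysis. The projected bump is scaled (by a
  short fixed-point iteration) so its integrated magnitude is the
  configured fraction of the processed target's integrated magnitude.
  With this construction the measured residual fraction tracks the
  configured fraction with slope ≈ 0.93 over {0, 0.08, 0.16, 0.24} and
  reproduces a cell-like 16% setting to within ±0.02.

The zero-background floor of the measured residual fraction is ~0.02:
about 0.016 of integrated |noise| of the 25-replicate mean plus a few
thousandths from the irreducible O$_2$-subtraction error. This floor is a
property of the stated noise conditions, not of the estimator.

What the generator does **not** emulate: Poisson shot noise (additive
Gaussian only — the analysis is noise-model agnostic), detector
nonlinearity, photodamage kinetics, wavelength-dependent instrument
response, hypochromism (available as optional per-component cross-section
multipliers via the weights, off by default), and real line-shape
variability between molecules. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the *pipeline*, not that
real cellular spectra satisfy the linear-mixture model.

## Numerical choices and degenerate inputs

* NNLS: Lawson–Hanson active set, tolerance scaled to the gradient at
  zero; exact ties in model ranking are broken by fewer nonzero
  components, then by simpler tier (nucleobase < dNTP < ssDNA).
* Rank-deficient libraries (duplicated components) produce a warning and
  an unreliable-correlation flag rather than an error; bound-at-zero
  coefficients report SE 0 and identity correlation rows.
* Spectra must have ≥ 2 channels, strictly increasing axes, finite
  intensities; baseline subtraction needs ≥ 3 channels; outlier
  detection needs ≥ 3 replicates; normalization requires a positive
  window maximum. All violations raise errors naming the condition.
* Rounding against printed reference figures uses round-half-away-from-
  zero at the printed precision, for determinism.
* Problem sizes in the shipped tests: 501-channel fingerprint fits, 25
  replicates, 10–20 seeds per statistical property — sizes chosen so the
  whole suite exercises every stage in seconds while keeping binomial
  acceptance margins comfortable.

## Limitations

The package fits whole spectra, not individual bands; it does not model
fluorescence backgrounds (DUV Raman is spectrally separated from
photoluminescence), vendor binary formats, or hyperspectral cubes.
$\chi^2$ values from different axes or normalizations are not comparable;
comparisons should use the same processed target. The composition budget
is a fixed-snapshot approximation for one growth condition and makes no
attempt at growth-rate dependence.
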