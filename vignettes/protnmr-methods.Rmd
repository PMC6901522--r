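---
title: "Methods and design of the protnmr analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the protnmr analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protnmr)
```

protnmr implements the quantitative workup that accompanies a solution-NMR
study of a small, monomeric protein: chemical shift perturbation (CSP)
mapping, pH titration pKa extraction, ^15^N relaxation and tumbling
analysis, ensemble precision statistics, and the supporting CD,
fluorescence, and sequence calculations. This vignette explains the models
behind each stage, the defaults and why they were chosen, and what the
synthetic-data generators do and do not establish about real data.

## Chemical shift perturbation analysis

An ^1^H,^15^N HSQC spectrum resolves one cross-peak per backbone amide.
When a condition changes (pH, ligand), each peak may move; the combined
perturbation used throughout the package is

$$\Delta\delta_{NH} = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N/5)^2},$$

where the nitrogen displacement is scaled by 1/5 to compensate for the
wider ^15^N ppm range. `csp_combine()` and `compute_csp()` implement this;
the quantity is non-negative and depends only on displacement magnitudes.

Spectra recorded under different conditions carry small global referencing
offsets. `align_to_reference()` removes them by subtracting, per spectrum,
the constant (H, N) offset that brings a designated pH-insensitive anchor
peak (for the protein that motivated this package, the W77 backbone amide)
onto its position in the first spectrum. Alignment is performed in ppm:
ppm offsets are field-independent, whereas Hz offsets are not, so this is
the convention that transfers across spectrometers.

### Binning by the Tukey fence

Perturbations are binned for structure coloring. The first bin's upper
bound is the Tukey outlier fence $Q_3 + 1.5\,\mathrm{IQR}$ computed from a
*reference* distribution of $\Delta\delta_{NH}$ between two replicate
spectra of nominally identical conditions: perturbations inside bin 1 are
indistinguishable from replicate noise. Subsequent bin boundaries are
multiples of the first bound; bins are right-closed, zero falls in bin 1,
and the last of the (default ten) bins is open above. Quartiles default to
the linear-interpolation convention (`stats::quantile` type 7) and the
type is configurable, because published CSP analyses rarely state which
quantile estimator they used. When no replicate pair exists, an explicit
first bound can be supplied; `compare_conditions()` defaults its
"unperturbed" threshold to 0.02 ppm, a conventional detectability level
for amide CSPs, since a fence is not always available.

`map_bins_to_structure()` writes the bin index into the B-factor column of
a copy of the first model (missing residues get the sentinel −1 and are
colored black on the gray-to-green ramp), a convention most molecular
graphics programs can color by directly.

## pH titration and pKa extraction

`build_titration_curves()` plots each residue's $\Delta\delta_{NH}$
relative to the lowest-pH spectrum, so every curve starts at zero.
Residues missing from the reference spectrum are excluded and reported;
per-residue curves use only the pH values where the residue is assigned.

Two estimators are provided:

* **Cubic inflection** (`fit_cubic_pka()`): an unweighted least-squares
  third-order polynomial in pH; the pKa is the inflection
  $-b/(3a)$ where the second derivative vanishes. Unweighted fitting is
  used because titration points have comparable precision. The estimate
  is invariant under positive scaling of the curve. If the leading
  coefficient is, after scale normalization, below $10^{-12}$, the fit is
  declared to have "no inflection" rather than returning a near-infinite
  pKa. Reported pKa values are conventionally read at one decimal.
* **Henderson–Hasselbalch** (`fit_hh_pka()`): nonlinear least squares of
  $\delta(pH) = \delta_{acid} + \Delta/(1 + 10^{pK_a - pH})$, the
  single-site fast-exchange titration model, Levenberg–Marquardt refined
  from an interpolated half-amplitude start.

Both report `in_range = FALSE` when the estimate lies outside the sampled
pH window; such values are estimates from incomplete titrations and are
printed as such. A caveat discovered during validation: for a curve whose
true pKa lies *below* the window (a nearly saturated titration), the
cubic's inflection is poorly determined and typically lands inside the
window, so the out-of-window diagnosis is reliable only from the HH fit.
The cubic method remains the primary estimator because it makes no
single-site assumption; the HH fit is the cross-check, and on noiseless
single-site data sampled over $[pK_a - 1, pK_a + 1.5]$ the two agree
within 0.2 pH units.

The recovery experiment shipped with the package (200 synthetic curves on
the experimental pH grid 5.5–8.0 with the additional 7.4 point, combined
amplitudes 0.1–0.5 ppm, noise 0.005 ppm per dimension) gives a median
absolute pKa error of about 0.02 for the HH fit and 0.05–0.1 for the
cubic — the cubic is the noisier estimator, which is why it is held only
to a 0.2 median bound.

## ^15^N relaxation and tumbling

T1 and T2 are obtained per residue by fitting peak intensity against
relaxation delay to $I(t) = I_0 e^{-t/T}$ (`fit_exponential()`). The fit
is initialized from a log-linear regression on positive intensities — a
deterministic, robust start — and refined by Levenberg–Marquardt with
tight tolerances, so noiseless decays are recovered to better than
$10^{-9}$ relative error on both the 10–210 ms and 80–2000 ms delay
schedules. A fitted time constant exceeding 100× the longest delay means
the data contain no decay information; the fit is flagged rather than
trusted. Peak heights (not volumes) are the assumed intensity measure.

The heteronuclear NOE is the per-residue ratio of intensity with and
without proton saturation; duplicate experiment pairs are combined by
averaging intensities before ratioing (averaging ratios would weight the
replicates differently when intensities differ; the convention is
configurable).

With T1 and T2 averaged over residues in regular secondary structure
(`average_over_mask()`; the mask is an input — no secondary-structure
computation is in scope), the rotational correlation time follows the
rigid-rotor closed form

$$\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6\,T_1/T_2 - 7},$$

valid when $6 T_1/T_2 \ge 7$ and for slow, isotropic tumbling.
$\nu_N$ defaults to 60.83 MHz, the ^15^N frequency at a 600 MHz proton
field; when relaxation data exist at several fields the frequency must
match the data that produced the averages, and the default is
flag-overridable. An apparent molecular mass comes from the empirical
linear calibration $\tau_c \approx 0.6\,\mathrm{ns/kDa} \times MW$ for
rigid monomers near room temperature; slope and intercept are exposed
because published calibrations differ by tens of percent, and the result
should be read as a monomer/oligomer discriminator, not a measurement.

## Ensemble statistics

`kabsch_superpose()` is a plain SVD implementation of least-squares
rigid-body superposition with the reflection guard (determinant forced to
+1). `ensemble_rmsd()` superposes each model onto model 1 — deposition
convention places the lowest-energy conformer first — over the selected
atoms of an ordered-region selection, and reports mean ± sd of the
per-model RMSDs. "Backbone" selects N, CA, C by default; the carbonyl O
is optional because "backbone heavy atoms" is used both ways in the
literature, and the difference on a well-ordered ensemble is within the
tolerance of any published value.

NOE distance restraints are classified by sequence separation: short
($|i-j| \le 1$), medium ($1 < |i-j| \le 5$), long ($|i-j| > 5$). Records
are counted exactly as deposited — no deduplication or ambiguity
expansion — because deposited totals are themselves raw record counts
more often than not; any other convention belongs to the caller.

`interface_residues()` enumerates residues of one structure with any
heavy atom within a cutoff (default 5 Å) of the other structure's heavy
atoms. Hydrogens are excluded: docked models frequently lack them, and
including them where present would make the criterion model-dependent.

## CD, fluorescence, and sequence utilities

CD scans are buffer-subtracted on an exactly matching grid (no
interpolation — a mismatched grid is an error, since silent resampling
changes band shapes), converted to molar ellipticity
$[\theta] = \theta_{mdeg}/(10\,c\,l)$ (the mean-residue variant divides
further by the peptide-bond count), and optionally smoothed with a
Savitzky–Golay filter (default window 11 points, order 3 — mild smoothing
that preserves CD band shapes; the filter reproduces any polynomial up to
the fit order exactly). Fluorescence emission maxima are located from a
least-squares polynomial (default degree 6) over the scan, taking the
best real critical point inside the window with a dense-grid fallback;
maxima on the window edge are flagged rather than reported as peaks. On
the 305–400 nm grid the degree-6 fit of a realistic emission band shows a
small systematic bias (≈0.3 nm for a Gaussian of width 25 nm centered at
338 nm), which is inherent to the polynomial-trendline method itself, so
recovered maxima are validated to ±0.5 nm (one grid step).

Sequence masses use the standard average/monoisotopic residue tables plus
one water, minus two hydrogens per disulfide; extinction coefficients
follow the $5500\,n_{Trp} + 1490\,n_{Tyr} + 125\,n_{cystine}$ rule, and
Beer's law inverts absorbance to concentration.

## Synthetic data: what it shows and what it does not

Every stage has a seeded generator emitting data plus machine-readable
ground truth: Henderson–Hasselbalch shift trajectories with flat
(pH-insensitive) residues and additive per-dimension noise (default
0.005 ppm, about digital resolution); single-exponential decays with
multiplicative noise; Gaussian-jittered coordinate ensembles whose
pre-superposition RMSD expectation is $\sigma\sqrt{3}$; restraint sets
with constructed class counts; and Gaussian emission bands. Generators
are pure functions of (scenario, seed) and leave the caller's RNG state
untouched.

These emulate the *statistical* structure each estimator assumes, which
is exactly what closed-loop recovery tests need. They deliberately do not
model peak overlap or crossing trajectories, chemical-exchange
broadening, multi-site coupled titrations, anisotropic tumbling, or
correlated coordinate variation along a chain. Passing recovery tests
therefore demonstrates estimator correctness under the stated models, not
robustness to those phenomena — which is why deposited-data validation
hooks exist in the test suite for users with network access.

## Problem sizes and numerical choices

The shipped experiments use 200 titration curves, 100 noisy decays, a
20-model/500-atom ensemble, and a 24,624-point Euler-angle grid as the
brute-force superposition oracle; all were chosen as the smallest sizes
at which the Monte-Carlo summaries are stable to well within the asserted
bounds. Ties and degeneracies are handled by explicit errors rather than
silent conventions: empty peak lists, duplicate labels, non-monotone
wavelength grids, all-zero reference distributions (the fence would be
zero), flat titration curves, all-equal intensities, collinear point
sets, and regions selecting no atoms all fail loudly with the offending
token named.

## Pipeline and reproducibility

`run_pipeline()` executes stage subsets (`simulate`, `csp`, `titrate`,
`relax`, `ensemble`, `spectra`) from a single validated configuration,
writing TSV/JSON outputs and a `report.json` that embeds the
configuration; re-running with the same configuration and seed reproduces
the outputs byte for byte. A thin command-line wrapper lives at
`inst/scripts/protnmr-pipeline.R`. Logs go to stderr, data to files, and
nothing in the pipeline touches the network.
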