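---
title: "From binding-site normal modes to SERS biomarker bands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binding-site normal modes to SERS biomarker bands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibraman)
```

## The model

`vibraman` connects two descriptions of a drug–receptor binding site.
On the theoretical side, a harmonic vibrational analysis of the bound
complex (drug or active metabolite plus the contacting arginine residue)
yields normal modes: wavenumbers $\nu_i$ and Raman scattering activities
$A_i$. On the experimental side, surface-enhanced Raman (SERS) spectra of
platelets are measured on an instrument grid. The package's job is to
make these comparable and to nominate the modes that could serve as
spectral biomarkers of drug binding.

Three transformations take a mode table to a simulated spectrum:

**Wavenumber scaling.** Harmonic calculations overestimate observed
frequencies, increasingly so at higher wavenumber. The empirical linear
correction on the ratio,
$$\nu_{\mathrm{exp}}/\nu_{\mathrm{calc}} = a\,\nu_{\mathrm{calc}} + b,$$
is applied as $\nu \mapsto \nu(a\nu + b)$. The defaults
$a = -8.3526\times 10^{-6}$ cm and $b = 0.98134$ are the coefficients for
B3LYP/6-31G(d) harmonic frequencies. With these values the map is
strictly increasing on $(0, 4000]$ cm$^{-1}$ (its derivative $2a\nu + b$
stays positive), so scaling never reorders modes — a property the test
suite asserts by dense sampling.

**Intensity conversion.** A scattering activity is not an observed peak
height; the standard conversion

$$I_i = \frac{f\,(\nu_0-\nu_i)^4\,A_i}
             {\nu_i\left[1 - e^{-h c \nu_i / k T}\right]}$$

weights each mode by the fourth power of the scattered frequency and by
the thermal population factor. Defaults: $\nu_0 = 10^7/532 \approx
18797$ cm$^{-1}$ (the 532 nm excitation line used for the platelet
measurements), $T = 298.15$ K (spectra are acquired from droplets dried
at room temperature; the temperature is configurable because it is not
part of the calculation itself), and $hc/k = 1.438776877$ cm·K (CODATA).
$f$ is a common factor across all modes; by default it is chosen after
synthesis so the spectrum maximum is exactly 100, matching the display
convention used for the normalized experimental spectra. The
implementation is checked against an independent scalar evaluation of
the same formula to 12 significant digits over $10^4$ random parameter
draws, and the $T \to 0$ limit (thermal factor $\to 1$) is asserted.

**Lorentzian broadening.** Each mode contributes a height-normalised
Lorentzian of 5 cm$^{-1}$ full width at half maximum:
$$S(\nu) = \sum_i I_i \frac{\gamma^2}{(\nu-\nu_i)^2+\gamma^2},
\qquad \gamma = \mathrm{FWHM}/2 ,$$
so a lone mode evaluated at its own center equals $I_i$ exactly and
equals $I_i/2$ at $\pm 2.5$ cm$^{-1}$ — identities the tests assert
exactly. Height normalisation (rather than unit area) keeps tabulated
strengths directly comparable to stem heights in overlay figures. The
default evaluation grid is 400–1800 cm$^{-1}$ at 0.5 cm$^{-1}$, fine
enough to resolve the 5 cm$^{-1}$ width; the experimental comparison grid
is coarser (below).

### Two synthesis modes

The packaged reference tables print a "Raman strength" per mode without
stating its units, and their wavenumbers are tabulated after frequency
adjustment. `fixture_spectrum()` therefore treats those strengths as
ready peak heights and applies no re-scaling and no conversion — the
faithful way to redraw the published stem plots. `synthesize_spectrum()`
is the full model (scaling + conversion + broadening) for genuine
frequency-job output, where $A_i$ really is an activity in
Å$^4$ amu$^{-1}$. Keeping the two entry points separate sidesteps the
units ambiguity instead of guessing.

One consequence worth knowing: under the full conversion the
$(\nu_0-\nu)^4/\nu$ weighting boosts low-wavenumber modes, so the
spectrum maximum need not sit at the largest $A_i$. For the
clopidogrel-site table the strongest tabulated strength is at
1303 cm$^{-1}$, and `fixture_spectrum()` peaks there; the full conversion
peaks near 411 cm$^{-1}$. Both behaviours are correct for what each
function models.

## Experimental preprocessing

The instrument exports two-column text at arbitrary sampling.
Preprocessing mirrors the fixed-grid treatment used for the platelet
spectra:

* **Binning** (`bin_spectrum()`): the analysis grid is 400 to
  1800 cm$^{-1}$ in 5 cm$^{-1}$ steps — 281 bin centers. "Grid cells" are
  interpreted as nearest-center assignment with a half-step catchment; a
  sample exactly halfway between two centers goes to the lower one. This
  is symmetric, deterministic, and matches a 5 cm$^{-1}$ cell picture.
  Every in-range sample lands in exactly one bin (conservation is
  asserted); a bin's value is the plain mean of its samples; empty bins
  stay missing — no interpolation, so no invented signal.
* **Replicate averaging** (`average_replicates()`): arithmetic per-bin
  mean, emulating spectra averaged over repeated acquisitions from
  different spots of a droplet. No outlier rejection, because the
  procedure being reproduced states averaging only. A bin missing in
  some replicates is averaged over the ones that have it.
* **Normalization** (`normalize_to_100()`): present intensities are
  scaled so the maximum is exactly 100; idempotent and ratio-preserving.
  Whether averaging happens before or after normalization is not pinned
  down by the source procedure; the default is average-then-normalize
  (replicates from one sample share an intensity scale, so averaging raw
  values loses nothing), and `run_config(preprocess.order =
  "normalize_then_average")` flips it.

## Fragment attribution and biomarker selection

The biomarker hypothesis is that modes whose motion spans *both* the
drug/metabolite and the receptor-side arginine — *joint* modes — are
where binding shows up spectroscopically. Reference tables record the
attribution directly (a molecule name, or a dash for joint modes), and
`attribution_from_table()` passes those labels through verbatim; when
both tabulated and displacement-derived labels exist, the tabulated ones
win, to stay faithful to the published assignments.

For raw frequency-job output with displacement vectors,
`attribute_mode()` quantifies participation with the standard
mass-weighted squared displacement measure,
$$p_F = \frac{\sum_{i \in F} m_i \lVert d_i\rVert^2}
             {\sum_i m_i \lVert d_i\rVert^2},$$
labelling a mode with fragment $F$ when $p_F \ge \theta$ and *joint*
otherwise. The published tables do not state the rule that produced
their dashes, so this is a declared surrogate, not a reconstruction; the
threshold default $\theta = 0.8$ is exposed because of exactly that
uncertainty. Fractions sum to one and are invariant under a common
rescaling of the displacements (tested properties).

`select_biomarkers()` applies the default rule — joint modes inside the
fingerprint window, ordered by wavenumber. On the clopidogrel-site table
this reproduces the curated 13-mode listing exactly. The curated aspirin
listing deviates from the raw joint rule in four places (two
single-fragment modes included, two joint modes omitted) with no stated
rule behind the deviation; the package encodes that as *data* — an
explicit include/exclude override shipped as a fixture — rather than
inventing logic that happens to fit.

## Band detection and matching

`detect_bands()` reports bins that are strict local maxima over their
nearest present neighbours with **topographic prominence** of at least a
fraction (default 0.05) of the global maximum — prominence being the
peak's height above the higher of the two valley minima reached before a
taller bin on either side. Published band markers are placed by eye; a
low deterministic prominence threshold replaces that judgment, and
prominence (rather than absolute height) keeps noise ripples riding on a
baseline or on a band's shoulder from flooding the band list.

`match_modes_to_bands()` pairs theoretical modes with experimental bands
greedily by globally smallest distance, discarding pairs beyond a
tolerance (default 10 cm$^{-1}$: the reference comparison pairs bands
4 cm$^{-1}$ apart and draws no pair beyond about 10), with ties broken
toward the lower wavenumber so results are deterministic. Shifts are
signed as experimental minus theoretical: the binding-site mode
calculated at 997 cm$^{-1}$ matched to the 1001 cm$^{-1}$ phenylalanine
band reads as $+4$ cm$^{-1}$. Matching is invariant under a common
wavenumber offset of both sets (tested).

## The synthetic-data generator

`generate_mode_table()` and `generate_sers_spectrum()` produce inputs
with the statistical structure the analysis assumes, so the whole chain
is testable without electronic-structure output or instrument exports.
Defaults emulate the reference tables: 120 modes over 400–1800
cm$^{-1}$, activities log-uniform on $[0.01, 1.5]$ (the dynamic range of
the printed strengths, 0.00–1.52), joint fraction 0.11 (13 of the 120
clopidogrel-site modes are joint), 5 cm$^{-1}$ Lorentzians. Spectra add
a low-order polynomial baseline (default a gentle quadratic rising to
roughly 15% of a typical peak height across the window — the simplest
shape consistent with smooth SERS backgrounds) and additive Gaussian
noise scaled to the noiseless maximum, sampled at 1 cm$^{-1}$ as an
instrument would provide. An `injected_shift` rigidly translates every
peak before binning, giving a known truth for recovery experiments.
Noise can dip below zero where the signal is near zero, as
baseline-corrected instrument exports do; the pipeline does not clip it.

What the generator does *not* emulate: mode-density clustering,
heteroscedastic shot noise, cosmic-ray spikes, wavenumber-calibration
drift, and plasmonic enhancement physics. Passing the synthetic
end-to-end tests therefore demonstrates correctness of the chain's
arithmetic and bookkeeping under controlled conditions, not robustness
to every artefact of real SERS data.

All draws run under a caller-isolated RNG seeded from the spec
(`seed` for the table, `seed + 1` for the spectrum noise), so results
are bit-reproducible and the caller's RNG stream is untouched.

### Shift recovery

The end-to-end recovery experiment — generate, bin, normalize, detect,
match, take the median shift over matches — uses 12 modes over
450–1750 cm$^{-1}$ with activities in $[0.5, 1.5]$: few enough modes
that peaks are typically resolved on a 5 cm$^{-1}$ grid with 5 cm$^{-1}$
FWHM, strong enough that every peak clears the detection threshold, and
the median makes the estimate robust to the occasional close pair. Under
2% noise, injected shifts of 2, 4 and 6 cm$^{-1}$ are recovered within
one grid step on every one of 50 seeds (the acceptance suite runs
exactly this), and without noise within half a step.

## Numerical choices and degenerate inputs

* Ties: binning ties go to the lower center; matching ties to the lower
  wavenumber; both are exact rules, not float accidents.
* Empty mode tables synthesize an all-zero spectrum with a warning
  rather than an error, so pipelines degrade visibly but gracefully.
* Duplicate wavenumbers in raw spectra are averaged (tolerant ingestion
  of instrument exports); duplicate mode indices are an error.
* `normalize_to_100()` refuses all-missing or non-positive spectra.
* The frequency-log parser targets the conventional
  three-modes-per-block text layout only; one format, tested
  bit-for-bit against a writer of the same layout, rather than a
  half-supported zoo of formats.
* Mode-table TSV accepts "-"/"–" and molecule-name synonyms for
  fragment labels on input and always writes the canonical spelling, so
  write-then-read is the identity.

## Pipeline determinism

`run_pipeline()` validates the entire configuration before any stage
runs, names the failing stage in its error, and emits no timestamps:
identical configuration and inputs give byte-identical outputs,
manifest included. The manifest echoes the full configuration tree,
input and output checksums, the seed and the stage list, so any output
directory is auditable after the fact.

## Problem sizes

The test and acceptance workloads are sized for quick iteration:
$10^4$ random draws for the conversion-oracle sweep, 100 seeds for the
binomial property of the generator, 50 seeds per injected shift for
recovery, full 120- and 86-mode reference tables everywhere they are
the subject. The whole suite runs in well under a minute on one core.

## Known limitations

* The published overlay figures are not numerically reproducible
  because neither the raw unscaled frequencies nor the experimental
  spectra are deposited; the package instead pins down every stated
  transformation and checks the table-driven results exactly.
* The joint/single attribution rule for tabulated modes is the source
  tables' own; the displacement-based rule here is a stated surrogate.
* No statistical testing of intensity differences between therapy
  groups is provided (none is defined for this workflow).
* Baseline subtraction, cosmic-ray removal and wavenumber calibration
  are instrument-side concerns, out of scope by design.
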