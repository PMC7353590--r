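---
title: "Quantifying intact-protein survival across digestion by PRM: models and methods"
author: "prmQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intact-protein survival across digestion by PRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmQuant)
```

## The measurement problem

An orally fed therapeutic protein (the reference workflow uses the
monoclonal antibody palivizumab spiked into human milk and fed to
infants) is useful in the gut only while it is intact. To measure how
much of it survives into the stomach, the upper small intestine and the
stool, three things have to be disentangled:

1. **How much target protein is in each sample.** The intact protein is
   trypsin-digested and a *surrogate peptide* — a tryptic peptide unique
   to the target among all background proteins — is quantified by
   parallel reaction monitoring (PRM): the peptide's precursor ion is
   isolated and all of its fragment ions are recorded at high
   resolution, with the summed fragment peak areas as the response.
2. **How much of the measured loss is analytical.** A stable-isotope-
   labeled (SIS) version of the surrogate peptide is spiked at a known
   amount after trypsin digestion; its measured recovery rescales the
   target concentration.
3. **How much of the measured loss is dilution.** Digestive secretions
   dilute, and water absorption concentrates, everything in the lumen. A
   co-fed non-digestible, non-absorbable marker — a single polyethylene
   glycol species, the 28-mer (PEG-28) — moves with the meal; the ratio
   of its feed concentration to its concentration in a sample is that
   sample's *dilution factor*.

Percent survival in a compartment is then

$$
\mathrm{survival} \,(\%) \;=\;
100 \times \frac{c_\text{target} \cdot
  \frac{c^{\mathrm{exp}}_\text{SIS}}{c^{\mathrm{meas}}_\text{SIS}}
  \cdot \frac{c^{\mathrm{feed}}_\text{PEG}}{c^{\mathrm{sample}}_\text{PEG}}}
  {c^{\mathrm{feed}}_\text{target}} .
$$

Both corrections are multiplicative, so their order does not change the
result; the package applies the SIS correction first (it is an
analytical, per-sample effect) and the dilution factor second (a
physiological one), which is also how the per-sample report columns are
laid out.

## Mass scale and transition lists

All m/z arithmetic is monoisotopic. Residue masses, water, the proton
and the ethylene-oxide repeat unit are carried at 8 decimal places;
6-decimal tables are *not* sufficient, because a rounding error of
3e-7 Da on the ethylene-oxide unit, multiplied by 14 repeat units, is
enough to flip the fourth decimal of a high-DP PEG fragment. Charging
uses the proton mass (1.00727647 Da), not the hydrogen atom mass.

* Peptide mass: sum of residue masses + water + modification deltas.
  The SIS label (`label_13C6_15N2_K`, +8.014199 Da) is an ordinary
  modification attached to the C-terminal lysine.
* y-ions only: tryptic peptides fragmented by HCD yield predominantly
  the y series, and only y-ions carry the C-terminal label — which is
  what makes light and heavy transitions separable (a constant
  +8.0142 m/z shift at z = 1). b-ions are deliberately not implemented.
* PEG: an oligomer of $n$ ethylene-oxide units is
  $(n \cdot 44.02621475 + 18.01056468 + z \cdot 1.00727647)/z$; the same
  formula covers the intact 28-mer precursor (z = 3) and the CID
  fragment ladder (DP 7–17 at z = 1, spaced one EO unit apart). DP 9 is
  excluded from the default panel, mirroring the reference acquisition.
* Reported m/z values round half-up at 4 decimals (3 for the z = 3 PEG
  precursor), matching how transition tables are conventionally printed.
  Two printed sources disagree on the PEG-28 precursor (417.933 vs
  417.922); the computed value is 417.9221, so 417.933 is treated as a
  typo.

```{r transitions}
buildTransitions(defaultStudyConfig())
```

## Surrogate-peptide selection

`trypticDigest()` cuts after every K and R (fully specific, up to two
missed cleavages by default). The commonly used keep-K|P/R|P-intact
variant exists as an explicit option but is **off** by default, because
the reference search settings name only "C-terminal R and K".

`uniquenessCheck()` is substring containment against a protein database
(the behavior of the public peptide-uniqueness checkers), not
shared-tryptic-peptide identity. Peptides shorter than 6 residues are
ineligible (`"too_short"`), never unique. Treating isoleucine and
leucine as equivalent (they are isobaric) is an explicit flag, off by
default, since the reference classification calls the I/L-containing
surrogate unique under the checker's defaults. The bundled database
(`inst/extdata/synthetic_uniqueness_db.fasta`) uses *synthetic* carrier
sequences for the three known non-unique peptides — the real accession
sequences are not redistributable here — so the published uniqueness
calls reproduce without network access.

`selectSurrogate()` applies four hard criteria — unique, unmodified, no
missed cleavage, detected at every standard concentration — and ranks
passers by mean chromatographic peak abundance. Any modification
disqualifies (a variable modification may not occur on every copy of
the peptide, so a modified surrogate undercounts). The tie-break
(shorter sequence, then lexicographic) is this package's own
deterministic choice; the reference study never needed one, since a
single candidate cleared all criteria.

## Synthetic signal model

Real vendor raw files for this workflow are not publicly available, so
the package ships a generator that emulates the *structure* of the
signal rather than the instrument physics:

* Gaussian elution peaks, default sd 0.05 min; peptides centered at
  14.4 min, PEG at 18.5 min (the two cited retention times differ by
  0.4 min between text and figure in the reference; the default is one
  of them and is configurable — nothing downstream depends on it).
* Peptide response linear in concentration (default 1000 area units per
  ng/µL); PEG response saturating, modeled directly as
  $a \ln c + b$ (default a = 300, b = 2000) — a log-linear description
  of the observed calibration behavior, not a mechanistic ionization
  model.
* Per-transition responses split by fragment factors summing to 1
  (uniform by default).
* Additive Gaussian noise per trace point, clamped at zero intensity;
  the default is 0 (deterministic), and tests opt into noise relative
  to the weakest analyte's peak height. The reference data cannot
  constrain a noise model, so the default favors test power over
  realism.
* One study-level seed; per-run seeds derive from it as
  `(seed * 1009 + runIndex) mod (2^31 - 1)`, so any single run is
  reproducible in isolation.

The generator's defaults *are* the study conditions used throughout the
tests: four subjects; feed at 18 ng/µL target, 0.1 ng/µL PEG,
0.5 ng/µL SIS; standard series 0.5–20 ng/µL (target), 0.01–1 (SIS),
0.005–1 (PEG); four replicate injections per sample; survival and
dilution patterns shaped like the published study (high gastric
survival, ~1/3 intestinal, near-zero stool with one non-detect, stool
dilution factors straddling 1). What passing end-to-end tests show is
that the *computational chain* is faithful — integration, calibration,
inversion and normalization undo the generative model exactly — not
that the method is robust to matrix effects, retention drift, chimeric
spectra or ion suppression, none of which are simulated.

## Quantitation choices

* **Integration**: trapezoidal area inside a per-analyte window
  (default ±0.3 min around the configured retention time — the
  reference delegates this to vendor software without stating a
  window). The default baseline is a straight line through the median
  of up to five points flanking each window edge; `"none"` is available
  and is what the synthetic tests use. Negative corrected areas clip to
  zero with a flag.
* **Calibration**: unweighted least squares (no weighting is stated in
  the reference), response = summed area over the analyte's full
  transition set. Linear for peptides, $a\ln c + b$ for PEG. Inversion
  outside the fitted response range is performed but flagged as
  extrapolation.
* **LOD/LOQ**: blank mean + 3 (resp. 10) blank standard deviations, in
  concentration units, sample sd throughout (n − 1). The published
  LOD/LOQ values cannot be recomputed — the blank replicate responses
  were never published — so the formulas are exercised on synthetic
  blanks instead.
* **Non-detects**: a sample whose mean target concentration falls below
  the target LOD (or below zero when no LOD is available) is reported
  as N/D, enters the study summary as 0% survival, and is flagged
  distinctly — consistent with how the published stool mean treats its
  non-detect.
* **Replication**: per-sample error is sd/√(injections); study-level SE
  is sd/√(subjects). The paired feed-vs-compartment t-test is run on
  subjects (n = 4 in the default design); with so few subjects it is
  less significant than the published asterisks, which may reflect
  injections as the unit of replication — the package reports the exact
  two-tailed p and leaves the display thresholds to the caller.

## Numerical behavior

On a noise-free synthetic study the pipeline returns the generating
survival fractions to about 1e-8 percentage points: trapezoidal
quadrature of a Gaussian is not exact, but the quadrature constant is
common to standards and samples and cancels through the calibration
fit. This is why the end-to-end identity test asserts 1e-6 relative
rather than literal equality. With per-point noise at 1% of the weakest
peak apex, survival is recovered well within 3 percentage points.

Default problem sizes (a 20-min run sampled at 0.005 min, 22
transitions, 6 standards + 3 blanks + 16 samples × 4 injections) were
chosen so a full study simulates, calibrates and reports in well under
a minute; the pipeline tests use a coarser grid (0.02 min, 2
injections) since the chain's correctness does not depend on grid
density.

Coordinates throughout are 1-based closed intervals
(`substr(parent, start, end) == sequence`), the R and Bioconductor
convention.

## Known limitations

* Only y-ions and a single fragmentation mode per analyte class; no
  neutral losses, no isotope envelopes, no a/b/c/x/z ions.
* Uniqueness is exact substring matching; homologous-but-not-identical
  background peptides (the realistic near-miss case) are not modeled.
* The PEG log-linear response is empirical; extrapolating it below the
  lowest standard is flagged but will be increasingly wrong physically.
* The generator's global recovery behavior is a single multiplicative
  knob (the SIS spike); matrix-dependent suppression is out of scope.
* ELISA cross-validation and four-parameter logistic fitting are out of
  scope; so is reading vendor raw files (the chromatogram TSV and the
  minimal spectrum-list XML are the interchange formats).
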