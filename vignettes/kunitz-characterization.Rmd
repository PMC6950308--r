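---
title: "Characterizing Kunitz-type protease inhibitors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing Kunitz-type protease inhibitors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KunitzChar)
```

KunitzChar implements the computational workflow used to characterize small
Kunitz-domain serine protease inhibitors, using the two inhibitors isolated
from the sea anemone *Actinia tenebrosa* (ATPI-I and ATPI-II) as the
reference system. This vignette is the package's account of the underlying
models, the parameters that matter, and the design decisions taken where
the methods literature leaves choices open.

## 1. Mass chemistry and in silico digestion

All mass arithmetic is built on IUPAC residue masses. A peptide's neutral
monoisotopic mass is the sum of its residue masses plus one water
(18.01056 Da) plus fixed-modification deltas; carbamidomethylation of
cysteine (iodoacetamide alkylation after disulfide reduction) adds
57.02146 Da per Cys. Charged-ion m/z uses the proton mass 1.00728 Da as the
charge carrier:

$$ m/z = \frac{M + z \cdot 1.00728}{z} $$

Using the proton mass rather than atomic hydrogen (1.00794) is required to
reproduce published 2-decimal precursor values; the difference is visible
at the second decimal for multiply charged ions. Printed comparisons use
half-up rounding (`roundHalfUp()`) at the presentation layer only; all
internal arithmetic is full precision.

Intact-chain masses are average (isotope-averaged) masses of the reduced
linear chain; each disulfide bond, when modeled, removes two hydrogens
(−2 × 1.008 Da). The 60-residue ATPI-I chain assembled from its tryptic
peptides has an average mass of
`r roundHalfUp(chainAverageMass(atpiSequences()[["ATPI_I"]]))` Da.

Tryptic digestion cleaves C-terminal to Lys/Arg except before Pro.
`trypticDigest()` enumerates all products up to a missed-cleavage cap
(default 2, since the published peptide table contains one-missed
products), with 1-based inclusive coordinates throughout. The zero-missed
products partition the parent exactly, and every k-missed product is the
concatenation of k+1 zero-missed products — both properties are tested
against a brute-force cut-site enumerator.

## 2. Fragment ions, spectrum annotation and sequence tags

CID product ions follow the standard series conventions: for prefix sums
$P(i)$ and suffix sums $S(i)$ of (modified) residue masses,
$b_i = (P(i) + z p)/z$, $y_i = (S(i) + \mathrm{H_2O} + z p)/z$,
$a_i = b_i - \mathrm{CO}/z$, and z ions use the z-dot radical convention
$z_i = y_i - \mathrm{NH_3}/z + \mathrm{H}/z$. The identity
$b_i + y_{n-i} = M + 2p$ for singly charged fragments is enforced as a
property test at every split point. The a- and z-series are annotation-only
and never drive tag deduction.

Spectrum annotation (`annotateSpectrum()`) assigns theoretical ions to
observed peaks greedily in order of increasing absolute m/z error, each
peak and ion used at most once; this equals an exhaustive assignment oracle
on small spectra.

De novo sequence tags are read from same-series peak spacings.
`deduceTags()` builds a directed gap graph over the peaks: an edge connects
two peaks whose spacing matches a residue mass (fixed modifications
included) within tolerance, and every maximal path of at least
`minTagLen` edges becomes a tag. Each tag position is an ambiguity class:
Ile/Leu always coincide; Lys/Gln merge once the tolerance covers their
0.03638 Da difference (so at the 0.3 Th default they merge, at 0.02 Th
they do not). Path enumeration is capped (200 paths per spectrum) because
dense spectra can alias two-residue spacings to single residues (e.g.
Gly+Gly vs Asn differ by 10 µDa), which legitimately multiplies maximal
paths. A tag stored in ascending-m/z order reads N→C if it came from a
b-ladder and C→N from a y-ladder; since the series is unknown at search
time, `searchTags()` scans both readings.

Defaults follow the instrument class of the source data (unit-resolution
QTRAP): fragment/spacing tolerance 0.3 Th, precursor tolerance 0.5 Th,
both configurable.

## 3. Proteogenomic verification and reconstruction

Candidate proteins come from six-frame translation of transcriptome
contigs (`candidateProteins()`), split at stop codons; segments shorter
than 20 residues or containing ambiguous translations are discarded before
verification. `verifyCandidate()` digests a candidate in silico and
matches each observed precursor to at most one theoretical peptide in m/z
space, ties broken by smallest |Δm/z| then fewer missed cleavages.
Coverage is the union of matched spans over the candidate length.
`reconstructSequence()` assembles the maximal contiguous covered region,
errors on conflicting residues (naming the position), flags unresolved
positions — for ATPI-II the published peptides leave positions 1–2
unresolved — and reports the assembly's average mass for comparison with
the intact-mass measurement.

One published ATPI-I row (`CRGYFPRYYYNTEAGK`, +4) is printed with observed
and calculated m/z values about 2 Th below the standard
carbamidomethyl-monoisotopic computation that reproduces every other row;
the package treats it as a printing error, flags it
(`atpiPeptideTable()$reproducible`) and excludes it from mass-verification
targets. A consequence is that full 1.0 coverage of ATPI-I from the
printed precursor list alone is not achievable at the 0.5 Th tolerance:
the row's observed value is 1.67 Th from the correct theoretical m/z, so
verification recovers 6 of 7 precursors (coverage 53/60). The chain
itself is not in doubt — its assembled average mass reproduces the
published 6719.43 Da exactly.

## 4. Tight-binding kinetics

When inhibitor and enzyme concentrations are comparable, free-inhibitor
depletion makes the classical isotherm invalid; the Morrison quadratic
applies instead:

$$ \frac{v}{v_0} = 1 - \frac{(E + I + K_i^{app}) -
  \sqrt{(E + I + K_i^{app})^2 - 4 E I}}{2E} $$

`fitKi()` fits $K_i^{app}$ by nonlinear least squares with the enzyme
concentration fixed (active-site titration is assumed), parameterized in
$\log K_i^{app}$ so positivity is structural; the SE is transported back
by the delta method, and $K_i = K_i^{app}/(1 + S/K_m)$ applies the
competitive correction. Residuals are unweighted (no weighting scheme is
published for the reference assays); the initial guess is the inhibitor
concentration at half-maximal observed inhibition. Zero-residual
(noiseless) fits are handled via `nls.control(scaleOffset = 1)`.

Because the raw assay tables behind the published Ki values are not
available, those values (0.05–94 nM, enzyme at the 0.5–3 nM scale) serve
as simulation truths for recovery tests, not as reproduction targets:
noiseless recovery within 1%, and at 5% multiplicative noise over 200
replicates the median relative error stays under 10% with ±2SE interval
coverage near 95%.

## 5. Conservation scoring and stability correlation

Column conservation uses an AMAS-style physico-chemical score on a 0–11
scale: a gap-free identical column scores 11; otherwise the score is the
number of the ten properties (hydrophobic, positive, negative, polar,
charged, small, tiny, aliphatic, aromatic, proline) whose membership is
uniform across the column — all residues have it or all lack it — capped
at 10. Gaps break every property, so gapped columns score 0 (a documented
convention; the scoring function takes the property table as an argument
so a gap-excluding or alternative classification can be swapped in). The
memberships are the Taylor/Zvelebil-style sets used by the AMAS lineage;
the exact table used by any given tool version is not published, so
results should be reported alongside the table (`kunitzPropertyTable()`).

Per-residue alanine-scan ΔΔG values (kcal/mol, from an external energy
function) are joined to the alignment by mapping each homolog's ungapped
positions to columns and averaging per column over the homologs with a
value there; columns with no observation are missing, never zero. The
conservation–stability relationship is summarized by OLS of mean ΔΔG on
score and the Pearson r of the pairs, computed per column (not on bins).

The ΔΔG generator draws
$\Delta\Delta G = b_0 + b_1 \cdot \mathrm{score} + \varepsilon$ per
homolog. When a target correlation is requested, the noise SD is solved
analytically from the realized score variance: the per-column-mean
residual SD is $|b_1|\,\mathrm{sd(score)}\sqrt{1/r^2 - 1}$, and a column
observed by n homologs receives per-homolog noise scaled by $\sqrt{n}$ so
the column mean has exactly that SD. At the published headline correlation
(r = 0.73) over a 52-column, 14-sequence alignment, the mean recovered r
over 200 seeds is within ±0.03 of target.

## 6. Trajectory post-processing

Frames are superposed by least-squares rigid-body (Kabsch/SVD) alignment
of a selection (default Cα) onto a reference frame; the per-frame RMSD of
the selection is reported. RMSF is the square root of the time-mean
squared deviation of each selected atom from its time-mean position,
aggregated per residue. RMSF is invariant under any global rigid motion
applied uniformly to all frames, and for isotropic Gaussian jitter with
per-axis SD σ it converges to σ√3 — both are tested, the latter within 3%
at 5,000 frames (the analysis window length used on the reference
trajectories).

Hydrogen bonds use geometric criteria that the source figures do not pin
down; the defaults are donor–acceptor distance ≤ 3.5 Å and, when
hydrogens are present, donor–H–acceptor angle ≥ 150° (hydrogens are
assigned to donors by covalent distance in the first frame; heavy-atom
trajectories fall back to distance-only, and the criteria used are echoed
in the report attributes). Occupancy is an exact frame-count ratio;
reporting classes follow the 30%/85% thresholds used in the reference
figures (≥85% "strong"). The mean number of interface H-bonds per frame
equals the sum of pair occupancies — an identity kept under test. Close
contacts mark a residue pair in any frame where any interatomic distance
is below 4 Å. Trajectory I/O is multi-model PDB only; binary formats are
out of scope at desk scale.

## 7. Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline needs, each deterministic
given a seed:

- `simulateTranscriptome()` back-translates the planted protein with
  random synonymous codons (random strand, UTR flanks with an in-frame
  stop immediately upstream, so the planted ORF segment is exactly the
  planted protein), plus decoys (GC 0.4, 300–3,000 nt) rejection-sampled
  to contain no 8-mer of the planted protein in any frame.
- `simulateSpectra()` emits complete singly charged b/y ladders per
  tryptic peptide with Gaussian m/z jitter, log-normal intensities,
  uniform decoy peaks, and precursor charge `clip(round(len/7), 1, 5)`.
- `simulateInhibitionAssay()` applies multiplicative Gaussian noise to
  Morrison-model rates.
- `simulateTrajectory()` adds independent per-residue Gaussian
  displacements around a reference, optionally with global rigid motion
  and a scripted H-bond present in an exact fraction of frames.
- `simulateDdgTables()` as in section 5.

These emulate the statistical structure the analyses assume — not real
data. Real spectra have isotope envelopes, charge-reduced species,
correlated noise and missing ions; real trajectories have anisotropic,
correlated fluctuations; real ΔΔG errors are not homoscedastic. Passing
the round-trip tests therefore demonstrates correctness of the inference
machinery under its own model, not instrument-grade performance.

## 8. Numerical choices and problem sizes

Tolerances: fragment 0.3 Th, precursor 0.5 Th, tag-spacing as given per
call; Ki fit convergence at relative parameter change < 1e-8 within 500
iterations; Morrison discriminant clamped at zero against float
underflow; regression refuses fewer than 3 paired columns and flags
zero-variance degeneracy rather than returning a number. Test problem
sizes are chosen to be decisive yet quick: 500-decoy transcriptomes,
200-replicate kinetic and correlation calibrations, 5,000-frame RMSF
convergence, exhaustive 20³ column enumeration for the conservation
oracle; the whole suite runs in about a minute.

## 9. Known limitations

No database-search scoring or FDR machinery (tag search is exact-match
over ambiguity classes; mismatch-tolerant search is out of scope);
variable modifications and isotopic fine structure are not modeled;
progress-curve (slow-binding) kinetics, IC50 fitting and mechanism
discrimination are out of scope; the energy function behind ΔΔG tables is
consumed, never reimplemented; PBC unwrapping and solvent analysis are
not performed on trajectories.
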