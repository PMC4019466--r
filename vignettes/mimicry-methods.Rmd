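---
title: "Quantifying RNA mimicry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA mimicry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamimicry)
```

# The scientific question

A protein is said to act as an *RNA mimic* when it binds a partner through
the same surface that RNA occupies in another biological context. In the
ribosome-assembly system that motivates this package, the adenylate kinase
Fap7 binds ribosomal protein Rps14 on the face that Rps14 otherwise
devotes to the 18S rRNA, and the basic C-terminal extension of Rps14
(Rps14-CE) reciprocally fills Fap7's AMP pocket, inhibiting the enzyme.
Establishing that claim quantitatively requires four kinds of measurement,
all provided here: interface geometry (buried areas, interface residues,
contact inventories), cross-complex interface comparison through a homolog
residue map, solution-scattering consistency checks, and enzyme-kinetics
and binding fits.

# Surface areas and interfaces

SASA uses the Shrake–Rupley construction: each atom's van der Waals sphere
is inflated by the probe radius (default 1.4 Å, the conventional water
probe) and sampled with `n_points` test points (default 960); points
falling inside any other inflated sphere are inaccessible. Two choices are
deliberate:

* **Deterministic golden-spiral points.** A Fibonacci lattice replaces the
  random sphere sampling of the original algorithm, so SASA values are
  bit-reproducible; the sampling resolution is one point's area,
  `4π(r+p)²/n_points`, and an isolated atom is exact by construction.
* **Radii.** A single Bondi-type table (C 1.70, N 1.55, O 1.52, S/P 1.80
  Å…) with a 1.80 Å fallback for unlisted elements. Published interface
  areas in this field come from a variety of tools with slightly different
  radii, probe placement and sampling; differences of a few percent in
  absolute areas between tools are normal, which is why the
  structure-level checks in the test suite use ±10% bands on areas and ±5
  on residue counts.

Buried surface area of partner X is `SASA(X alone) − SASA(X in complex)`,
the interface area is the mean of the two partner BSAs, and an *interface
residue* is one with summed per-residue ΔSASA above a threshold (default
0 Å², the PISA-style "any burial" rule; the threshold is exposed because
published residue counts rarely state their rule). Waters are always
excluded; hydrogens are ignored (the crystal structures of interest, at
2.1–2.45 Å, carry none); hetero ligands such as ADP/ATP are kept in the
model but excluded from polymer selections unless requested. For the
extension-specific numbers (the ~500 Å² contributed by the Fap7 η8
extension, the ~800 Å² of the Rps14-CE) we compute ΔSASA restricted to the
extension selection — a decomposition of one partner's burial, not a
symmetric pairwise interface; the alternative convention (mean of both
sides) would differ, and the restricted form matches how such
contributions are usually quoted.

# Contacts

With no hydrogens present, hydrogen bonds use a heavy-atom distance
criterion only (donor–acceptor N/O/S pairs from residue-type tables,
default ≤ 3.5 Å) and no angular term. Salt bridges pair charged-group
nitrogens (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 — His is counted as basic
by default, assuming protonation) with carboxylate oxygens (Asp, Glu,
terminal OXT) or nucleic-acid phosphate oxygens, default ≤ 4.0 Å, reported
once per residue pair at the minimum N–O distance. Atom pairs that qualify
as salt bridges are excluded from the hydrogen-bond list so the two
inventories never double-count. Published contact counts rarely state
their criteria, so counts from different tools can differ by one or two
contacts; the tests treat printed counts with a ±2 band.

# The mimicry statistics

Two homologous chains are mapped by an end-gap-free global alignment
(Needleman–Wunsch, affine gaps) under BLOSUM62 with gap open 10 and extend
0.5 — conventional protein-alignment settings, exposed as arguments.
Identity is identical pairs over aligned (both-non-gap) columns. The
interface-overlap report counts residues of interface A whose mapped
position lies in interface B. A printed statement like "35 residues, over
70% of the total" is ambiguous about its denominator (35/50 = 70% of the
larger interface, 35/45 = 78% of the smaller), so both fractions are
reported; `overlap_fraction` uses the larger set. Residues with no aligned
partner are counted unshared and listed separately. Author residue
numbering is preserved end to end so reports cite residues the way the
crystallographic literature does (Asp124, Arg100, …).

# Scattering

The Guinier fit regresses `ln I` on `q²` over a window shrunk from high q
until `qmax·Rg < 1.3` holds self-consistently — the one numeric rule fixed
by standard practice. Model intensities use the in-vacuo point-scatterer
Debye sum, evaluated through a fine pair-distance histogram (default bin
0.02 Å; the binning error is far below other error sources at the q ranges
used). No hydration layer or excluded-volume term is applied — a
deliberate deviation from CRYSOL-style predictors — so experimental
absolute parameters of hydrated particles are *not* reproduction targets
here; the scattering module is validated against analytic oracles
(spheres, two-point systems) instead. P(r) is the weighted pair-distance
histogram with `Rg² = ∫r²P dr / 2∫P dr`; Dmax is the exact maximum pair
distance. The Porod volume `V = 2π² I(0)/Q` estimates the invariant by
trapezoidal integration after subtracting a constant background fitted as
`I ≈ B + K q⁻⁴` over the upper half of the q range (for point models the
background absorbs the flat self-scattering term `Σf²`), adds the analytic
`K/qmax` tail, and takes `I(0)` from the Guinier extrapolation; profiles
truncated before `qmax·Rg = 2` are flagged unreliable. The model-fit
statistic is `χ² = (1/N) Σ [(I_exp(q_k) − c·I_m(q_k))/σ_exp(q_k)]²` with
the closed-form scale `c = Σ(I_exp I_m/σ²)/Σ(I_m²/σ²)`; the `1/N`
normalisation (rather than `1/(N−1)`) follows the plain sum-over-points
definition and is what the tests cross-check against a grid search.

# Kinetics and binding

The coupled assay reports adenylate-kinase turnover as NADH consumption at
340 nm. `rate_from_trace` selects the most linear contiguous window
(highest R² straight-line fit, default 60% of points — mixing transients
make the earliest points unreliable), optionally subtracts a no-enzyme
reference trace first, and converts the slope with ε(NADH, 340 nm) =
6220 M⁻¹cm⁻¹ (the standard value; configurable). Michaelis–Menten and
single-site binding fits are nonlinear least squares
(Levenberg–Marquardt), initialised from a Hanes-Woolf linearisation so
convergence does not depend on user guesses; fits are unweighted by
default with optional weights. The binding model is the single-site
hyperbola with a fitted amplitude `s` (which can be frozen to propagate a
scale calibrated on one titration across a series); where a source
describes its fit equation only loosely this hyperbola is the assumed
form. Efficiency reduction is the dimensionless statistic
`100·(1 − (kcat/Km)_complexed/(kcat/Km)_free)`, invariant to a common
rescaling of both fits.

# What the synthetic fixtures emulate — and what they do not

The generators produce every input class the pipeline consumes, with the
truth recorded in a manifest:

* `make_toy_complex` builds two extended poly-alanine backbones 16 Å apart
  and engineers Asp–Arg salt bridges and Asn–Gln hydrogen bonds whose
  terminal heavy atoms sit at exact requested distances, so the contact
  and interface stages have unambiguous ground truth. These are not
  folded proteins: no secondary structure, no packing, no competing
  near-cutoff contacts. Passing these tests shows the *algorithms* are
  correct, not that any particular published count is reproduced.
* `make_sphere_cloud` gives uniform balls with known `Rg = √(3/5)·R` and
  `Dmax = 2R`. The `"grid"` variant (deterministic cubic lattice) exists
  because a random cloud's Debye curve carries Monte-Carlo variance that
  overwhelms the small form-factor values near `qR = 4`, while the lattice
  tracks the analytic sphere factor to ~2% there. At spacing ~2 Å and
  R = 20 Å (about 4,000 points) the whole scattering test battery runs in
  seconds.
* `make_kinetics_data` defaults to the published free-yFap7 operating
  point — Km 52 µM, kcat 6.12×10⁻³ s⁻¹, 5 µM enzyme (the assay used
  5–10 µM; 5 µM is taken as the generator default, and kcat recovery is
  independent of this choice), 8 ATP levels from 5 to 1000 µM. The
  recovery study uses 5% multiplicative Gaussian noise over 200 seeded
  replicates. `make_binding_data` spans 0.0036–3.6 µM, the titration range
  of the filter-binding assay, with default Kd 1.50 µM.

# Numerical choices and degenerate inputs

* Alternate locations collapse at read time (`first` or
  `highest_occupancy`); occupancy ties break alphabetically by altloc.
* Kabsch superposition enforces proper rotations (reflection correction on
  the smallest singular vector) and refuses rank-deficient (collinear)
  inputs; RMSD is reported after the transform.
* Neighbour search is an exact cell-list: identical output to brute-force
  all-pairs enumeration, verified property-style on random clouds.
* Empty atom selections warn rather than error (an empty interface is a
  result, not a failure); structure files with zero polymer atoms are an
  error; a Guinier fit on a rising profile is an error; a single-atom
  P(r) is an error.
* Guinier windows shrink monotonically and stop at five points minimum;
  non-positive intensities are dropped with a warning before the log.

# Problem sizes and known limitations

The test battery is sized for interactive use: toy complexes of ~100
atoms, scattering clouds of ~4,000 points, 200-replicate kinetics
recovery — everything runs in about a minute on one core. Full
crystal-structure analyses (an 8-chain asymmetric unit, a ribosome
neighbourhood) use exactly the same code paths but need the deposited
coordinate files, which are looked up under
`options(rnamimicry.structure_dir=)` by the two structure-level acceptance
tests. Known limitations: no mmCIF parsing or symmetry-mate generation; no
angular hydrogen-bond term (inappropriate without hydrogens); in-vacuo
scattering only (no hydration shell, so absolute experimental SAXS
parameters of hydrated particles will differ); pairwise alignment only
(no MSA or structure-based alignment); and the binding model is strictly
single-site.
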