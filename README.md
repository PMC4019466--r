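# rnamimicry

Structural and biochemical analysis of protein chaperones that work by
**RNA mimicry** — presenting a protein surface that substitutes for the RNA
contacts of a binding partner. The motivating system is the Fap7–Rps14
complex of small-ribosomal-subunit biogenesis: the atypical adenylate
kinase Fap7 sequesters ribosomal protein Rps14 by occupying the same
surface of Rps14 that the 18S rRNA binds in the ribosome, while the basic
C-terminal extension of Rps14 plugs Fap7's AMP site and inhibits its
kinase activity.

The package provides, as composable R functions, every quantitative step
such a study needs:

* **Interfaces** — solvent-accessible surface area by Shrake–Rupley sphere
  sampling with a deterministic golden-spiral point set; buried surface
  area `BSA(X) = SASA(X alone) − SASA(X in complex)`; interface residues by
  per-residue ΔSASA.
* **Contacts** — heavy-atom hydrogen-bond and salt-bridge inventories
  (charged N vs carboxylate or phosphate O, default 4.0 Å; donor–acceptor
  N/O pairs, default 3.5 Å).
* **Mimicry statistics** — end-gap-free global alignment (BLOSUM62) giving
  a residue map between homologous chains; cross-complex interface-overlap
  counts with both denominators; a contact-replacement table that
  classifies substitutions such as `phosphate->carboxylate`.
* **Geometry** — Kabsch superposition (proper rotations only), exact
  grid-accelerated neighbour search, Cα distance matrices.
* **SAXS** — Guinier fits with the `qmax·Rg < 1.3` window rule, Debye
  model profiles from coordinates, P(r)/Dmax, Porod volume, and the
  standard `χ² = (1/N) Σ [(I_exp − c·I_m)/σ]²` model-fit statistic with the
  closed-form scale `c`.
* **Kinetics** — coupled-assay rate extraction from A340 traces,
  Michaelis–Menten fits (`v = Vmax·[S]/(Km+[S])`), catalytic-efficiency
  reduction `100·(1 − (kcat/Km)_complexed/(kcat/Km)_free)`, and single-site
  binding fits `signal = s·[P]/(Kd+[P])` with an optionally frozen scale.
* **Synthetic fixtures** — seeded generators (toy complexes with engineered
  contacts, uniform pseudo-atom balls, rate/binding/scattering data) whose
  manifests carry the ground truth every stage is tested against.

## Worked example

```r
library(rnamimicry)

# a two-chain complex with one engineered Asp-Arg salt bridge (3.2 A)
# and one Asn-Gln hydrogen bond (2.9 A)
tc <- make_toy_complex(12, 12, salt_bridges = 3.2, hbonds = 2.9, seed = 1)
a <- select_atoms(tc$model, chain = "A")
b <- select_atoms(tc$model, chain = "B")

buried_surface(tc$model, a, b)
#> <interface_report>
#>   BSA partner A: 52 A^2 (4.1% of free surface)
#>   BSA partner B: 51 A^2
#>   interface area: 52 A^2
#>   interface residues: 2 (A) / 2 (B)

salt_bridges(a, b)[, c("basic_res", "acidic_res", "partner_kind", "distance")]
#>   basic_res acidic_res partner_kind distance
#> 1      ARG3       ASP3  carboxylate      3.2

# Michaelis-Menten recovery at the published free-enzyme operating point
kd <- make_kinetics_data(Km = 52, kcat = 6.12e-3, enzyme_conc = 5)
mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
#> <mm_fit: Km 52 uM, Vmax 0.0306 uM/s, kcat 0.00612 1/s, kcat/Km 0.000118>
```

The interface report says that forming the complex buries 52 Å² of chain A
(4.1% of its free surface) and that exactly the two engineered residues per
chain lose accessible area; the contact table recovers the engineered
bridge at its built distance. The kinetics fit returns the generating
parameters exactly because the synthetic rates are noise-free.

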