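# bindfe

Free-energy bookkeeping and order-parameter analysis for umbrella-sampling
studies of peptide–nucleic-acid association.

Binding of short, highly charged peptides to folded RNA elements usually
couples folding and binding: the peptide is disordered in solution, orients
in the RNA's electrostatic field, and folds only late in the association.
Quantifying this requires (a) absolute binding free energies from biased
simulations and (b) structural order parameters resolved along the
separation coordinate. `bindfe` provides the analysis layer for both, for
people who already have (or simulate) biased sample sets and want tested,
reproducible estimators rather than one-off scripts.

## What it computes

**Restraint-route binding free energy.** With axial, orientational and
conformational restraints applied during separation, the standard-state
binding free energy assembles as

    dG_b = -kT ln(I* S* C°) + dG_p^B + dG_n^B + dG_o^B
           - dG_p^S - dG_n^S - dG_o^S - dG_a^S

where `I*` is the separation integral of the restrained PMF over the bound
range, `S*` the angular surface factor at the bulk separation, `C°` the
1 M standard state (one molecule per 1660.6 Å³), and the `dG` terms are
the bulk (B) and site (S) restraint-release free energies for the peptide
(p), nucleic-acid (n), orientational (o) and axial (a) restraint families.
The package supplies the estimators feeding every term — 1-D WHAM, BAR,
mBAR, exponential averaging with block-averaged errors, the angular
release quadratures — and a signed ledger assembler with error
propagation.

**Order parameters and transition fits.** Closest-contact statistics,
contact frequencies, dipole projections, orientation-distribution total
variation distance (range 0–2), soft native contacts, hydrogen bonds,
RMSD variants, dihedral helicity; generalized-logistic and
log-exponential transition fits, onset-boundary extraction, Debye–Hückel
tail fits and the salt-dependence regression d(dG)/d(ln[NaCl]).

**Synthetic ground truth.** Seeded Metropolis/Langevin samplers on
analytic potentials, umbrella and replica-exchange window generators, a
charged-chain + rigid-polyanion bead complex and von Mises–Fisher
orientation ensembles — every estimator in the package is tested against
these known-truth generators.

## Worked example

```r
library(bindfe)

# assemble a published ledger column (packaged printed-table fixture)
led <- ledger_from_table("TIP3P", 81)
res <- assemble_binding_free_energy(led)
d   <- bulk_to_site_deltas(led)

# salt dependence of binding for the TIP4P-D water model
ser <- table_salt_series("TIP4P-D", "restraint")
reg <- salt_dependence_regression(ser)

# recover a double-well PMF from seeded biased sampling
pot <- analytic_potential("double_well", barrier = 1, width = 1)
ds  <- generate_umbrella_dataset(pot, seq(-1.6, 1.6, by = 0.2), 8, "full",
                                 n_per_window = 4000, seed = 11)
pmf <- wham_1d(ds$windows, bin_width = 0.1)
```

This prints:

```
dG_b = -19.95 +/- 0.23 kcal/mol
ddG_p(B->S) = 5.49, ddG_o(B->S) = 4.32 kcal/mol
salt slope = 4.46 +/- 0.60 kcal/mol per ln[NaCl]
predicted concentration at -12.2 kcal/mol: 126 mM
reconstructed double-well barrier: 1.028 kcal/mol (true 1.000)
```

Reading the numbers: the eight ledger terms sum to a strongly favorable
−19.95 kcal/mol binding free energy, of which restricting the peptide's
conformation (+5.49) and orientation (+4.32) are the largest opposing
contributions. The regression slope says binding weakens by ~4.5 kcal/mol
per e-fold increase in salt, and inverting the line locates the
concentration at which a −12.2 kcal/mol affinity would be measured. The
WHAM reconstruction recovers the known 1 kcal/mol barrier of the synthetic
double well to within its sampling error.

See `vignettes/bindfe-methods.Rmd` for the model assumptions, parameter
conventions (force-constant and dihedral-domain conventions, helicity
rule, boundary-extraction rule) and the limitations of the synthetic
generators.

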