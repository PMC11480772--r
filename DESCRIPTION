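Package: bindfe
Title: Restraint-Based Binding Free Energies and Coupled Folding-and-Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Free-energy bookkeeping and order-parameter analysis for
    umbrella-sampling studies of peptide-nucleic-acid association. Implements
    1-D WHAM, Bennett acceptance ratio (BAR) and multistate BAR (mBAR)
    estimators with block-averaged errors, the restraint-release ledger of the
    Woo-Roux absolute binding free-energy protocol (separation integral I*,
    angular surface term S*, standard-state correction and signed assembly),
    per-window structural order parameters (closest contacts, total variation
    distance of orientation distributions, dipole projections, native
    contacts, hydrogen bonds, RMSD variants, helicity), transition fits
    (generalized logistic, log-exponential contact decay, Debye-Hueckel tail,
    salt-dependence regression), and seeded synthetic-data generators
    (Metropolis/Langevin samplers on analytic potentials, umbrella and
    replica-exchange window sets, a charged-chain/rigid-polyanion toy complex)
    that provide ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
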