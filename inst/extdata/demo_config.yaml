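# Demo pipeline: umbrella windows on a quadratic well, WHAM reconstruction,
# a printed-table ledger assembly and the salt-dependence regression.
# Units: kcal/mol, Angstrom, K, mM throughout.
seed: 42
temperature: 300
output_dir: demo_output
stages: [generate, estimate, ledger, fits]
generate:
  potential:
    form: polynomial
    params:
      coefficients: [0.0, 0.0, 2.0]   # U(x) = 2 x^2 kcal/mol
  centers: [-2.0, -1.6, -1.2, -0.8, -0.4, 0.0, 0.4, 0.8, 1.2, 1.6, 2.0]
  k_bias: 10.0
  convention: full
  n_per_window: 2000
estimate:
  bin_width: 0.1
  tol: 1.0e-7
  site_range: [-1.0, 1.0]
  r_ref: 0.0
ledger:
  from_table:
    water: TIP3P
    salt_mM: 81
fits:
  salt_regression:
    water: TIP4P-D
    source: restraint
    target_dG: -12.2
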