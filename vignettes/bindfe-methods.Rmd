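---
title: "Methods behind bindfe: restraint-based binding free energies and order-parameter analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind bindfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfe)
```

# Scope

`bindfe` implements the analysis layer of an absolute binding free-energy
study of a flexible, highly charged peptide associating with a rigid
polyanion (the motivating system is an arginine-rich phage peptide binding
an RNA hairpin). It covers three things:

1. **Free-energy estimators** over biased sample sets: 1-D WHAM, BAR, mBAR,
   exponential averaging, block-averaged errors and histogram-overlap QC.
2. **Restraint bookkeeping**: the ledger of the restraint-release protocol
   (often called the Woo--Roux or geometric route), in which axial,
   orientational and conformational restraints are imposed during the
   separation PMF calculation and their free-energy cost is removed
   analytically or numerically at the endpoints.
3. **Order parameters and transition fits** that characterize coupled
   folding and binding along the separation coordinate: closest contacts,
   orientation-distribution distances, dipole projections, native contacts,
   hydrogen bonds, RMSD variants, helicity, logistic/log-exponential fits,
   a screened-electrostatics tail fit and the salt-dependence regression.

Everything is exercised end-to-end on synthetic data with known ground
truth; the package does not run molecular dynamics and makes no attempt to
re-simulate the raw per-window data behind published tables.

# The binding free-energy ledger

The standard-state binding free energy is assembled from eight terms,

$$
\Delta G_b^\circ = -k_BT \ln (I^* S^* C^\circ)
 + \Delta G_p^B + \Delta G_n^B + \Delta G_o^B
 - \Delta G_p^S - \Delta G_n^S - \Delta G_o^S - \Delta G_a^S ,
$$

where superscripts $B$/$S$ denote bulk and site, subscripts $p$, $n$, $o$,
$a$ the peptide-conformational, nucleic-acid-conformational, orientational
and axial restraint families, $I^*$ the separation integral over the bound
range of the restrained PMF, $S^*$ the angular surface factor at the bulk
separation $r^*$, and $C^\circ = 1/1660.6\ \mathrm{\AA^{-3}}$ the 1 M
standard state. The ledger (`free_energy_ledger()`) stores *magnitudes*
with bulk/site labels and `assemble_binding_free_energy()` applies the
signs, which prevents double-negation mistakes when tables print site rows
with the minus sign already attached. Standard errors combine as a
root-sum-square because each term comes from an independent calculation.

## Angular release integrals and an observation about conventions

The bulk orientational release is

$$
\Delta G_o^B = -k_BT\ln\!\left[\frac{1}{8\pi^2}
 \iiint \sin\Theta\, e^{-\beta u(\Theta,\Phi,\Psi)}\,
 d\Theta\, d\Phi\, d\Psi\right],
$$

with $u$ the harmonic restraint; the integral factorizes into three 1-D
adaptive quadratures (`orientational_release_bulk()`), and the surface term
$S^* = r^{*2}\iint \sin\theta\, e^{-\beta u(\theta,\phi)}\,d\theta\,d\phi$
is evaluated the same way (`axial_surface_term()`). Tests pin both to
dense-grid Simpson oracles, the $k \to 0$ sphere limits and a Laplace
(stiff-restraint) approximation.

Two conventions are explicit everywhere rather than defaulted:

* **Force-constant convention** — `full` ($u = k\,\delta^2$, the form used
  by Amber-style restraints and the package default) versus `half`
  ($u = k\,\delta^2/2$).
* **Dihedral integration domain** — `periodic` wraps deviations to
  $(-\pi,\pi]$ (the physically periodic measure, the default), while
  `fixed` integrates the unwrapped harmonic over fixed bounds. The
  distinction is invisible when equilibrium dihedrals sit far from
  $\pm\pi$, but with an equilibrium of $-3.13\ \mathrm{rad}$ the fixed
  domain truncates half of that Gaussian. For the reference parameters
  ($k = 100\ \mathrm{kcal\,mol^{-1}\,rad^{-2}}$, 300 K) the periodic
  measure gives 6.493 kcal/mol and the fixed domain 6.814 kcal/mol; the
  latter is what general-purpose fixed-bounds quadrature routines (such as
  SciPy's `nquad`) produce, and it coincides with the widely quoted 6.81
  value for this restraint set. Both are regression-tested; the periodic
  measure remains the default because it is the correct measure for a
  periodic coordinate.

The conformational release (`conformational_release()`) integrates a
WHAM-built RMSD profile over the restrained and the full range and returns
the (non-negative) confinement cost. `single_step_release()` covers the
one-step perturbation used at the complex site: exponential reweighting
with a block-averaged error, an effective-sample-size diagnostic, and a BAR
fallback when forward and reverse energy differences are both available
(the two-sided estimator is far less biased when the restraint is stiff
relative to the sampled ensemble).

# Estimators

**WHAM** (`wham_1d()`) solves the self-consistent histogram equations on
shared global bin edges (default width 0.1 in coordinate units, tolerance
$10^{-7}$ kcal/mol on the window free energies, at most $10^5$ iterations;
the defaults are deliberately conservative and configurable because no
single choice suits all coordinates). Adjacent-window support is checked
with a Bhattacharyya overlap; disconnected window sets warn or error per
flag. Per-bin uncertainties are reported as the counting floor
$k_BT/\sqrt{n_b}$; correlated-data errors should come from block averaging
of window contributions, which is why `block_error()` (ten equal blocks,
trailing remainder discarded — the simplest reproducible rule) is a
separate, composable primitive.

**BAR** (`bar()`) solves the Bennett self-consistency equation by bracketed
root finding and reports the standard asymptotic variance. **mBAR**
(`mbar()`) iterates the multistate equations with log-sum-exp
stabilization, pins the first state to zero and estimates the covariance by
block resampling: each state's samples are split into consecutive blocks,
the equations re-solved per block, and the covariance of the block
solutions divided by the block count. This replaces the analytic
asymptotic covariance with an estimator that is robust to the correlated
samples our Metropolis generators produce.

$I^*$ (`pmf_to_I_star()`) integrates
$e^{-\beta\,[W(r) - W(r_\mathrm{ref})]}$ over the bound range by the
trapezoid rule on the profile grid; tests include the exact flat-profile
and Gaussian-well values and a grid-refinement (Richardson) check.

# Order parameters

All statistics operate on a plain `trajectory()` container (topology +
coordinate frames) with declarative `atom_selection()`s, default
non-hydrogen. Notable conventions, chosen where the field is genuinely
split:

* $\langle r_{cc}\rangle$ reports the *population standard deviation* of
  the per-frame closest contact as its spread (the alternative, the
  standard error of the mean, is available via `spread = "sem"`).
* The dipole of a *charged* group depends on the origin; it is taken about
  the group's center of mass, matching the coordinate used to steer the
  partners. A negative projection on the receptor-to-peptide unit vector
  means the positive charge points at the receptor.
* The orientation-distribution distance is $D_{TV} = \sum_\omega
  |P(\omega) - P_\mathrm{ref}(\omega)|$ on shared 5-degree bins — twice the
  conventional total variation distance, ranging 0 (bulk-like) to 2
  (disjoint). Tests verify symmetry and the triangle inequality on the
  half scale.
* The principal axis is headless, so its angle is folded to $[0, \pi/2]$;
  dipole and end-to-end vectors are headed and keep $[0, \pi]$.
* Native contacts use the soft-sigmoid count over inter-partner heavy-atom
  pairs within 4.5 Å in the reference frame (steepness 5 Å$^{-1}$, width
  multiplier 1.8).
* Hydrogen bonds use the 4 Å donor–acceptor / 120° donor–hydrogen–acceptor
  definition, counted per peptide residue and averaged.
* Helicity is a dihedral-run rule — residues with $(\phi,\psi)$ inside the
  $\alpha$ basin ($\phi \in [-100°,-30°]$, $\psi \in [-67°,-7°]$) count
  only in runs of at least three. This replaces assignment programs such
  as STRIDE to avoid an external binary; it is deliberately simpler and is
  *not* equivalent to them.
* The orientational RMSD superposes each frame on the receptor only and
  then measures the peptide without re-fitting, so it reports displacement
  plus misorientation; it is bounded below by the best-fit peptide RMSD.

# Transition fits and boundary extraction

`fit_generalized_logistic()` fits $y = A + (K-A)/(1+e^{-B(x-M)})^{1/\nu}$
with 16 seeded starts and a positivity bound on $\nu$ (the surface is
multimodal and no published protocol exists, so multi-start with a
fixed seed is the reproducible choice).

`fit_contact_decay()` fits $f(x) = a + b\log(c\,e^{x-d} + e)$. This
5-parameter family carries an exact two-parameter gauge freedom
($c,e \to sc,se$ with $a \to a - b\log s$; and $c \to sc$ with
$d \to d + \log s$), i.e. it *is* the 3-parameter family
$a + b\log(e^{x-d}+1)$. The fit therefore works in the canonical gauge
$c = e = 1$; data generated on the $e \to 0$ boundary (a pure line) is
detected and flagged rather than forced through the nonlinear optimizer.

`extract_boundary()` encodes the onset rule: scanning from the largest
separation downward, the boundary $\Xi$ is the middle of the first run of
three consecutive windows that each increase (by more than a noise floor,
default 0.01) relative to their larger-$r$ neighbour. On the worked
example — a profile flat at 0.1 for $r = 40,38,36$ and rising 0.3, 0.5,
0.7 at $r = 34,32,30$ — the increasing columns are 34, 32, 30 and
$\Xi = 32$. "No such run" is a signal (`NA`), not an error, because
profiles that never order are a legitimate outcome.

`debye_huckel_fit()` fits the screened-Coulomb tail
$W(r) = A\,e^{-\kappa r}/r + w_0$ beyond a start distance (default 20 Å)
and, given an ionic strength, also reports the theoretical
$\kappa_{DH} = \sqrt{I}/3.04$ Å$^{-1}$ for a 1:1 electrolyte near 300 K.
`salt_dependence_regression()` is an ordinary least-squares slope of
$\Delta G_b^\circ$ against $\ln[\mathrm{NaCl}]$; natural log is the
default because only that base reproduces published per-log-unit slopes,
and the decadic slope is exactly $\ln 10$ times larger (tested as an
identity). `interpolate_concentration()` inverts the fitted line.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions for every test:

* `metropolis_sample()` / `generate_umbrella_dataset()` — seeded Metropolis
  chains on analytic potentials under harmonic biases, with the analytic
  PMF attached. The default WHAM recovery suite uses 11 windows on
  $[-2,2]$ with $k = 10$ (full convention) and 5000 samples per window for
  the quadratic well, and 17 windows with 4000 samples for the double
  well; these sizes give per-bin errors well below the 0.1 kcal/mol RMS
  criterion while keeping the whole suite at desk scale.
* `generate_hremc_dataset()` — the same windows advanced in lockstep with
  neighbour swap attempts every few sweeps, accepted on the cross-bias
  energy difference; detailed balance is verified on a flat potential
  where each window marginal is exactly the bias Gaussian.
* `toy_complex_spec()` / `simulate_toy_complex()` — a 19-bead charged
  chain (9 basic, 3 acidic beads, net +6e, mimicking an arginine-rich
  19-mer) and a rigid 15-bead arc of net charge −14e, interacting through
  harmonic bonds, angular stiffness, Debye-screened Coulomb forces
  ($\lambda_D = 3.04/\sqrt{I}$ Å) and a soft $r^{-8}$ core. Bead charges
  are integers; there are no partial charges, no solvent, and no attempt
  to reproduce real peptide–RNA energetics — the model exists to exercise
  the analysis code paths with controllable contact, orientation and
  dipole statistics. Sampling is single-bead Metropolis or overdamped
  Euler–Maruyama Langevin whose time step is capped by the stiffest
  curvature in the system (Euler diverges beyond
  $\beta D k\,\Delta t \approx 0.5$; the cap keeps it at 0.25).
* `generate_orientation_ensemble()` — a rigid dipolar dumbbell whose axis
  follows a von Mises–Fisher distribution about the separation axis, with
  the true angle density attached for quadrature comparisons.

## The end-to-end consistency check

The restraint-release cycle is closed on the *single-bead reduction* of the
toy complex: one +2e ligand bead and one −4e scaffold bead, i.e. a central
potential. For that geometry an exhaustive, unrestrained umbrella
reference is exactly comparable to the restrained route — the radial
distribution is unaffected by an axial restraint, the free surface factor
is $4\pi r^{*2}$, and the site release reduces to the isotropic average of
the restraint Boltzmann factor. The check runs both routes through the
real machinery (3-D Metropolis sampling, 18 radial windows of 2500 retained
samples, WHAM, $I^*$, $S^*$, two-sided single-step release, signed
assembly) for three seeds and requires the two routes to agree within the
combined seed-replication standard error. The 19-bead chain cannot be
checked this way at desk scale — its conformational-release terms have no
cheap exact reference — so the chain model is validated qualitatively
instead (charge-driven association against a charge-free control, bounded
statistics, reproducibility).

# Numerical choices and degenerate inputs

* $k_B = 0.0019872041$ kcal/mol/K; default temperature 300 K.
* Dihedrals follow the right-handed two-plane `atan2` convention; the
  sign is frozen by a square-geometry fixture in the tests.
* Anchor centers of mass are mass-weighted by default with a geometric
  mode behind a flag, since sources rarely state which they use.
* Quadratures: `stats::integrate` at $10^{-12}$ relative tolerance on each
  1-D factor of the separable angular integrals.
* Errors are structured conditions (`bindfe_error` subclasses:
  selection, geometry, convergence, disconnected-windows, reliability,
  ledger, config...), so callers can distinguish degenerate geometry from
  bad input without parsing messages.
* Degenerate fits (constant response, flat tails, pure-linear decay) are
  returned flagged rather than raised, because scans over many windows
  routinely contain such profiles.

# Known limitations

* WHAM is 1-D only and there is no autocorrelation-time machinery beyond
  block averaging; samples from the package's own Metropolis generators
  are correlated, which the seed-replication errors of the consistency
  check absorb but the per-bin counting errors do not.
* The dihedral-run helicity is not equivalent to DSSP/STRIDE assignments.
* No periodic-boundary imaging: frames are assumed whole-molecule.
* The bead model's Langevin integrator trades realism for stability and
  is unsuitable for kinetics.
* Printed-table fixtures carry the rounding of their source; assembling
  rounded inputs can differ from a rounded total by up to the accumulated
  half-units of the inputs, which the acceptance test accounts for
  explicitly.
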