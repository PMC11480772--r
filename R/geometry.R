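## Geometric measurements: centers of mass, angles, dihedrals, anchors ----

.vnorm <- function(v) sqrt(sum(v * v))

#' Center of mass of a selection in one frame
#'
#' Mass-weighted by default, matching the anchor definition used for
#' restraint schemes ("centers-of-mass of all nonhydrogen atoms"); a
#' geometric (unweighted) mode is available since some tools define anchor
#' points that way.
#'
#' @param frame an Nx3 coordinate matrix (Angstrom).
#' @param sel an [atom_selection()] or integer ids.
#' @param topology the [topology()].
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return A length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(frame, sel, topology,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  ids <- resolve_selection(sel, topology) + 1L
  w <- if (weighting == "mass") topology$mass[ids] else rep(1, length(ids))
  colSums(frame[ids, , drop = FALSE] * w) / sum(w)
}

#' Center-of-mass separation distance between two selections
#'
#' @inheritParams center_of_mass
#' @param selA,selB the two selections.
#' @return Distance in Angstrom (non-negative).
#' @export
separation_distance <- function(frame, selA, selB, topology,
                                weighting = "mass") {
  .vnorm(center_of_mass(frame, selA, topology, weighting) -
         center_of_mass(frame, selB, topology, weighting))
}

#' Planar angle at b formed by points a-b-c, in radians on [0, pi]
#' @param a,b,c length-3 coordinate vectors.
#' @return Angle in radians.
#' @export
angle_points <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- .vnorm(u); nv <- .vnorm(v)
  .assert(nu > 1e-12 && nv > 1e-12, "bindfe_geometry_error",
          "coincident points in angle")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang)))
}

#' Signed dihedral angle for points a-b-c-d, right-handed, on (-pi, pi]
#'
#' Uses the standard two-plane atan2 formulation (IUPAC sign convention:
#' looking from b to c, a counterclockwise rotation of the far bond is
#' positive).
#'
#' @param a,b,c,d length-3 coordinate vectors.
#' @return Dihedral angle in radians.
#' @export
dihedral_points <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  .assert(.vnorm(n1) > 1e-12 && .vnorm(n2) > 1e-12,
          "bindfe_geometry_error", "collinear triple in dihedral")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / .vnorm(b2)
  atan2(y, x)
}

#' Wrap an angular deviation to (-pi, pi]
#' @param x angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, w + 2 * pi, w)
}

#' Place a point from internal coordinates (NeRF construction)
#'
#' Given three prior points `a`, `b`, `c`, returns the point `d` such that
#' |cd| = `bond`, the angle b-c-d equals `angle` and the dihedral a-b-c-d
#' equals `dihedral` under the convention of [dihedral_points()].
#'
#' @param a,b,c length-3 coordinate vectors.
#' @param bond bond length (Angstrom), > 0.
#' @param angle planar angle (rad) in (0, pi).
#' @param dihedral dihedral (rad).
#' @return Length-3 coordinate vector.
#' @export
place_from_internal <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b; bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  .assert(.vnorm(n) > 1e-12, "bindfe_geometry_error",
          "collinear prior points in place_from_internal")
  n <- n / .vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dihedral),
          -bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Bias potentials --------------------------------------------------------

#' Define a harmonic bias potential
#'
#' The `convention` is always explicit: `"full"` means U = k (x - x0)^2 (the
#' form used by Amber-style NMR restraints, and the default throughout the
#' package), `"half"` means U = (k/2)(x - x0)^2.
#'
#' @param kind one of `"harmonic_distance"`, `"harmonic_angle"`,
#'   `"harmonic_dihedral"`, `"harmonic_rmsd"`.
#' @param center bias center (Angstrom or rad).
#' @param force_constant kcal mol^-1 A^-2 or kcal mol^-1 rad^-2; >= 0.
#' @param convention `"full"` or `"half"`.
#' @return An object of class `bindfe_bias`.
#' @export
bias_potential <- function(kind = c("harmonic_distance", "harmonic_angle",
                                    "harmonic_dihedral", "harmonic_rmsd"),
                           center, force_constant,
                           convention = c("full", "half")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  .assert(force_constant >= 0, "bindfe_input_error", "force_constant must be >= 0")
  structure(list(kind = kind, center = center,
                 force_constant = force_constant, convention = convention),
            class = "bindfe_bias")
}

#' Evaluate a bias potential at coordinate value(s)
#' @param bias a [bias_potential()].
#' @param x coordinate values (Angstrom or rad).
#' @return Energies in kcal mol^-1.
#' @export
bias_energy <- function(bias, x) {
  d <- x - bias$center
  if (bias$kind %in% c("harmonic_angle", "harmonic_dihedral"))
    d <- wrap_angle(d)
  pre <- if (bias$convention == "half") 0.5 else 1
  pre * bias$force_constant * d^2
}

## Restraint scheme -------------------------------------------------------

#' Define a Woo-Roux restraint scheme
#'
#' Six anchor points (three per binding partner) define one distance, two
#' axial ("spherical") angles and three orientational angles:
#' r = |P0-Q0|, theta = angle(P1,P0,Q0), phi = dihedral(P2,P1,P0,Q0),
#' Theta = angle(P0,Q0,Q1), Psi = dihedral(P1,P0,Q0,Q1),
#' Phi = dihedral(P0,Q0,Q1,Q2).
#'
#' @param P0,P1,P2 anchor selections on the receptor (e.g. the RNA).
#' @param Q0,Q1,Q2 anchor selections on the ligand (e.g. the peptide).
#' @param Theta0,Phi0,Psi0 equilibrium orientational angles (rad).
#' @param theta0,phi0 equilibrium axial angles (rad).
#' @param k angular force constant, kcal mol^-1 rad^-2 (shared by all five).
#' @param convention `"full"` (U = k d^2, default) or `"half"`.
#' @param rmsd_reference optional list of reference frames per partner for
#'   conformational restraints.
#' @param weighting anchor center-of-mass weighting, `"mass"` or `"geometric"`.
#' @return An object of class `bindfe_restraint_scheme`.
#' @export
restraint_scheme <- function(P0, P1, P2, Q0, Q1, Q2,
                             Theta0, Phi0, Psi0, theta0, phi0,
                             k = 100, convention = c("full", "half"),
                             rmsd_reference = NULL,
                             weighting = c("mass", "geometric")) {
  convention <- match.arg(convention)
  weighting <- match.arg(weighting)
  .assert(k >= 0, "bindfe_input_error", "k must be >= 0")
  .assert(Theta0 > 0 && Theta0 < pi, "bindfe_input_error", "Theta0 must lie in (0, pi)")
  .assert(theta0 > 0 && theta0 < pi, "bindfe_input_error", "theta0 must lie in (0, pi)")
  for (d0 in c(Phi0, Psi0, phi0))
    .assert(d0 > -pi && d0 <= pi, "bindfe_input_error",
            "dihedral equilibria must lie in (-pi, pi]")
  structure(list(P0 = P0, P1 = P1, P2 = P2, Q0 = Q0, Q1 = Q1, Q2 = Q2,
                 Theta0 = Theta0, Phi0 = Phi0, Psi0 = Psi0,
                 theta0 = theta0, phi0 = phi0, k = k,
                 convention = convention, rmsd_reference = rmsd_reference,
                 weighting = weighting),
            class = "bindfe_restraint_scheme")
}

#' Measure the restraint-scheme virtual-bond coordinates in a frame
#'
#' @param frame Nx3 coordinate matrix.
#' @param scheme a [restraint_scheme()].
#' @param topology the [topology()].
#' @return A named list with elements `r`, `theta`, `phi`, `Theta`, `Phi`,
#'   `Psi` (Angstrom / radians).
#' @export
measure_virtual_angles <- function(frame, scheme, topology) {
  com <- function(sel) center_of_mass(frame, sel, topology, scheme$weighting)
  P0 <- com(scheme$P0); P1 <- com(scheme$P1); P2 <- com(scheme$P2)
  Q0 <- com(scheme$Q0); Q1 <- com(scheme$Q1); Q2 <- com(scheme$Q2)
  for (pair in list(list(P1, P0), list(P0, Q0), list(Q0, Q1), list(Q1, Q2),
                    list(P2, P1)))
    .assert(.vnorm(pair[[1]] - pair[[2]]) > 1e-10, "bindfe_geometry_error",
            "coincident consecutive anchor points")
  list(
    r     = .vnorm(P0 - Q0),
    theta = angle_points(P1, P0, Q0),
    phi   = dihedral_points(P2, P1, P0, Q0),
    Theta = angle_points(P0, Q0, Q1),
    Psi   = dihedral_points(P1, P0, Q0, Q1),
    Phi   = dihedral_points(P0, Q0, Q1, Q2)
  )
}

#' Restraint energy of a measured angle record under a scheme
#'
#' Sums the five harmonic angle terms; dihedral deviations are wrapped to
#' (-pi, pi] before squaring.  Planar-angle deviations are used directly.
#'
#' @param record a list with `theta`, `phi`, `Theta`, `Phi`, `Psi` (as from
#'   [measure_virtual_angles()]).
#' @param scheme a [restraint_scheme()].
#' @return Energy in kcal mol^-1 (>= 0).
#' @export
restraint_energy <- function(record, scheme) {
  pre <- if (scheme$convention == "half") 0.5 else 1
  dev2 <- (record$Theta - scheme$Theta0)^2 +
    wrap_angle(record$Phi - scheme$Phi0)^2 +
    wrap_angle(record$Psi - scheme$Psi0)^2 +
    (record$theta - scheme$theta0)^2 +
    wrap_angle(record$phi - scheme$phi0)^2
  pre * scheme$k * dev2
}
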