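## Per-frame / per-window structural order parameters ---------------------

.pairwise_min_dist <- function(frame, idsA, idsB) {
  A <- frame[idsA, , drop = FALSE]
  B <- frame[idsB, , drop = FALSE]
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Closest-contact distance per frame
#'
#' @param traj a [trajectory()].
#' @param selA,selB selections on the two partners (hydrogens excluded by
#'   the default selection mode).
#' @return Numeric vector of per-frame minimum inter-selection distances
#'   (Angstrom).
#' @export
closest_contact_series <- function(traj, selA, selB) {
  .assert(n_frames(traj) >= 1L, "bindfe_input_error", "empty trajectory")
  idsA <- resolve_selection(selA, traj$topology) + 1L
  idsB <- resolve_selection(selB, traj$topology) + 1L
  vapply(traj$frames, .pairwise_min_dist, numeric(1), idsA = idsA, idsB = idsB)
}

#' Mean closest-contact distance and its spread
#'
#' Time average of the per-frame closest inter-partner distance; `spread`
#' selects the population standard deviation of the series (default) or the
#' standard error of its mean.
#'
#' @inheritParams closest_contact_series
#' @param spread `"stdev"` (default) or `"sem"`.
#' @return Named numeric vector `c(mean, spread)` in Angstrom.
#' @export
mean_closest_contact <- function(traj, selA, selB,
                                 spread = c("stdev", "sem")) {
  spread <- match.arg(spread)
  r <- closest_contact_series(traj, selA, selB)
  n <- length(r)
  pop_sd <- sqrt(mean((r - mean(r))^2))
  s <- if (spread == "stdev") pop_sd else pop_sd / sqrt(n)
  c(mean = mean(r), spread = s)
}

#' Fraction of frames with a close inter-partner contact
#'
#' @inheritParams closest_contact_series
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @return Fraction in `[0, 1]`.
#' @export
contact_frequency <- function(traj, selA, selB, cutoff = 4.0) {
  mean(closest_contact_series(traj, selA, selB) <= cutoff)
}

#' Dipole moment of a selection in one frame
#'
#' d = sum_i q_i (x_i - origin); for a charged group the result depends on
#' the origin, which defaults to the selection's center of mass.
#'
#' @param frame Nx3 coordinate matrix.
#' @param sel selection (hydrogens included: charges live on all atoms).
#' @param topology the [topology()]; must carry charges.
#' @param origin reference origin (length-3) or `NULL` for the selection COM.
#' @return Length-3 dipole vector in e*Angstrom.
#' @export
dipole_moment <- function(frame, sel, topology, origin = NULL) {
  ids <- resolve_selection(sel, topology) + 1L
  q <- topology$charge[ids]
  .assert(!any(is.na(q)), "bindfe_input_error", "topology charges missing")
  if (is.null(origin)) origin <- center_of_mass(frame, sel, topology)
  colSums((frame[ids, , drop = FALSE] -
             matrix(origin, length(ids), 3, byrow = TRUE)) * q)
}

#' Rolling dipole-projection profile along a window trajectory
#'
#' For each frame the peptide dipole (about the peptide COM) is projected on
#' the unit receptor-to-peptide COM vector; a negative value means the
#' peptide's positive charge points toward the (negative) receptor.  The
#' series is then smoothed with a sliding window.
#'
#' @param traj a [trajectory()] of one umbrella window.
#' @param receptor_sel,peptide_sel selections for the two partners.
#' @param step sliding-window step in frames (default 5000).
#' @param window sliding-window size in frames (default 20000).
#' @param normalized if `TRUE`, project the unit dipole vector (direction
#'   only).
#' @return A data frame with `frame_center`, `value` (e*Angstrom, or
#'   dimensionless when normalized) and `stderr` columns.
#' @export
dipole_projection_profile <- function(traj, receptor_sel, peptide_sel,
                                      step = 5000, window = 20000,
                                      normalized = FALSE) {
  nf <- n_frames(traj)
  .assert(nf >= window, "bindfe_input_error",
          "trajectory shorter than the sliding window")
  proj <- vapply(traj$frames, function(fr) {
    d <- dipole_moment(fr, peptide_sel, traj$topology)
    rhat <- center_of_mass(fr, peptide_sel, traj$topology) -
      center_of_mass(fr, receptor_sel, traj$topology)
    rhat <- rhat / .vnorm(rhat)
    if (normalized) {
      nd <- .vnorm(d)
      .assert(nd > 1e-12, "bindfe_degenerate_vector_error", "zero dipole")
      d <- d / nd
    }
    sum(d * rhat)
  }, numeric(1))
  starts <- seq(1L, nf - window + 1L, by = step)
  data.frame(
    frame_center = starts + (window - 1) / 2,
    value = vapply(starts, function(s) mean(proj[s:(s + window - 1L)]), numeric(1)),
    stderr = vapply(starts, function(s) {
      x <- proj[s:(s + window - 1L)]
      sd(x) / sqrt(length(x))
    }, numeric(1))
  )
}

## Angle distributions and DTV --------------------------------------------

#' Construct a discretized angle distribution
#'
#' @param edges increasing bin edges (rad).
#' @param probs bin probabilities (>= 0, summing to 1).
#' @param count number of observations behind the distribution.
#' @return An object of class `bindfe_angle_dist`.
#' @export
angle_distribution <- function(edges, probs, count = NA_integer_) {
  .assert(all(diff(edges) > 0), "bindfe_input_error", "edges must increase")
  .assert(length(probs) == length(edges) - 1L, "bindfe_input_error",
          "need one probability per bin")
  .assert(all(probs >= 0), "bindfe_input_error", "probabilities must be >= 0")
  .assert(abs(sum(probs) - 1) < 1e-8, "bindfe_input_error",
          "probabilities must sum to 1")
  structure(list(edges = edges, probs = probs, count = count),
            class = "bindfe_angle_dist")
}

#' Bin angle samples into a distribution on fixed edges
#'
#' @param omega angle samples (rad).
#' @param edges bin edges; default 5-degree bins on `[0, pi]` (shared edges
#'   make distributions comparable under [total_variation_distance()]).
#' @return An [angle_distribution()].
#' @export
bin_angles <- function(omega, edges = seq(0, pi, by = 5 * pi / 180)) {
  B <- length(edges) - 1L
  h <- tabulate(pmin(B, pmax(1L, findInterval(omega, edges,
                                              rightmost.closed = TRUE))),
                nbins = B)
  angle_distribution(edges, h / sum(h), count = length(omega))
}

#' Angle of peptide structural vectors against a reference direction
#'
#' For every frame, computes the angle omega between a chosen peptide vector
#' (principal axis, dipole moment, or end-to-end vector) and either the
#' receptor-to-peptide COM vector or the laboratory x axis (the bulk
#' reference), and bins the angles.  The principal axis is the headless long
#' axis (largest-eigenvalue eigenvector of the mass-weighted gyration
#' tensor), so its angle is folded to `[0, pi/2]`; dipole and end-to-end
#' vectors are headed and keep the full `[0, pi]` range.
#'
#' @param traj a [trajectory()].
#' @param sel peptide selection.
#' @param vector_kind `"principal_axis"`, `"dipole"` or `"end_to_end"`.
#' @param reference `"com_vector"` (requires `partner_sel`) or `"x_axis"`.
#' @param partner_sel receptor selection for the COM vector reference.
#' @param edges histogram edges passed to [bin_angles()].
#' @return An [angle_distribution()].
#' @export
orientation_angles <- function(traj, sel,
                               vector_kind = c("principal_axis", "dipole",
                                               "end_to_end"),
                               reference = c("com_vector", "x_axis"),
                               partner_sel = NULL,
                               edges = seq(0, pi, by = 5 * pi / 180)) {
  vector_kind <- match.arg(vector_kind)
  reference <- match.arg(reference)
  topo <- traj$topology
  ids <- resolve_selection(sel, topo) + 1L
  omega <- vapply(traj$frames, function(fr) {
    v <- switch(vector_kind,
      principal_axis = {
        X <- fr[ids, , drop = FALSE]
        w <- topo$mass[ids]
        mu <- colSums(X * w) / sum(w)
        Xc <- sweep(X, 2, mu)
        S <- t(Xc * w) %*% Xc / sum(w)
        eigen(S, symmetric = TRUE)$vectors[, 1]
      },
      dipole = dipole_moment(fr, sel, topo),
      end_to_end = fr[ids[length(ids)], ] - fr[ids[1], ])
    nv <- .vnorm(v)
    .assert(nv > 1e-12, "bindfe_degenerate_vector_error",
            sprintf("zero-length %s vector", vector_kind))
    ref <- if (reference == "x_axis") c(1, 0, 0) else {
      .assert(!is.null(partner_sel), "bindfe_input_error",
              "partner_sel required for com_vector reference")
      u <- center_of_mass(fr, sel, topo) -
        center_of_mass(fr, partner_sel, topo)
      u / .vnorm(u)
    }
    ang <- acos(min(1, max(-1, sum(v * ref) / (nv * .vnorm(ref)))))
    if (vector_kind == "principal_axis") min(ang, pi - ang) else ang
  }, numeric(1))
  bin_angles(omega, edges)
}

#' Total variation distance between two discretized angle distributions
#'
#' DTV = sum over shared bins of |P - P_ref|.  Note this is twice the
#' conventional total variation distance: it ranges from 0 (identical) to 2
#' (disjoint support), the normalization used throughout the package.
#'
#' @param P,P_ref two [angle_distribution()]s on identical bin edges.
#' @return DTV in `[0, 2]`.
#' @export
total_variation_distance <- function(P, P_ref) {
  .assert(length(P$edges) == length(P_ref$edges) &&
            all(abs(P$edges - P_ref$edges) < 1e-12),
          "bindfe_input_error", "distributions must share bin edges")
  sum(abs(P$probs - P_ref$probs))
}

## Native contacts, hydrogen bonds, RMSD, helicity ------------------------

#' Soft-cutoff fraction of native contacts
#'
#' Native inter-partner heavy-atom pairs are identified in the native frame
#' within `native_cutoff`; for a query frame the soft fraction is
#' Q = (1/|S|) sum 1/(1 + exp(beta_q (r_ij - lambda r_ij0))).
#'
#' @param frame query Nx3 coordinate matrix.
#' @param native_frame reference Nx3 coordinate matrix.
#' @param selA,selB partner selections (hydrogens excluded by default
#'   selection mode).
#' @param topology the [topology()].
#' @param beta_q sigmoid steepness, 1/Angstrom (default 5.0).
#' @param lam contact-width multiplier (default 1.8).
#' @param native_cutoff pair-list cutoff in the native frame, Angstrom
#'   (default 4.5).
#' @return Q in `(0, 1)`.
#' @export
native_contacts_q <- function(frame, native_frame, selA, selB, topology,
                              beta_q = 5.0, lam = 1.8, native_cutoff = 4.5) {
  idsA <- resolve_selection(selA, topology) + 1L
  idsB <- resolve_selection(selB, topology) + 1L
  A0 <- native_frame[idsA, , drop = FALSE]
  B0 <- native_frame[idsB, , drop = FALSE]
  d0 <- sqrt(pmax(outer(rowSums(A0^2), rowSums(B0^2), "+") - 2 * A0 %*% t(B0), 0))
  pairs <- which(d0 <= native_cutoff, arr.ind = TRUE)
  .assert(nrow(pairs) >= 1L, "bindfe_input_error",
          "no native inter-partner pairs within cutoff")
  A <- frame[idsA, , drop = FALSE]
  B <- frame[idsB, , drop = FALSE]
  r <- sqrt(rowSums((A[pairs[, 1], , drop = FALSE] -
                       B[pairs[, 2], , drop = FALSE])^2))
  r0 <- d0[pairs]
  mean(1 / (1 + exp(beta_q * (r - lam * r0))))
}

#' Hydrogen bonds per peptide residue
#'
#' Counts donor-acceptor pairs with |D-A| <= `d_cut` and donor-hydrogen-
#' acceptor angle >= `angle_cut`; bonds are attributed to the peptide residue
#' of their donor (or acceptor when the donor is not on the peptide) and the
#' counts are averaged over all peptide residues.
#'
#' @param frame Nx3 coordinate matrix.
#' @param topology the [topology()].
#' @param donors data frame with zero-based columns `donor` and `hydrogen`.
#' @param acceptors zero-based acceptor atom ids.
#' @param peptide_residues residue indices of the peptide over which the
#'   average is taken.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 4.0).
#' @param angle_cut D-H-A angle cutoff in degrees (default 120).
#' @return Mean hydrogen-bond count per peptide residue.
#' @export
hydrogen_bonds_per_residue <- function(frame, topology, donors, acceptors,
                                       peptide_residues, d_cut = 4.0,
                                       angle_cut = 120) {
  .assert(nrow(donors) >= 1L && length(acceptors) >= 1L, "bindfe_input_error",
          "need donors and acceptors")
  .assert(all(topology$is_hydrogen[donors$hydrogen + 1L]),
          "bindfe_topology_error", "donor 'hydrogen' atoms must be hydrogens")
  counts <- setNames(rep(0, length(peptide_residues)),
                     as.character(peptide_residues))
  pep <- topology$residue_index %in% peptide_residues
  for (i in seq_len(nrow(donors))) {
    D <- donors$donor[i] + 1L; H <- donors$hydrogen[i] + 1L
    for (Araw in acceptors) {
      A <- Araw + 1L
      if (A == D) next
      if (.vnorm(frame[D, ] - frame[A, ]) > d_cut) next
      ang <- angle_points(frame[D, ], frame[H, ], frame[A, ]) * 180 / pi
      if (ang < angle_cut) next
      res <- if (pep[D]) topology$residue_index[D]
             else if (pep[A]) topology$residue_index[A] else next
      key <- as.character(res)
      counts[key] <- counts[key] + 1
    }
  }
  mean(counts)
}

.kabsch_rotation <- function(P, Q) {
  # rotation R minimizing ||P R - Q|| for row-vector coordinates
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation between two frames
#'
#' With `fit = TRUE` the optimal-rotation (Kabsch) least-squares RMSD after
#' centering; with `fit = FALSE` the raw coordinate RMSD in the frames'
#' current superposition.
#'
#' @param frame,ref_frame Nx3 coordinate matrices with equal atom counts.
#' @param sel optional selection restricting the comparison (requires
#'   `topology`).
#' @param topology needed only when `sel` is given.
#' @param fit superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, ref_frame, sel = NULL, topology = NULL, fit = TRUE) {
  if (!is.null(sel)) {
    ids <- resolve_selection(sel, topology) + 1L
    frame <- frame[ids, , drop = FALSE]
    ref_frame <- ref_frame[ids, , drop = FALSE]
  }
  .assert(nrow(frame) == nrow(ref_frame), "bindfe_input_error",
          "atom counts differ")
  if (fit) {
    P <- sweep(frame, 2, colMeans(frame))
    Q <- sweep(ref_frame, 2, colMeans(ref_frame))
    R <- .kabsch_rotation(P, Q)
    frame <- P %*% R
    ref_frame <- Q
  }
  sqrt(mean(rowSums((frame - ref_frame)^2)))
}

#' Superpose a frame onto a reference by fitting a sub-selection
#'
#' Least-squares fit of `fit_sel` atoms, with the resulting rigid transform
#' applied to the whole frame.
#'
#' @param frame,ref_frame Nx3 coordinate matrices.
#' @param fit_sel selection defining the fit atoms.
#' @param topology the [topology()].
#' @return The transformed Nx3 frame.
#' @export
superpose_on <- function(frame, ref_frame, fit_sel, topology) {
  ids <- resolve_selection(fit_sel, topology) + 1L
  P <- frame[ids, , drop = FALSE]
  Q <- ref_frame[ids, , drop = FALSE]
  cP <- colMeans(P); cQ <- colMeans(Q)
  R <- .kabsch_rotation(sweep(P, 2, cP), sweep(Q, 2, cQ))
  sweep(sweep(frame, 2, cP) %*% R, 2, cQ, "+")
}

#' Orientational RMSD of the peptide after receptor superposition
#'
#' Every frame is superposed onto the reference complex by fitting the
#' receptor atoms only; the peptide RMSD is then measured without any further
#' rotational alignment, so it reports both displacement and misorientation
#' of the peptide relative to its pose in the complex.
#'
#' @param traj a [trajectory()].
#' @param complex_ref reference complex frame (Nx3).
#' @param receptor_sel,peptide_sel partner selections.
#' @return Numeric vector of per-frame orientational RMSDs (Angstrom).
#' @export
orientational_rmsd <- function(traj, complex_ref, receptor_sel, peptide_sel) {
  topo <- traj$topology
  vapply(traj$frames, function(fr) {
    fitted <- superpose_on(fr, complex_ref, receptor_sel, topo)
    rmsd(fitted, complex_ref, peptide_sel, topo, fit = FALSE)
  }, numeric(1))
}

#' Dihedral-based helicity of a peptide
#'
#' Backbone (phi, psi) dihedrals are computed from N/CA/C atoms; a residue is
#' alpha-helical when phi lies in `[-100, -30]` degrees and psi in
#' `[-67, -7]` degrees, and only runs of at least `min_run` consecutive
#' helical residues count.  Returns the helical fraction over residues with
#' defined (phi, psi), averaged over frames.
#'
#' @param traj a [trajectory()].
#' @param residues residue indices of the peptide (in chain order).
#' @param min_run minimum helical run length (default 3).
#' @return Helical fraction in `[0, 1]`.
#' @export
helicity <- function(traj, residues, min_run = 3) {
  topo <- traj$topology
  idx <- function(res, nm) {
    i <- which(topo$residue_index == res & topo$name == nm)
    .assert(length(i) == 1L, "bindfe_topology_error",
            sprintf("backbone atom %s missing in residue %d", nm, res))
    i
  }
  nres <- length(residues)
  per_frame <- vapply(traj$frames, function(fr) {
    helical <- rep(FALSE, nres)
    defined <- rep(FALSE, nres)
    for (j in seq_len(nres)) {
      if (j == 1L || j == nres) next   # phi/psi need both neighbours
      res <- residues[j]
      prevC <- idx(residues[j - 1], "C")
      nextN <- idx(residues[j + 1], "N")
      Ni <- idx(res, "N"); CAi <- idx(res, "CA"); Ci <- idx(res, "C")
      phi <- dihedral_points(fr[prevC, ], fr[Ni, ], fr[CAi, ], fr[Ci, ]) * 180 / pi
      psi <- dihedral_points(fr[Ni, ], fr[CAi, ], fr[Ci, ], fr[nextN, ]) * 180 / pi
      defined[j] <- TRUE
      helical[j] <- phi >= -100 && phi <= -30 && psi >= -67 && psi <= -7
    }
    # keep only runs of >= min_run
    r <- rle(helical)
    r$values <- r$values & r$lengths >= min_run
    keep <- inverse.rle(r)
    if (!any(defined)) return(0)
    sum(keep & defined) / sum(defined)
  }, numeric(1))
  mean(per_frame)
}

#' Tabulate a statistic against window centers
#'
#' @param centers window centers r_i (strictly monotone, Angstrom).
#' @param values statistic values, aligned with `centers`.
#' @param stderr per-window standard errors (default 0).
#' @param statistic_id label for the statistic.
#' @return An object of class `bindfe_op_profile` (a data frame, sorted by
#'   decreasing r as the profiles are read during association).
#' @export
order_parameter_profile <- function(centers, values, stderr = 0,
                                    statistic_id = "statistic") {
  .assert(length(centers) == length(values), "bindfe_input_error",
          "centers and values lengths differ")
  d <- diff(sort(centers))
  .assert(all(d > 0), "bindfe_input_error", "window centers must be distinct")
  df <- data.frame(r = centers, value = values,
                   stderr = rep_len(stderr, length(centers)))
  df <- df[order(-df$r), ]
  rownames(df) <- NULL
  attr(df, "statistic_id") <- statistic_id
  class(df) <- c("bindfe_op_profile", "data.frame")
  df
}
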