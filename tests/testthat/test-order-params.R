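make_two_group_topology <- function(nA, nB, chargesA = 0, chargesB = 0) {
  topology(name = c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB))),
           residue_index = c(rep(1, nA), rep(2, nB)),
           residue_name = c(rep("GRA", nA), rep("GRB", nB)),
           chain_id = c(rep("A", nA), rep("B", nB)),
           mass = rep(12, nA + nB),
           charge = c(rep_len(chargesA, nA), rep_len(chargesB, nB)),
           element = rep("C", nA + nB))
}

test_that("closest contacts match hand values and a brute-force oracle", {
  topo <- make_two_group_topology(2, 2)
  selA <- atom_selection(chain_id = "A"); selB <- atom_selection(chain_id = "B")
  f1 <- rbind(c(0, 0, 0), c(10, 0, 0), c(3.7, 0, 0), c(20, 0, 0))
  tr1 <- trajectory(topo, f1)
  expect_equal(unname(mean_closest_contact(tr1, selA, selB)), c(3.7, 0))

  f2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(2, 0, 0), c(20, 0, 0))
  f3 <- rbind(c(0, 0, 0), c(10, 0, 0), c(4, 0, 0), c(20, 0, 0))
  tr2 <- trajectory(topo, list(f2, f3))
  expect_equal(unname(mean_closest_contact(tr2, selA, selB)), c(3, 1))

  set.seed(2)
  topo_r <- make_two_group_topology(7, 9)
  frames <- lapply(1:5, function(i) matrix(rnorm(16 * 3, sd = 5), 16, 3))
  tr <- trajectory(topo_r, frames)
  got <- closest_contact_series(tr, atom_selection(chain_id = "A"),
                                atom_selection(chain_id = "B"))
  oracle <- vapply(frames, function(fr) {
    best <- Inf
    for (i in 1:7) for (j in 8:16)
      best <- min(best, sqrt(sum((fr[i, ] - fr[j, ])^2)))
    best
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("contact frequency counts frames below the cutoff", {
  topo <- make_two_group_topology(1, 1)
  selA <- atom_selection(chain_id = "A"); selB <- atom_selection(chain_id = "B")
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  dists <- c(1, 2, 3, 3.9, 4.5, 5, 6, 7, 8, 9)   # 4 of 10 within 4 A
  tr <- trajectory(topo, lapply(dists, mk))
  expect_equal(contact_frequency(tr, selA, selB), 0.4)
  expect_equal(contact_frequency(trajectory(topo, lapply(c(1, 2), mk)),
                                 selA, selB), 1)
  expect_equal(contact_frequency(trajectory(topo, lapply(c(9, 8), mk)),
                                 selA, selB), 0)
})

test_that("dipole moment matches hand values and the origin-shift identity", {
  topo <- make_two_group_topology(2, 0, chargesA = c(1, -1))
  frame <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(dipole_moment(frame, atom_selection(chain_id = "A"), topo),
               c(2, 0, 0))

  frame0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(dipole_moment(frame0, atom_selection(chain_id = "A"), topo),
               c(0, 0, 0))

  # net +9e system: shifting the origin by d changes the dipole by -9 d
  topo9 <- topology(name = sprintf("C%d", 1:9), residue_index = 1:9,
                    residue_name = "X", mass = rep(12, 9), charge = rep(1, 9))
  set.seed(4)
  fr <- matrix(rnorm(27), 9, 3)
  d <- c(0.5, -1, 2)
  base <- dipole_moment(fr, 0:8, topo9, origin = c(0, 0, 0))
  shifted <- dipole_moment(fr, 0:8, topo9, origin = d)
  expect_equal(shifted - base, -9 * d, tolerance = 1e-10)
})

test_that("dipole projection profile respects the sign convention", {
  # positive charge displaced toward the receptor => negative projection
  topo <- topology(name = c("R1", "DP", "DM"), residue_index = 1:3,
                   residue_name = c("NUC", "PEP", "PEP"),
                   chain_id = c("R", "P", "P"), mass = c(12, 12, 12),
                   charge = c(-1, 1, -1), element = rep("C", 3))
  selR <- atom_selection(chain_id = "R"); selP <- atom_selection(chain_id = "P")
  frame <- rbind(c(0, 0, 0), c(19, 0, 0), c(21, 0, 0))  # + bead nearer RNA
  tr <- trajectory(topo, replicate(8, frame, simplify = FALSE))
  prof <- dipole_projection_profile(tr, selR, selP, step = 2, window = 4)
  expect_true(all(prof$value < 0))
  expect_equal(prof$value, rep(prof$value[1], nrow(prof)))  # constant geometry
  expect_equal(abs(prof$value[1]), 2)  # |d| = 1e * 2 A along the axis
  expect_error(dipole_projection_profile(tr, selR, selP, window = 100),
               class = "bindfe_input_error")
})

test_that("orientation angle histograms behave for rods and isotropy", {
  tr <- generate_orientation_ensemble(kappa = 0, n_frames = 3000, seed = 12)
  selP <- atom_selection(chain_id = "P"); selR <- atom_selection(chain_id = "R")
  P_iso <- orientation_angles(tr, selP, "end_to_end", "com_vector",
                              partner_sel = selR)
  expect_lt(total_variation_distance(P_iso, isotropic_reference()), 0.15)

  # all frames identical: a single occupied bin
  tr1 <- trajectory(tr$topology, tr$frames[rep(1, 5)])
  P1 <- orientation_angles(tr1, selP, "end_to_end", "com_vector",
                           partner_sel = selR)
  expect_equal(sum(P1$probs > 0), 1L)

  # a rod along the COM vector has folded principal-axis angle ~ 0
  tr_rod <- generate_orientation_ensemble(kappa = 400, n_frames = 500, seed = 3)
  P_rod <- orientation_angles(tr_rod, selP, "principal_axis", "com_vector",
                              partner_sel = selR)
  expect_gt(sum(P_rod$probs[P_rod$edges[-1] <= pi / 6]), 0.95)
})

test_that("total variation distance has the documented normalization", {
  e <- seq(0, pi, length.out = 4)
  P <- angle_distribution(e, c(0.5, 0.5, 0))
  Q <- angle_distribution(e, c(0.25, 0.25, 0.5))
  expect_equal(total_variation_distance(P, Q), 1.0)
  expect_equal(total_variation_distance(P, P), 0)
  D <- angle_distribution(e, c(0, 0, 1))
  expect_equal(total_variation_distance(P, D), 2)

  e2 <- seq(0, pi, length.out = 5)
  expect_error(total_variation_distance(P, angle_distribution(e2, rep(0.25, 4))),
               class = "bindfe_input_error")

  # symmetry and triangle inequality on the half scale
  set.seed(14)
  for (i in 1:10) {
    p <- diff(sort(c(0, runif(2), 1))); q <- diff(sort(c(0, runif(2), 1)))
    s <- diff(sort(c(0, runif(2), 1)))
    Pp <- angle_distribution(e, p); Qq <- angle_distribution(e, q)
    Ss <- angle_distribution(e, s)
    expect_equal(total_variation_distance(Pp, Qq),
                 total_variation_distance(Qq, Pp))
    expect_lte(total_variation_distance(Pp, Qq) / 2,
               total_variation_distance(Pp, Ss) / 2 +
                 total_variation_distance(Ss, Qq) / 2 + 1e-12)
    expect_gte(total_variation_distance(Pp, Qq), 0)
    expect_lte(total_variation_distance(Pp, Qq), 2)
  }
})

test_that("native contacts follow the soft-cutoff model", {
  topo <- make_two_group_topology(3, 3)
  selA <- atom_selection(chain_id = "A"); selB <- atom_selection(chain_id = "B")
  native <- rbind(c(0, 0, 0), c(0, 6, 0), c(0, 12, 0),
                  c(3, 0, 0), c(3, 6, 0), c(3, 12, 0))
  # only the three 3.0-A pairs fall inside the 4.5-A native cutoff
  q_native <- native_contacts_q(native, native, selA, selB, topo)
  expect_gt(q_native, 0.9)
  expect_equal(q_native, 1 / (1 + exp(5 * (3 - 1.8 * 3))), tolerance = 1e-9)

  scaled <- native * 1.8      # every pair at exactly lambda * r0
  expect_equal(native_contacts_q(scaled, native, selA, selB, topo), 0.5,
               tolerance = 1e-9)

  apart <- native; apart[4:6, 1] <- apart[4:6, 1] + 100
  expect_lt(native_contacts_q(apart, native, selA, selB, topo), 1e-6)

  # monotone non-increasing under uniform scaling s >= 1
  qs <- vapply(c(1, 1.2, 1.5, 2, 3), function(s)
    native_contacts_q(native * s, native, selA, selB, topo), numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("hydrogen bonds respect distance and angle cutoffs", {
  topo <- topology(name = c("N", "H", "O"), residue_index = c(1, 1, 2),
                   residue_name = c("RES", "RES", "ACC"),
                   chain_id = c("P", "P", "R"),
                   mass = c(14, 1, 16), element = c("N", "H", "O"))
  donors <- data.frame(donor = 0, hydrogen = 1)
  lin <- function(dDA) rbind(c(0, 0, 0), c(1, 0, 0), c(dDA, 0, 0))
  expect_equal(hydrogen_bonds_per_residue(lin(2.9), topo, donors, 2, 1), 1)
  expect_equal(hydrogen_bonds_per_residue(lin(4.5), topo, donors, 2, 1), 0)

  # 100-degree D-H-A angle fails the 120-degree cutoff
  ang <- 100 * pi / 180
  A <- c(1, 0, 0) + 1.9 * c(cos(pi - ang), sin(pi - ang), 0)
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), A)
  expect_equal(hydrogen_bonds_per_residue(bent, topo, donors, 2, 1), 0)

  # 19-residue chain with 3 bonds averages to 3/19
  n <- 19
  topo19 <- topology(name = rep(c("N", "H"), n), residue_index = rep(1:n, each = 2),
                     residue_name = "RES", chain_id = "P",
                     mass = rep(c(14, 1), n), element = rep(c("N", "H"), n))
  acc_topo <- topology(name = "O", residue_index = n + 1, residue_name = "ACC",
                       chain_id = "R", mass = 16, element = "O")
  full <- rbind(topo19, acc_topo)
  class(full) <- c("bindfe_topology", "data.frame")
  full$atom_id <- seq_len(nrow(full)) - 1L
  frame <- matrix(0, 2 * n + 1, 3)
  for (i in 1:n) {
    frame[2 * i - 1, ] <- c(10 * i, 0, 0)        # N
    frame[2 * i, ] <- c(10 * i + 1, 0, 0)        # H
  }
  frame[2 * n + 1, ] <- c(10 * 2 + 2.9, 0, 0)    # acceptor near residue 2 only
  donors3 <- data.frame(donor = c(2, 2, 2), hydrogen = c(3, 3, 3))
  # one donor triple hit by three acceptor copies = 3 bonds on residue 2
  got <- hydrogen_bonds_per_residue(frame, full, donors3, 2 * n, 1:n)
  expect_equal(got, 3 / 19, tolerance = 1e-12)
})

test_that("RMSD agrees with rigid motions and a quaternion oracle", {
  set.seed(15)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(rmsd(X, X), 0, tolerance = 1e-12)

  Xt <- sweep(X, 2, c(3, 4, 0), "+")
  expect_equal(rmsd(Xt, X, fit = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd(Xt, X, fit = FALSE), 5, tolerance = 1e-9)

  tf <- random_rigid_transform()
  expect_lt(rmsd(apply_rigid(X, tf), X, fit = TRUE), 1e-9)

  # quaternion (Horn) oracle for optimal-rotation RMSD
  quat_rmsd <- function(P, Q) {
    P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
    M <- t(P) %*% Q
    Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
    Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
    Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
    K <- matrix(c(
      Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
      Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
      Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
      Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4)
    lam <- max(eigen(K, symmetric = TRUE)$values)
    sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam)) / nrow(P))
  }
  for (i in 1:5) {
    Y <- X + matrix(rnorm(30, sd = 0.8), 10, 3)
    expect_equal(rmsd(Y, X, fit = TRUE), quat_rmsd(Y, X), tolerance = 1e-9)
  }
})

test_that("orientational RMSD reports misorientation after receptor fit", {
  set.seed(16)
  topo <- make_two_group_topology(6, 5)
  selA <- atom_selection(chain_id = "A")   # receptor
  selB <- atom_selection(chain_id = "B")   # peptide
  ref <- matrix(rnorm(33, sd = 4), 11, 3)
  expect_equal(orientational_rmsd(trajectory(topo, ref), ref, selA, selB), 0,
               tolerance = 1e-9)

  # rotate the peptide 180 degrees about z through its own COM
  rot <- ref
  pep <- 7:11
  comB <- colMeans(ref[pep, ])
  Rz <- diag(c(-1, -1, 1))
  rot[pep, ] <- sweep(sweep(ref[pep, ], 2, comB) %*% Rz, 2, comB, "+")
  hand <- sqrt(mean(rowSums((rot[pep, ] - ref[pep, ])^2)))
  expect_equal(orientational_rmsd(trajectory(topo, rot), ref, selA, selB),
               hand, tolerance = 1e-9)

  # always >= best-fit peptide RMSD
  for (i in 1:5) {
    fr <- ref + matrix(rnorm(33, sd = 1), 11, 3)
    o <- orientational_rmsd(trajectory(topo, fr), ref, selA, selB)
    best <- rmsd(fr, ref, selB, topo, fit = TRUE)
    expect_gte(o, best - 1e-9)
  }
})

test_that("dihedral-run helicity classifies canonical conformations", {
  n <- 8
  topo <- backbone_topology(n)
  helix <- build_backbone(rep(-57 * pi / 180, n), rep(-47 * pi / 180, n))
  expect_equal(helicity(trajectory(topo, helix), 1:n), 1)

  ext <- build_backbone(rep(-120 * pi / 180, n), rep(120 * pi / 180, n))
  expect_equal(helicity(trajectory(topo, ext), 1:n), 0)

  half <- build_backbone(c(rep(-57, 4), rep(-120, 4)) * pi / 180,
                         c(rep(-47, 4), rep(120, 4)) * pi / 180)
  expect_equal(helicity(trajectory(topo, half), 1:n), 0.5)

  # an isolated helical residue (run < 3) does not count
  lone <- build_backbone(c(-120, -120, -57, -120, -120, -120, -120, -120) * pi / 180,
                         c(120, 120, -47, 120, 120, 120, 120, 120) * pi / 180)
  expect_equal(helicity(trajectory(topo, lone), 1:n), 0)
})

test_that("bounded statistics are invariant under rigid transforms", {
  set.seed(17)
  topo <- make_two_group_topology(5, 4, chargesA = c(1, 0, -1, 1, 0))
  selA <- atom_selection(chain_id = "A"); selB <- atom_selection(chain_id = "B")
  frames <- lapply(1:4, function(i) matrix(rnorm(27, sd = 3), 9, 3))
  tr <- trajectory(topo, frames)
  tf <- random_rigid_transform()
  tr2 <- trajectory(topo, lapply(frames, apply_rigid, tf = tf))

  expect_equal(closest_contact_series(tr, selA, selB),
               closest_contact_series(tr2, selA, selB), tolerance = 1e-9)
  expect_equal(contact_frequency(tr, selA, selB, 5),
               contact_frequency(tr2, selA, selB, 5))
  q1 <- native_contacts_q(frames[[2]], frames[[1]], selA, selB, topo,
                          native_cutoff = 8)
  q2 <- native_contacts_q(apply_rigid(frames[[2]], tf),
                          apply_rigid(frames[[1]], tf), selA, selB, topo,
                          native_cutoff = 8)
  expect_equal(q1, q2, tolerance = 1e-9)
  expect_true(q1 >= 0 && q1 <= 1)
})
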