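# Shared fixture builders; everything is generated in code at test time.

kB <- k_boltzmann()

water_fixture <- function() {
  topo <- topology(name = c("O", "H1", "H2"), residue_index = c(1, 1, 1),
                   residue_name = "HOH")
  frame <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  list(topology = topo, frame = frame)
}

# peptide backbone (N, CA, C per residue) built from prescribed (phi, psi)
# by NeRF placement with ideal bond geometry
build_backbone <- function(phis, psis) {
  n <- length(phis)
  coords <- matrix(NA_real_, 3 * n, 3)
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(1.458, 0, 0)
  coords[3, ] <- place_from_internal(c(-1, 1, 0), coords[1, ], coords[2, ],
                                     1.525, 111 * pi / 180, 0)
  for (i in 2:n) {
    b <- 3 * (i - 1)
    coords[b + 1, ] <- place_from_internal(coords[b - 2, ], coords[b - 1, ],
                                           coords[b, ], 1.329,
                                           117 * pi / 180, psis[i - 1])
    coords[b + 2, ] <- place_from_internal(coords[b - 1, ], coords[b, ],
                                           coords[b + 1, ], 1.458,
                                           121 * pi / 180, pi)
    coords[b + 3, ] <- place_from_internal(coords[b, ], coords[b + 1, ],
                                           coords[b + 2, ], 1.525,
                                           111 * pi / 180, phis[i])
  }
  coords
}

backbone_topology <- function(n_res) {
  topology(name = rep(c("N", "CA", "C"), n_res),
           residue_index = rep(seq_len(n_res), each = 3),
           residue_name = "ALA", mass = rep(14, 3 * n_res))
}

# six anchor points realizing the scheme's equilibrium internal coordinates
anchors_at_equilibrium <- function(scheme, r = 8) {
  P2 <- c(0, 0, 0); P1 <- c(2, 0, 0)
  P0 <- P1 + 2 * c(cos(1), sin(1), 0)
  Q0 <- place_from_internal(P2, P1, P0, r, scheme$theta0, scheme$phi0)
  Q1 <- place_from_internal(P1, P0, Q0, 3, scheme$Theta0, scheme$Psi0)
  Q2 <- place_from_internal(P0, Q0, Q1, 3, 2.0, scheme$Phi0)
  rbind(P0, P1, P2, Q0, Q1, Q2)
}

anchor_topology <- function() {
  topology(name = rep("C", 6), residue_index = 1:6, residue_name = "ANC",
           mass = rep(12, 6))
}

default_scheme <- function(k = 100, convention = "full") {
  restraint_scheme(P0 = 0, P1 = 1, P2 = 2, Q0 = 3, Q1 = 4, Q2 = 5,
                   Theta0 = 2.53, Phi0 = 2.7, Psi0 = -3.13,
                   theta0 = 1.49, phi0 = -2.88, k = k,
                   convention = convention)
}

random_rigid_transform <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 5))
}

apply_rigid <- function(frame, tf) sweep(frame %*% tf$R, 2, tf$t, "+")

# discretized isotropic reference on the standard 5-degree edges
isotropic_reference <- function(edges = seq(0, pi, by = 5 * pi / 180)) {
  angle_distribution(edges, diff((1 - cos(edges)) / 2))
}

# single-bead reduction of the toy complex (central potential), used by the
# end-to-end restraint-ledger consistency check
single_bead_spec <- function() {
  toy_complex_spec(chain_length = 1, chain_charges = 2,
                   scaffold_coords = matrix(0, 1, 3), scaffold_charges = -4,
                   salt_mM = 150, sigma = 3, eps_rep = 1, temperature = 300)
}

# axial restraint energy series of the single ligand bead of a toy trajectory
axial_restraint_series <- function(traj, ar) {
  vapply(seq_len(n_frames(traj)), function(i) {
    v <- traj$frames[[i]][1, ]
    r <- sqrt(sum(v^2))
    th <- acos(max(-1, min(1, v[3] / r)))
    ph <- atan2(v[2], v[1])
    pre <- if (identical(ar$convention, "half")) 0.5 else 1
    pre * ar$k * ((th - ar$theta0)^2 + wrap_angle(ph - ar$phi0)^2)
  }, numeric(1))
}
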