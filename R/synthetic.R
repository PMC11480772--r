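## Seeded synthetic-data generators ---------------------------------------

.generator_version <- "1.0"

#' Define an analytic 1-D potential
#'
#' @param form one of `"harmonic"` (params `k`, `x0`; U = (k/2)(x-x0)^2),
#'   `"double_well"` (params `barrier`, `width`; U = barrier ((x/width)^2 -
#'   1)^2), `"screened_coulomb"` (params `q1q2`, `lambda`, `epsilon`, `sigma`,
#'   `eps_rep`; U(r) = 332.0637 q1q2 exp(-r/lambda)/(epsilon r) + eps_rep
#'   (sigma/r)^8), or `"polynomial"` (param `coefficients`, ascending powers).
#' @param ... named parameters for the chosen form.
#' @return An object of class `bindfe_potential` with `fn` and `grad`
#'   callables.
#' @export
analytic_potential <- function(form = c("harmonic", "double_well",
                                        "screened_coulomb", "polynomial"),
                               ...) {
  form <- match.arg(form)
  p <- list(...)
  get_par <- function(nm, default) if (!is.null(p[[nm]])) p[[nm]] else default
  obj <- switch(form,
    harmonic = {
      k <- get_par("k", 1); x0 <- get_par("x0", 0)
      list(fn = function(x) 0.5 * k * (x - x0)^2,
           grad = function(x) k * (x - x0))
    },
    double_well = {
      h <- get_par("barrier", 1); w <- get_par("width", 1)
      list(fn = function(x) h * ((x / w)^2 - 1)^2,
           grad = function(x) h * 4 * ((x / w)^2 - 1) * x / w^2)
    },
    screened_coulomb = {
      q <- get_par("q1q2", -1); lam <- get_par("lambda", 8)
      epsr <- get_par("epsilon", 80)
      sig <- get_par("sigma", 3); er <- get_par("eps_rep", 1)
      list(fn = function(r) .KE * q * exp(-r / lam) / (epsr * r) +
             er * (sig / r)^8,
           grad = function(r) -.KE * q * exp(-r / lam) / (epsr * r) *
             (1 / lam + 1 / r) - 8 * er * sig^8 / r^9)
    },
    polynomial = {
      co <- get_par("coefficients", c(0, 0, 1))
      list(fn = function(x) {
             out <- 0
             for (i in seq_along(co)) out <- out + co[i] * x^(i - 1)
             out
           },
           grad = function(x) {
             out <- 0
             for (i in seq_along(co)[-1]) out <- out + (i - 1) * co[i] * x^(i - 2)
             out
           })
    })
  structure(c(obj, list(form = form, params = p)),
            class = "bindfe_potential")
}

.as_potential_fn <- function(potential) {
  if (inherits(potential, "bindfe_potential")) potential$fn
  else { .assert(is.function(potential), "bindfe_input_error",
                 "potential must be a function or analytic_potential")
         potential }
}

#' Metropolis sampler on a 1-D potential (optionally biased)
#'
#' Markov chain targeting exp(-beta (U + U_bias)) with Gaussian displacement
#' proposals; fully reproducible given `seed`.  The realized acceptance rate
#' is attached as an attribute and a tuning warning is emitted when it falls
#' outside `[0.05, 0.95]`.
#'
#' @param potential a function of x or an [analytic_potential()].
#' @param bias an optional [bias_potential()].
#' @param n_steps chain length (post burn-in).
#' @param step_size proposal standard deviation (> 0).
#' @param temperature temperature in K.
#' @param seed integer RNG seed.
#' @param x0 starting coordinate (default: bias center, else 0).
#' @param burn_in discarded initial steps (default `n_steps %/% 10`).
#' @return Numeric sample vector with attributes `acceptance_rate` and
#'   `seed`.
#' @export
metropolis_sample <- function(potential, bias = NULL, n_steps = 1000,
                              step_size = 0.5, temperature = 300, seed = 1,
                              x0 = NULL, burn_in = NULL) {
  .assert(step_size > 0, "bindfe_input_error", "step_size must be > 0")
  if (is.null(burn_in)) burn_in <- n_steps %/% 10L
  fn <- .as_potential_fn(potential)
  energy <- if (is.null(bias)) fn else function(x) fn(x) + bias_energy(bias, x)
  beta <- .beta(temperature)
  if (is.null(x0)) x0 <- if (!is.null(bias)) bias$center else 0
  total <- n_steps + burn_in
  set.seed(seed)
  prop <- rnorm(total, 0, step_size)
  u <- runif(total)
  out <- numeric(total)
  x <- x0; e <- energy(x); acc <- 0L
  for (i in seq_len(total)) {
    xn <- x + prop[i]
    en <- energy(xn)
    if (u[i] < exp(-beta * (en - e))) { x <- xn; e <- en; acc <- acc + 1L }
    out[i] <- x
  }
  rate <- acc / total
  if (rate < 0.05 || rate > 0.95)
    warning(sprintf("Metropolis acceptance rate %.3f outside [0.05, 0.95]; tune step_size", rate))
  res <- out[(burn_in + 1L):total]
  attr(res, "acceptance_rate") <- rate
  attr(res, "seed") <- seed
  res
}

.truth_pmf_grid <- function(potential, lo, hi, n = 1001) {
  fn <- .as_potential_fn(potential)
  grid <- seq(lo, hi, length.out = n)
  U <- fn(grid)
  list(grid = grid, pmf = U - min(U))
}

#' Generate a seeded umbrella-sampling dataset on an analytic potential
#'
#' One Metropolis chain per window, each biased harmonically at its center;
#' the analytic ground-truth PMF is attached so every downstream estimator
#' can be scored.
#'
#' @param potential a function or [analytic_potential()].
#' @param centers monotone window centers.
#' @param k_bias bias force constant.
#' @param convention bias convention, `"full"` (U = k d^2) or `"half"`.
#' @param n_per_window samples per window.
#' @param temperature temperature in K.
#' @param seed integer master seed (window w uses `seed + w`).
#' @param step_size proposal width (default: matched to the bias stiffness).
#' @return A list of class `bindfe_synth_dataset` with `windows` (an
#'   [umbrella_window_set()]), `ground_truth` (`grid`, `pmf`), and
#'   `generator` provenance.
#' @export
generate_umbrella_dataset <- function(potential, centers, k_bias,
                                      convention = "full",
                                      n_per_window = 5000, temperature = 300,
                                      seed = 1, step_size = NULL) {
  .assert(all(diff(centers) > 0) || all(diff(centers) < 0),
          "bindfe_input_error", "centers must be monotone")
  beta <- .beta(temperature)
  keff <- if (convention == "half") k_bias / 2 else k_bias
  if (is.null(step_size))
    step_size <- if (keff > 0) 1.5 / sqrt(2 * beta * keff) else 1
  biases <- lapply(centers, function(cen)
    bias_potential("harmonic_distance", cen, k_bias, convention))
  samples <- lapply(seq_along(centers), function(w)
    as.numeric(metropolis_sample(potential, biases[[w]], n_per_window,
                                 step_size, temperature, seed = seed + w)))
  windows <- umbrella_window_set(biases, samples, temperature,
                                 coordinate_id = "synthetic", seed = seed)
  pad <- if (length(centers) > 1) abs(diff(range(centers))) * 0.2 else 2
  structure(list(
    windows = windows,
    ground_truth = .truth_pmf_grid(potential, min(centers) - pad,
                                   max(centers) + pad),
    generator = list(version = .generator_version, seed = seed,
                     k_bias = k_bias, convention = convention,
                     n_per_window = n_per_window, temperature = temperature)),
    class = "bindfe_synth_dataset")
}

#' Generate a replica-exchange umbrella dataset
#'
#' All window chains advance in lockstep; every `attempt_interval` sweeps,
#' neighbouring windows attempt to swap configurations with the Metropolis
#' criterion on the cross-bias energy difference (the unbiased potential is
#' shared, so it cancels), which preserves detailed balance in each window.
#' Samples are attributed to the window whose bias generated them.
#'
#' @inheritParams generate_umbrella_dataset
#' @param attempt_interval sweeps between exchange attempts (default 10).
#' @return As [generate_umbrella_dataset()], with an `exchange` element
#'   holding per-pair attempt counts and acceptance rates.
#' @export
generate_hremc_dataset <- function(potential, centers, k_bias,
                                   convention = "full", n_per_window = 5000,
                                   temperature = 300, seed = 1,
                                   attempt_interval = 10, step_size = NULL) {
  .assert(length(centers) >= 2L, "bindfe_input_error", "need >= 2 windows")
  fn <- .as_potential_fn(potential)
  beta <- .beta(temperature)
  keff <- if (convention == "half") k_bias / 2 else k_bias
  if (is.null(step_size))
    step_size <- if (keff > 0) 1.5 / sqrt(2 * beta * keff) else 1
  K <- length(centers)
  biases <- lapply(centers, function(cen)
    bias_potential("harmonic_distance", cen, k_bias, convention))
  set.seed(seed)
  x <- as.numeric(centers)
  e_bias <- vapply(seq_len(K), function(k) bias_energy(biases[[k]], x[k]),
                   numeric(1))
  e_pot <- vapply(x, fn, numeric(1))
  samples <- matrix(NA_real_, n_per_window, K)
  attempts <- numeric(K - 1); accepts <- numeric(K - 1)
  parity <- 0L
  for (sweep in seq_len(n_per_window)) {
    xn <- x + rnorm(K, 0, step_size)
    en_pot <- vapply(xn, fn, numeric(1))
    en_bias <- vapply(seq_len(K), function(k) bias_energy(biases[[k]], xn[k]),
                      numeric(1))
    acc <- runif(K) < exp(-beta * (en_pot + en_bias - e_pot - e_bias))
    x[acc] <- xn[acc]; e_pot[acc] <- en_pot[acc]; e_bias[acc] <- en_bias[acc]
    if (sweep %% attempt_interval == 0L) {
      parity <- 1L - parity
      pairs_start <- if (1L + parity <= K - 1L) seq(1L + parity, K - 1L, by = 2L)
                     else integer(0)
      for (i in pairs_start) {
        j <- i + 1L
        delta <- bias_energy(biases[[i]], x[j]) + bias_energy(biases[[j]], x[i]) -
          e_bias[i] - e_bias[j]
        attempts[i] <- attempts[i] + 1
        if (runif(1) < exp(-beta * delta)) {
          accepts[i] <- accepts[i] + 1
          tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
          tmp <- e_pot[i]; e_pot[i] <- e_pot[j]; e_pot[j] <- tmp
          e_bias[i] <- bias_energy(biases[[i]], x[i])
          e_bias[j] <- bias_energy(biases[[j]], x[j])
        }
      }
    }
    samples[sweep, ] <- x
  }
  windows <- umbrella_window_set(biases,
                                 lapply(seq_len(K), function(k) samples[, k]),
                                 temperature, "synthetic_hremc", seed = seed)
  pad <- abs(diff(range(centers))) * 0.2
  structure(list(
    windows = windows,
    ground_truth = .truth_pmf_grid(potential, min(centers) - pad,
                                   max(centers) + pad),
    exchange = list(attempts = attempts,
                    acceptance = ifelse(attempts > 0, accepts / attempts, NA)),
    generator = list(version = .generator_version, seed = seed,
                     k_bias = k_bias, convention = convention,
                     attempt_interval = attempt_interval,
                     n_per_window = n_per_window, temperature = temperature)),
    class = "bindfe_synth_dataset")
}

## Toy charged-chain / rigid-polyanion complex ----------------------------

.default_chain_charges <- function(n) {
  # mimics an arginine-rich 19-mer: 9 basic (+1), 3 acidic (-1), rest neutral
  if (n == 19) return(c(0, 0, 1, 0, 1, 1, 1, -1, 1, 1, 1, 1, 0, 0, 0, -1, 1, -1, 0))
  ch <- rep(0, n)
  if (n >= 2) ch[seq(2, n, by = 2)] <- 1
  ch
}

.default_scaffold <- function() {
  # 15 rigid beads on a hairpin-like arc, 5 A spacing, net charge -14
  t <- seq(0, pi, length.out = 15)
  coords <- cbind(12 * cos(t), 12 * sin(t), 0)
  charges <- rep(-1, 15); charges[8] <- 0
  list(coords = coords, charges = charges)
}

#' Specify the toy charged-chain / rigid-polyanion complex
#'
#' A flexible bead chain (the "peptide": default 19 beads, 9 basic and 3
#' acidic, net +6e) interacting with a rigid charged scaffold (the
#' "polyanion": default 15 beads on an arc, net -14e) through harmonic bonds,
#' angular stiffness, Debye-screened Coulomb forces and soft-core repulsion.
#'
#' @param chain_length number of chain beads (default 19).
#' @param chain_charges per-bead charges (default basic/acidic pattern).
#' @param bond_length equilibrium bond length, Angstrom (default 3.8).
#' @param bond_k bond force constant, kcal mol^-1 A^-2 (default 40).
#' @param bend_k bending stiffness about the straight chain, kcal mol^-1
#'   rad^-2 (default 2).
#' @param scaffold_coords rigid scaffold coordinates (Mx3) or `NULL` for the
#'   default arc.
#' @param scaffold_charges scaffold charges.
#' @param salt_mM salt concentration in mM (default 150; sets the Debye
#'   length 3.04/sqrt(I[M]) Angstrom).
#' @param dielectric relative dielectric constant (default 80).
#' @param sigma soft-core diameter, Angstrom (default 3.0).
#' @param eps_rep soft-core prefactor, kcal mol^-1 (default 1.0).
#' @param temperature temperature in K (default 300).
#' @param bead_mass bead mass in amu (default 110).
#' @param seed integer seed recorded as provenance in the returned object.
#' @return An object of class `bindfe_toy_spec`.
#' @export
toy_complex_spec <- function(chain_length = 19, chain_charges = NULL,
                             bond_length = 3.8, bond_k = 40, bend_k = 2,
                             scaffold_coords = NULL, scaffold_charges = NULL,
                             salt_mM = 150, dielectric = 80, sigma = 3.0,
                             eps_rep = 1.0, temperature = 300,
                             bead_mass = 110, seed = 1) {
  if (is.null(chain_charges)) chain_charges <- .default_chain_charges(chain_length)
  .assert(length(chain_charges) == chain_length, "bindfe_input_error",
          "chain_charges length must equal chain_length")
  if (is.null(scaffold_coords)) {
    sc <- .default_scaffold()
    scaffold_coords <- sc$coords
    if (is.null(scaffold_charges)) scaffold_charges <- sc$charges
  }
  scaffold_coords <- as.matrix(scaffold_coords)
  if (is.null(scaffold_charges)) scaffold_charges <- rep(-1, nrow(scaffold_coords))
  .assert(all(is.finite(chain_charges)) && all(is.finite(scaffold_charges)),
          "bindfe_input_error", "charges must be finite")
  structure(list(chain_length = chain_length, chain_charges = chain_charges,
                 bond_length = bond_length, bond_k = bond_k, bend_k = bend_k,
                 scaffold_coords = scaffold_coords,
                 scaffold_charges = scaffold_charges,
                 salt_mM = salt_mM, dielectric = dielectric, sigma = sigma,
                 eps_rep = eps_rep, temperature = temperature,
                 bead_mass = bead_mass, seed = seed),
            class = "bindfe_toy_spec")
}

#' Debye screening length for a 1:1 electrolyte near 300 K
#' @param ionic_strength_M ionic strength in mol/L.
#' @return Debye length in Angstrom (3.04/sqrt(I)).
#' @export
debye_length <- function(ionic_strength_M) 3.04 / sqrt(ionic_strength_M)

#' Topology of a toy-complex specification
#'
#' Chain beads form chain "P" (residues 1..n, atom name "CA"), scaffold beads
#' chain "R" (atom name "P1"); charges and masses are carried so all order
#' parameters apply.
#'
#' @param spec a [toy_complex_spec()].
#' @return A [topology()].
#' @export
toy_complex_topology <- function(spec) {
  n <- spec$chain_length; m <- nrow(spec$scaffold_coords)
  topology(
    name = c(rep("CA", n), rep("P1", m)),
    residue_index = c(seq_len(n), n + seq_len(m)),
    residue_name = c(ifelse(spec$chain_charges > 0, "BSC",
                            ifelse(spec$chain_charges < 0, "ACD", "NEU")),
                     rep("NUC", m)),
    chain_id = c(rep("P", n), rep("R", m)),
    mass = rep(spec$bead_mass, n + m),
    charge = c(spec$chain_charges, spec$scaffold_charges),
    element = c(rep("C", n), rep("P", m))
  )
}

.toy_energy_fns <- function(spec) {
  n <- spec$chain_length
  S <- spec$scaffold_coords
  qs <- spec$scaffold_charges
  qc <- spec$chain_charges
  lam <- debye_length(spec$salt_mM / 1000)
  epsr <- spec$dielectric
  sig <- spec$sigma; er <- spec$eps_rep
  pair_e <- function(r, qq) {
    e <- er * (sig / r)^8
    nz <- qq != 0
    e[nz] <- e[nz] + .KE * qq[nz] * exp(-r[nz] / lam) / (epsr * r[nz])
    e
  }
  chain_pairs <- if (n > 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx[idx[, 2] - idx[, 1] > 1, , drop = FALSE]
  } else matrix(numeric(0), 0, 2)
  energy <- function(X) {
    # X: n x 3 chain coordinates
    e <- 0
    if (n > 1) {
      d <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-n, , drop = FALSE])^2))
      e <- e + sum(spec$bond_k * (d - spec$bond_length)^2)
    }
    if (n > 2 && spec$bend_k > 0) {
      for (j in 2:(n - 1)) {
        th <- angle_points(X[j - 1, ], X[j, ], X[j + 1, ])
        e <- e + spec$bend_k * (th - pi)^2
      }
    }
    if (nrow(chain_pairs) > 0) {
      dv <- X[chain_pairs[, 1], , drop = FALSE] - X[chain_pairs[, 2], , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      e <- e + sum(pair_e(r, qc[chain_pairs[, 1]] * qc[chain_pairs[, 2]]))
    }
    # chain-scaffold
    for (i in seq_len(n)) {
      r <- sqrt(colSums((t(S) - X[i, ])^2))
      e <- e + sum(pair_e(r, qc[i] * qs))
    }
    e
  }
  energy
}

#' Simulate the toy complex under an optional separation bias
#'
#' Evolves the flexible chain in the field of the rigid scaffold with
#' single-bead Metropolis moves (default) or overdamped Euler-Maruyama
#' Langevin dynamics.  An optional harmonic [bias_potential()] acts on the
#' chain-scaffold center-of-mass separation, and an optional axial restraint
#' on the polar/azimuthal direction of the separation vector.
#'
#' @param spec a [toy_complex_spec()].
#' @param bias optional [bias_potential()] on the COM separation (Angstrom).
#' @param n_steps number of Monte Carlo sweeps / Langevin steps.
#' @param seed integer RNG seed (bit-reproducible trajectories).
#' @param method `"metropolis"` (default) or `"langevin"`.
#' @param step_size Metropolis bead displacement scale or Langevin time step
#'   control (target RMS displacement per step, Angstrom).
#' @param save_every store a frame every this many sweeps (default 10).
#' @param x0 optional initial chain coordinates (n x 3); default: straight
#'   chain placed along +z at 1.2x the bias center (or 15 Angstrom).
#' @param axial_restraint optional list(theta0, phi0, k, convention) acting
#'   on the polar/azimuthal angles of the scaffold-to-chain COM vector.
#' @return A [trajectory()] (chain + scaffold beads) with attributes
#'   `separation` (COM separation per saved frame), `acceptance_rate`,
#'   `seed`.
#' @export
simulate_toy_complex <- function(spec, bias = NULL, n_steps = 2000, seed = 1,
                                 method = c("metropolis", "langevin"),
                                 step_size = 0.35, save_every = 10,
                                 x0 = NULL, axial_restraint = NULL) {
  method <- match.arg(method)
  n <- spec$chain_length
  S <- spec$scaffold_coords
  topo <- toy_complex_topology(spec)
  beta <- .beta(spec$temperature)
  energy <- .toy_energy_fns(spec)
  scom <- colMeans(S)   # equal bead masses: scaffold COM is the mean
  restraint_e <- function(com) {
    if (is.null(bias) && is.null(axial_restraint)) return(0)
    v <- com - scom
    r <- .vnorm(v)
    e <- if (!is.null(bias)) bias_energy(bias, r) else 0
    if (!is.null(axial_restraint)) {
      ar <- axial_restraint
      pre <- if (identical(ar$convention, "half")) 0.5 else 1
      th <- acos(min(1, max(-1, v[3] / r)))
      ph <- atan2(v[2], v[1])
      e <- e + pre * ar$k * ((th - ar$theta0)^2 + wrap_angle(ph - ar$phi0)^2)
    }
    e
  }
  if (is.null(x0)) {
    target <- if (!is.null(bias)) bias$center else 15
    dir0 <- if (!is.null(axial_restraint))
      c(sin(axial_restraint$theta0) * cos(axial_restraint$phi0),
        sin(axial_restraint$theta0) * sin(axial_restraint$phi0),
        cos(axial_restraint$theta0))
    else c(0, 0, 1)
    center0 <- scom + target * dir0
    offs <- (seq_len(n) - (n + 1) / 2) * spec$bond_length
    perp <- if (abs(dir0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- perp - sum(perp * dir0) * dir0; perp <- perp / .vnorm(perp)
    x0 <- t(vapply(offs, function(o) center0 + o * perp, numeric(3)))
  }
  X <- as.matrix(x0)
  set.seed(seed)
  frames <- vector("list", n_steps %/% save_every)
  seps <- numeric(length(frames))
  acc <- 0L; tries <- 0L
  e_tot <- energy(X) + restraint_e(colMeans(X))
  if (method == "metropolis") {
    for (sweep in seq_len(n_steps)) {
      for (i in seq_len(n)) {
        Xn <- X
        Xn[i, ] <- X[i, ] + rnorm(3, 0, step_size)
        en <- energy(Xn) + restraint_e(colMeans(Xn))
        tries <- tries + 1L
        if (runif(1) < exp(-beta * (en - e_tot))) {
          X <- Xn; e_tot <- en; acc <- acc + 1L
        }
      }
      if (sweep %% save_every == 0L) {
        k <- sweep %/% save_every
        frames[[k]] <- rbind(X, S)
        seps[k] <- .vnorm(colMeans(X) - scom)
      }
    }
  } else {
    # overdamped Euler-Maruyama; dt is the smaller of the user target
    # (sqrt(2 D dt) = step_size) and the stiffness stability bound
    # beta D k_max dt <= 0.25 (Euler diverges beyond ~0.5), with k_max the
    # largest harmonic curvature in the system.
    D <- 1 / beta          # kT in kcal/mol, gamma = 1 => D = kT
    k_max <- max(2 * spec$bond_k, 4 * spec$bend_k, 20,
                 if (!is.null(bias)) 2 * bias$force_constant else 0)
    dt <- min(step_size^2 / (2 * D), 0.25 / (beta * D * k_max))
    h <- 1e-4
    grad_bead <- function(X, i, base_e) {
      g <- numeric(3)
      for (d in 1:3) {
        Xp <- X; Xp[i, d] <- Xp[i, d] + h
        g[d] <- (energy(Xp) + restraint_e(colMeans(Xp)) - base_e) / h
      }
      g
    }
    for (sweep in seq_len(n_steps)) {
      noise <- matrix(rnorm(3 * n, 0, sqrt(2 * D * dt)), n, 3)
      for (i in seq_len(n)) {
        base_e <- energy(X) + restraint_e(colMeans(X))
        g <- grad_bead(X, i, base_e)
        disp <- -D * beta * g * dt + noise[i, ]
        nd <- .vnorm(disp)
        if (nd > 10 * spec$bond_length)
          .bindfe_stop("bindfe_stability_error",
                       "Langevin displacement blow-up; reduce step_size")
        X[i, ] <- X[i, ] + disp
      }
      if (sweep %% save_every == 0L) {
        k <- sweep %/% save_every
        frames[[k]] <- rbind(X, S)
        seps[k] <- .vnorm(colMeans(X) - scom)
      }
    }
    acc <- NA_integer_; tries <- NA_integer_
  }
  traj <- trajectory(topo, frames)
  attr(traj, "separation") <- seps
  attr(traj, "acceptance_rate") <- if (is.na(tries)) NA_real_ else acc / tries
  attr(traj, "seed") <- seed
  attr(traj, "generator") <- list(version = .generator_version, method = method,
                                  n_steps = n_steps, step_size = step_size)
  traj
}

#' Generate a rigid-dumbbell orientation ensemble with known angle density
#'
#' A two-bead dipolar dumbbell is placed at fixed separation from a single
#' scaffold bead at the origin; its axis is drawn from a von Mises-Fisher
#' distribution about the separation (+z) axis with concentration `kappa`
#' (kappa = 0 is isotropic).  The true angle density p(omega) is attached.
#'
#' @param kappa vMF concentration parameter (>= 0).
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param separation scaffold-to-dumbbell COM distance, Angstrom.
#' @param half_length half the dumbbell length, Angstrom.
#' @return A [trajectory()] (beads: scaffold, plus(+1e), minus(-1e)) with
#'   attributes `true_density` (function of omega on `[0, pi]`) and
#'   `omega` (the sampled angles).
#' @export
generate_orientation_ensemble <- function(kappa, n_frames = 1000, seed = 1,
                                          separation = 25, half_length = 4) {
  .assert(kappa >= 0, "bindfe_input_error", "kappa must be >= 0")
  set.seed(seed)
  u <- runif(n_frames)
  cosw <- if (kappa == 0) 2 * u - 1
          else 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  cosw <- pmin(1, pmax(-1, cosw))
  phi <- runif(n_frames, -pi, pi)
  sinw <- sqrt(1 - cosw^2)
  axis <- cbind(sinw * cos(phi), sinw * sin(phi), cosw)
  center <- c(0, 0, separation)
  topo <- topology(name = c("P1", "DP", "DM"),
                   residue_index = c(1, 2, 2),
                   residue_name = c("NUC", "DMB", "DMB"),
                   chain_id = c("R", "P", "P"),
                   mass = c(110, 110, 110), charge = c(-1, 1, -1),
                   element = c("P", "C", "C"))
  frames <- lapply(seq_len(n_frames), function(i) {
    rbind(c(0, 0, 0),
          center + half_length * axis[i, ],
          center - half_length * axis[i, ])
  })
  traj <- trajectory(topo, frames)
  dens <- if (kappa == 0) function(w) sin(w) / 2
          else function(w) kappa * sin(w) * exp(kappa * cos(w)) /
                 (2 * sinh(kappa))
  attr(traj, "true_density") <- dens
  attr(traj, "omega") <- acos(cosw)
  attr(traj, "generator") <- list(version = .generator_version, seed = seed,
                                  kappa = kappa, separation = separation)
  traj
}
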