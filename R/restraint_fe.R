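## Woo-Roux restraint-release ledger and assembly -------------------------

.gauss_line_integral <- function(keff, beta, x0 = 0, wrap = TRUE) {
  # integral over (-pi, pi] of exp(-beta*keff*wrap(x - x0)^2) dx.
  # With wrap = TRUE the deviation is periodic and the result is independent
  # of x0; with wrap = FALSE the Gaussian is truncated at the fixed bounds
  # (the behaviour of plain fixed-bounds quadrature), which matters when x0
  # sits near +/- pi.
  if (wrap)
    integrate(function(t) exp(-beta * keff * t^2), -pi, pi,
              rel.tol = 1e-12, abs.tol = 1e-14)$value
  else
    integrate(function(x) exp(-beta * keff * (x - x0)^2), -pi, pi,
              rel.tol = 1e-12, abs.tol = 1e-14)$value
}

.polar_integral <- function(keff, beta, x0, jacobian) {
  J <- switch(jacobian,
              sin = function(x) sin(x),
              sin_at_eq = function(x) rep(sin(x0), length(x)),
              none = function(x) rep(1, length(x)))
  integrate(function(x) J(x) * exp(-beta * keff * (x - x0)^2), 0, pi,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

#' Free energy of releasing the orientational restraints in bulk
#'
#' Analytic/numeric evaluation of
#' -kT ln of (1/(8 pi^2)) int int int J(Theta) exp(-beta u(Theta,Phi,Psi))
#' dTheta dPhi dPsi, with u the harmonic orientational restraint of the
#' scheme; the triple integral factorizes into three adaptive 1-D
#' quadratures.  `jacobian` selects the measure on Theta: the textbook
#' `"sin"` Jacobian, its value frozen at the equilibrium angle
#' (`"sin_at_eq"`), or none -- conventions differ between published
#' implementations, so the choice is always explicit.  `dihedral_domain`
#' controls the Phi/Psi integrals: `"periodic"` wraps the deviation (the
#' physically periodic measure), `"fixed"` integrates the unwrapped harmonic
#' over the fixed bounds (-pi, pi], which truncates the Gaussian when an
#' equilibrium dihedral sits near the boundary -- the behaviour of
#' general-purpose fixed-bounds quadrature routines.
#'
#' @param scheme a [restraint_scheme()]; its `k` must be > 0.
#' @param temperature temperature in K.
#' @param convention override of the scheme's convention (`"full"`/`"half"`).
#' @param jacobian `"sin"` (default), `"sin_at_eq"` or `"none"`.
#' @param dihedral_domain `"periodic"` (default) or `"fixed"`.
#' @return Free energy in kcal mol^-1 (>= 0 for k > 0).
#' @export
orientational_release_bulk <- function(scheme, temperature = 300,
                                       convention = NULL,
                                       jacobian = c("sin", "sin_at_eq", "none"),
                                       dihedral_domain = c("periodic", "fixed")) {
  jacobian <- match.arg(jacobian)
  dihedral_domain <- match.arg(dihedral_domain)
  if (is.null(convention)) convention <- scheme$convention
  .assert(scheme$k > 0, "bindfe_input_error", "scheme k must be > 0")
  beta <- .beta(temperature)
  keff <- if (convention == "half") scheme$k / 2 else scheme$k
  wrap <- dihedral_domain == "periodic"
  Z <- .polar_integral(keff, beta, scheme$Theta0, jacobian) *
    .gauss_line_integral(keff, beta, scheme$Phi0, wrap) *
    .gauss_line_integral(keff, beta, scheme$Psi0, wrap)
  -log(Z / (8 * pi^2)) / beta
}

#' Axial surface term S* at separation r*
#'
#' S* = r*^2 * int int sin(theta) exp(-beta u(theta, phi)) dtheta dphi with
#' the harmonic axial restraint of the scheme; for k -> 0 this approaches the
#' full sphere 4 pi r*^2.
#'
#' @param scheme a [restraint_scheme()].
#' @param r_star separation at which the surface term is evaluated (Angstrom,
#'   > 0).
#' @param temperature temperature in K.
#' @param convention override of the scheme's convention.
#' @return S* in Angstrom^2.
#' @export
axial_surface_term <- function(scheme, r_star, temperature = 300,
                               convention = NULL) {
  .assert(r_star > 0, "bindfe_input_error", "r_star must be > 0")
  if (is.null(convention)) convention <- scheme$convention
  beta <- .beta(temperature)
  keff <- if (convention == "half") scheme$k / 2 else scheme$k
  if (keff == 0) return(4 * pi * r_star^2)
  r_star^2 * .polar_integral(keff, beta, scheme$theta0, "sin") *
    .gauss_line_integral(keff, beta)
}

#' Standard-state separation term -kT ln(I* S* C-standard)
#'
#' @param I_star separation integral, Angstrom (> 0).
#' @param S_star angular surface term, Angstrom^2 (> 0).
#' @param temperature temperature in K.
#' @return Term in kcal mol^-1 (signed).
#' @export
standard_state_term <- function(I_star, S_star, temperature = 300) {
  .assert(I_star > 0 && S_star > 0, "bindfe_domain_error",
          "I* and S* must be > 0")
  -log(I_star * S_star * c_standard()) / .beta(temperature)
}

#' Conformational-restraint release free energy from an RMSD PMF
#'
#' Builds (or takes) the PMF along a conformational RMSD coordinate and
#' returns -kT ln of the ratio of the restrained-region to the full-region
#' configurational integrals, i.e. the free-energy cost of confining the
#' molecule to `restrained_range` (>= 0).
#'
#' @param windows_on_rmsd a [umbrella_window_set()] on the RMSD coordinate,
#'   or a ready [pmf_profile()].
#' @param restrained_range numeric length-2, `[0, r_cut]` in Angstrom.
#' @param temperature temperature in K (ignored when a profile is supplied).
#' @param ... further arguments passed to [wham_1d()].
#' @return Free energy in kcal mol^-1.
#' @export
conformational_release <- function(windows_on_rmsd, restrained_range,
                                   temperature = 300, ...) {
  pmf <- if (inherits(windows_on_rmsd, "bindfe_pmf")) windows_on_rmsd
         else wham_1d(windows_on_rmsd, ...)
  r <- pmf$bin_centers; W <- pmf$free_energy
  beta <- .beta(pmf$temperature)
  lo <- max(restrained_range[1], min(r))
  hi <- min(restrained_range[2], max(r))
  .assert(hi > lo, "bindfe_input_error",
          "restrained_range does not intersect the profile")
  trapz_exp <- function(a, b) {
    inside <- r > a & r < b
    xs <- c(a, r[inside], b)
    Ws <- c(approx(r, W, xout = a)$y, W[inside], approx(r, W, xout = b)$y)
    y <- exp(-beta * Ws)
    sum(diff(xs) * (head(y, -1) + tail(y, -1)) / 2)
  }
  -log(trapz_exp(lo, hi) / trapz_exp(min(r), max(r))) / beta
}

#' Single-step restraint release by exponential reweighting
#'
#' Free energy of a restraint whose energies `u` were evaluated on samples of
#' the unrestrained target ensemble (-kT ln <exp(-beta u)>), with a
#' block-averaged standard error; when both `u_forward` and `u_reverse` are
#' supplied the two-sided [bar()] estimate is used instead.
#'
#' @param u restraint-energy series on unrestrained-target samples,
#'   kcal mol^-1.
#' @param temperature temperature in K.
#' @param u_forward,u_reverse optional forward/reverse energy differences for
#'   the BAR fallback.
#' @param min_ess minimum effective sample size before a reliability
#'   diagnostic is raised.
#' @param on_low_ess `"warn"` (default) or `"error"`.
#' @param n_blocks blocks for the stderr.
#' @return A [fe_estimate()].
#' @export
single_step_release <- function(u, temperature = 300,
                                u_forward = NULL, u_reverse = NULL,
                                min_ess = 10, on_low_ess = c("warn", "error"),
                                n_blocks = 10) {
  on_low_ess <- match.arg(on_low_ess)
  if (!is.null(u_forward) && !is.null(u_reverse))
    return(bar(u_forward, u_reverse, temperature))
  est <- exp_free_energy(u, temperature, n_blocks = n_blocks)
  if (est$diagnostics$ess < min_ess) {
    msg <- sprintf("effective sample size %.1f below %g; estimate unreliable",
                   est$diagnostics$ess, min_ess)
    if (on_low_ess == "error") .bindfe_stop("bindfe_reliability_error", msg)
    warning(msg)
  }
  est
}

## Ledger -----------------------------------------------------------------

.ledger_terms <- c("sep_term", "dG_p_B", "dG_n_B", "dG_o_B",
                   "dG_p_S", "dG_n_S", "dG_o_S", "dG_a_S")

#' Build a Woo-Roux free-energy ledger
#'
#' Terms are stored as magnitudes with bulk (B) / site (S) labels; the
#' assembler applies the signs of the binding equation, so the site terms are
#' entered positive (e.g. `dG_p_S = 7.61` for a printed row "-dG_p_S =
#' -7.61").  `sep_term` is the signed separation contribution
#' -kT ln(I* S* C-standard).
#'
#' @param values named numeric vector containing all of
#'   `r paste(.ledger_terms, collapse = ", ")` (kcal mol^-1).
#' @param stderrs named numeric vector of standard errors (missing names
#'   default to 0).
#' @param temperature temperature in K.
#' @param salt_mM salt-concentration label (mM).
#' @param water_model water-model label.
#' @return An object of class `bindfe_ledger`.
#' @export
free_energy_ledger <- function(values, stderrs = NULL, temperature = 300,
                               salt_mM = NA_real_, water_model = NA_character_) {
  missing <- setdiff(.ledger_terms, names(values))
  .assert(length(missing) == 0, "bindfe_ledger_error",
          paste("missing ledger term(s):", paste(missing, collapse = ", ")))
  if (is.null(stderrs)) stderrs <- setNames(numeric(0), character(0))
  se <- setNames(rep(0, length(.ledger_terms)), .ledger_terms)
  se[names(stderrs)] <- stderrs
  .assert(all(se >= 0), "bindfe_ledger_error", "stderrs must be >= 0")
  structure(list(values = values[.ledger_terms], stderrs = se,
                 temperature = temperature, salt_mM = salt_mM,
                 water_model = water_model),
            class = "bindfe_ledger")
}

#' Assemble the standard-state binding free energy from a ledger
#'
#' dG_b = sep_term + dG_p_B + dG_n_B + dG_o_B - dG_p_S - dG_n_S - dG_o_S -
#' dG_a_S, with the standard error as the root-sum-square of the term
#' standard errors (terms come from independent simulations).
#'
#' @param ledger a [free_energy_ledger()].
#' @return A list with `value` and `stderr` (kcal mol^-1).
#' @export
assemble_binding_free_energy <- function(ledger) {
  .assert(inherits(ledger, "bindfe_ledger"), "bindfe_ledger_error",
          "ledger must be a free_energy_ledger")
  signs <- setNames(c(1, 1, 1, 1, -1, -1, -1, -1), .ledger_terms)
  v <- sum(signs * ledger$values[.ledger_terms])
  se <- sqrt(sum(ledger$stderrs[.ledger_terms]^2))
  list(value = unname(v), stderr = unname(se))
}

#' Bulk-to-site restriction costs from a ledger
#'
#' ddG_x(B->S) = dG_x^B - dG_x^S for the peptide (p), nucleic-acid (n) and
#' orientational (o) restraint families.
#'
#' @param ledger a [free_energy_ledger()].
#' @return Named list with `ddG_p`, `ddG_n`, `ddG_o` (each `value`/`stderr`).
#' @export
bulk_to_site_deltas <- function(ledger) {
  v <- ledger$values; s <- ledger$stderrs
  one <- function(x) list(
    value = unname(v[[paste0("dG_", x, "_B")]] - v[[paste0("dG_", x, "_S")]]),
    stderr = sqrt(s[[paste0("dG_", x, "_B")]]^2 + s[[paste0("dG_", x, "_S")]]^2))
  list(ddG_p = one("p"), ddG_n = one("n"), ddG_o = one("o"))
}

#' Write a ledger to JSON
#' @param ledger a [free_energy_ledger()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(list(
    values = as.list(ledger$values), stderrs = as.list(ledger$stderrs),
    temperature = ledger$temperature, salt_mM = ledger$salt_mM,
    water_model = ledger$water_model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ledger from JSON
#' @param path file written by [write_ledger_json()].
#' @return A [free_energy_ledger()].
#' @export
read_ledger_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  free_energy_ledger(unlist(x$values), unlist(x$stderrs), x$temperature,
                     x$salt_mM, x$water_model)
}
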