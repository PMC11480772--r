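## Transition fits and change-point extraction ----------------------------

.fit_result <- function(model, par, residual_rms, covariance, converged,
                        notes = character(0)) {
  structure(list(model = model, par = par, residual_rms = residual_rms,
                 covariance = covariance, converged = converged,
                 notes = notes),
            class = "bindfe_fit")
}

#' @export
print.bindfe_fit <- function(x, ...) {
  cat(sprintf("<bindfe_fit '%s': RMS %.4g, converged %s>\n",
              x$model, x$residual_rms, x$converged))
  print(x$par)
  invisible(x)
}

.multistart_nls <- function(formula, data, starts, lower, upper,
                            weights = NULL) {
  best <- NULL
  args <- list(formula, data = data, lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(do.call(minpack.lm::nlsLM, c(args, list(start = st)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a generalized logistic curve
#'
#' Least-squares fit of y = A + (K - A)/(1 + exp(-B (x - M)))^(1/nu) with
#' multi-start initialization (the 5-parameter surface is multimodal) and a
#' positivity bound on nu.  For nu = 1 the curve is symmetric and M is the
#' half-height abscissa.
#'
#' @param x,y data vectors (>= 6 points).
#' @param weights optional fit weights.
#' @param n_starts number of seeded starts (default 16).
#' @param seed RNG seed for the start jitter.
#' @return A fit-result list with `par` = c(A, K, B, M, nu).
#' @export
fit_generalized_logistic <- function(x, y, weights = NULL, n_starts = 16,
                                     seed = 1) {
  .assert(length(x) >= 6 && length(x) == length(y), "bindfe_input_error",
          "need >= 6 (x, y) points")
  if (sd(y) < 1e-12 * (abs(mean(y)) + 1)) {
    p <- c(A = mean(y), K = mean(y), B = 0, M = mean(x), nu = 1)
    return(.fit_result("generalized_logistic", p, 0, matrix(0, 5, 5), FALSE,
                       "degenerate: constant response"))
  }
  rngx <- range(x); span <- diff(rngx)
  base <- list(A = min(y), K = max(y), B = 4 / span, M = mean(rngx), nu = 1)
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- base
    if (i > 1) {
      s$M <- runif(1, rngx[1], rngx[2])
      s$B <- sample(c(-1, 1), 1) * 10^runif(1, -2, 1.2) / span * span
      s$nu <- 10^runif(1, -0.7, 0.7)
      if (runif(1) < 0.5) { tmp <- s$A; s$A <- s$K; s$K <- tmp }
    }
    s
  })
  yr <- diff(range(y))
  lower <- c(A = min(y) - 5 * yr, K = min(y) - 5 * yr, B = -Inf,
             M = rngx[1] - span, nu = 1e-3)
  upper <- c(A = max(y) + 5 * yr, K = max(y) + 5 * yr, B = Inf,
             M = rngx[2] + span, nu = 1e3)
  best <- .multistart_nls(
    y ~ A + (K - A) / (1 + exp(-B * (x - M)))^(1 / nu),
    data.frame(x = x, y = y), starts, lower, upper, weights)
  if (is.null(best))
    .bindfe_stop("bindfe_fit_error",
                 "generalized logistic fit failed from all starts")
  .fit_result("generalized_logistic", coef(best$fit),
              sqrt(best$rss / length(x)),
              tryCatch(vcov(best$fit), error = function(e) NULL), TRUE)
}

#' Fit the log-exponential contact-decay curve
#'
#' Least-squares fit of f(x) = a + b log(c exp(x - d) + e).  The 5-parameter
#' form carries an exact two-parameter gauge freedom: rescaling the argument
#' of the logarithm by s maps (a, c, e) -> (a - b log s, s c, s e) and
#' c trades against d via c exp(x - d) = exp(x - (d - log c)), so the family
#' is identical to the 3-parameter canonical form a + b log(exp(x - d) + 1).
#' The fit is therefore performed in the canonical gauge c = e = 1, where the
#' curve has the plateau a for x << d and the line a + b (x - d) for x >> d;
#' `par` reports all five parameters with c = e = 1.
#'
#' @param x,y data vectors (>= 6 points).
#' @param n_starts number of starts.
#' @param seed RNG seed for start jitter.
#' @return A fit-result list with `par` = c(a, b, c, d, e); a note flags the
#'   degenerate pure-linear regime (transition midpoint outside the data,
#'   the e -> 0 boundary of the original parametrization).
#' @export
fit_contact_decay <- function(x, y, n_starts = 16, seed = 1) {
  .assert(length(x) >= 6 && length(x) == length(y), "bindfe_input_error",
          "need >= 6 (x, y) points")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  top <- max(3L, n %/% 3L)
  b0 <- unname(coef(lm(y ~ x, subset = (n - top + 1L):n))[2])
  if (!is.finite(b0) || abs(b0) < 1e-8) b0 <- 1
  a0 <- min(y); d0 <- mean(range(x))
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- list(a = a0, b = b0, d = d0)
    if (i > 1) {
      s$d <- runif(1, min(x), max(x))
      s$b <- b0 * 10^runif(1, -0.3, 0.3)
      s$a <- a0 - runif(1, 0, diff(range(y)))
    }
    s
  })
  best <- .multistart_nls(y ~ a + b * log(exp(x - d) + 1),
                          data.frame(x = x, y = y), starts,
                          lower = c(a = -Inf, b = -Inf, d = -Inf),
                          upper = c(a = Inf, b = Inf, d = Inf))
  span <- diff(range(x))
  lin <- lm(y ~ x)
  lin_rms <- sqrt(mean(stats::residuals(lin)^2))
  if (is.null(best) ||
      lin_rms < 0.999 * sqrt(best$rss / n)) {
    # degenerate pure-linear regime (e -> 0 boundary of the original
    # parametrization): the transition midpoint lies outside the data
    if (is.null(best) && lin_rms > 1e-6 * (sd(y) + 1e-12))
      .bindfe_stop("bindfe_fit_error", "contact-decay fit failed from all starts")
    d_deg <- min(x) - 2 * span
    co <- coef(lin)
    p <- c(a = unname(co[1] + co[2] * d_deg), b = unname(co[2]), c = 1,
           d = d_deg, e = 1)
    return(.fit_result("contact_decay", p, lin_rms, NULL, TRUE,
                       "transition midpoint outside the data range (boundary regime)"))
  }
  p <- coef(best$fit)
  p <- c(a = unname(p["a"]), b = unname(p["b"]), c = 1,
         d = unname(p["d"]), e = 1)
  notes <- character(0)
  span <- diff(range(x))
  if (p[["d"]] < min(x) - span || p[["d"]] > max(x) + span)
    notes <- "transition midpoint outside the data range (boundary regime)"
  .fit_result("contact_decay", p, sqrt(best$rss / length(x)),
              tryCatch(vcov(best$fit), error = function(e) NULL), TRUE, notes)
}

#' Extract the onset boundary Xi from an order-parameter profile
#'
#' Scanning from the largest separation downward, finds the first run of
#' three consecutive windows whose statistic each increases (by more than
#' the noise floor `eps`) relative to its larger-r neighbour, and returns the
#' middle of those three windows.  Returns `NA` (a not-found signal, not an
#' error) when no such run exists.
#'
#' @param profile an [order_parameter_profile()] (or data frame with `r` and
#'   `value`).
#' @param eps noise floor on an increase (default 0.01).
#' @return The boundary separation Xi in Angstrom, or `NA_real_`.
#' @export
extract_boundary <- function(profile, eps = 0.01) {
  df <- profile[order(-profile$r), ]
  .assert(nrow(df) >= 4L, "bindfe_input_error",
          "need >= 4 windows to find three consecutive increases")
  inc <- diff(df$value) > eps        # inc[i]: window i+1 increased vs window i
  for (i in seq_len(length(inc) - 2L)) {
    if (inc[i] && inc[i + 1L] && inc[i + 2L])
      return(df$r[i + 2L])           # middle of windows i+1, i+2, i+3
  }
  NA_real_
}

#' Fit a Debye-Hueckel screened-Coulomb tail to a PMF
#'
#' Least-squares fit of W(r) = A exp(-kappa r)/r + w0 on the profile region r
#' >= `r_min`.  When `ionic_strength` (M) is given, the theoretical screening
#' constant kappa_DH = sqrt(I)/3.04 (1/Angstrom, 1:1 electrolyte near 300 K)
#' is reported alongside the fitted kappa.
#'
#' @param pmf a [pmf_profile()].
#' @param r_min start of the tail region, Angstrom (default 20).
#' @param ionic_strength optional ionic strength in M.
#' @param n_starts number of starts.
#' @param seed RNG seed.
#' @return A fit-result list with `par` = c(A, kappa, w0) and optionally a
#'   `kappa_theory` entry in `notes`' attributes.
#' @export
debye_huckel_fit <- function(pmf, r_min = 20, ionic_strength = NULL,
                             n_starts = 16, seed = 1) {
  keep <- pmf$bin_centers >= r_min
  .assert(sum(keep) >= 4L, "bindfe_input_error",
          "too few tail points beyond r_min")
  r <- pmf$bin_centers[keep]; W <- pmf$free_energy[keep]
  w0g <- W[which.max(r)]
  amp <- W - w0g
  if (max(abs(amp)) < 1e-10) {
    p <- c(A = 0, kappa = NA_real_, w0 = w0g)
    return(.fit_result("debye_huckel", p, 0, NULL, FALSE,
                       "flat tail: kappa unidentifiable"))
  }
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    kap <- if (i == 1) 0.1 else 10^runif(1, -2.3, 0.3)
    mid <- which.min(abs(r - stats::median(r)))
    list(A = amp[mid] * r[mid] * exp(kap * r[mid]), kappa = kap, w0 = w0g)
  })
  best <- .multistart_nls(W ~ A * exp(-kappa * r) / r + w0,
                          data.frame(r = r, W = W), starts,
                          lower = c(A = -Inf, kappa = 1e-6, w0 = -Inf),
                          upper = c(A = Inf, kappa = 10, w0 = Inf))
  if (is.null(best))
    .bindfe_stop("bindfe_fit_error", "Debye-Hueckel fit failed from all starts")
  res <- .fit_result("debye_huckel", coef(best$fit),
                     sqrt(best$rss / length(r)),
                     tryCatch(vcov(best$fit), error = function(e) NULL), TRUE)
  if (!is.null(ionic_strength))
    res$kappa_theory <- sqrt(ionic_strength) / 3.04
  res
}

## Salt dependence --------------------------------------------------------

#' Build a salt-concentration series of binding free energies
#'
#' @param concentration_mM salt concentrations in mM (positive, distinct,
#'   >= 2 values).
#' @param dG binding free energies, kcal mol^-1.
#' @param stderr standard errors (default 0).
#' @return An object of class `bindfe_salt_series`.
#' @export
salt_series <- function(concentration_mM, dG, stderr = 0) {
  .assert(length(concentration_mM) >= 2L &&
            length(concentration_mM) == length(dG),
          "bindfe_input_error", "need >= 2 aligned (concentration, dG) pairs")
  .assert(all(concentration_mM > 0), "bindfe_input_error",
          "concentrations must be positive")
  .assert(!anyDuplicated(concentration_mM), "bindfe_input_error",
          "concentrations must be distinct")
  structure(list(concentration_mM = concentration_mM, dG = dG,
                 stderr = rep_len(stderr, length(dG))),
            class = "bindfe_salt_series")
}

#' Salt-dependence regression d(dG)/d(log [salt])
#'
#' Ordinary least-squares slope of dG against the logarithm of the salt
#' concentration in molar.  The natural logarithm is the default; the
#' decadic-base slope is exactly ln(10) times the natural-base slope.
#'
#' @param series a [salt_series()].
#' @param log_base `"natural"` (default) or `"decadic"`.
#' @return A list with `slope`, `stderr` (kcal mol^-1 per log unit),
#'   `intercept`, `log_base` and the underlying `lm` fit.
#' @export
salt_dependence_regression <- function(series,
                                       log_base = c("natural", "decadic")) {
  log_base <- match.arg(log_base)
  logc <- log(series$concentration_mM / 1000)
  if (log_base == "decadic") logc <- logc / log(10)
  fit <- lm(series$dG ~ logc)
  co <- summary(fit)$coefficients
  list(slope = unname(co[2, 1]),
       stderr = if (length(logc) > 2) unname(co[2, 2]) else NA_real_,
       intercept = unname(co[1, 1]),
       log_base = log_base, fit = fit)
}

#' Invert the salt regression at a target binding free energy
#'
#' @param series a [salt_series()].
#' @param target_dG target binding free energy, kcal mol^-1.
#' @param log_base passed to [salt_dependence_regression()].
#' @return Concentration in mM.
#' @export
interpolate_concentration <- function(series, target_dG,
                                      log_base = c("natural", "decadic")) {
  log_base <- match.arg(log_base)
  reg <- salt_dependence_regression(series, log_base)
  .assert(abs(reg$slope) > 1e-12, "bindfe_domain_error",
          "zero regression slope: concentration not identifiable")
  logc <- (target_dG - reg$intercept) / reg$slope
  conc_M <- if (log_base == "natural") exp(logc) else 10^logc
  conc_M * 1000
}
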