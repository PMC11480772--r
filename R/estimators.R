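## Free-energy estimators: WHAM, BAR, mBAR, block errors, I* -------------

#' Construct a PMF profile
#'
#' @param bin_centers strictly increasing coordinate values (Angstrom, rad or
#'   RMSD Angstrom).
#' @param free_energy free energies in kcal mol^-1; normalized so the minimum
#'   is 0.
#' @param stderr per-bin standard errors (kcal mol^-1, >= 0).
#' @param temperature temperature in K.
#' @return An object of class `bindfe_pmf`.
#' @export
pmf_profile <- function(bin_centers, free_energy, stderr = NULL,
                        temperature = 300) {
  .assert(all(diff(bin_centers) > 0), "bindfe_input_error",
          "bin centers must be strictly increasing")
  .assert(length(bin_centers) == length(free_energy), "bindfe_input_error",
          "bin_centers and free_energy lengths differ")
  if (is.null(stderr)) stderr <- rep(0, length(free_energy))
  .assert(all(stderr >= 0), "bindfe_input_error", "stderr must be >= 0")
  structure(list(bin_centers = as.numeric(bin_centers),
                 free_energy = as.numeric(free_energy - min(free_energy)),
                 stderr = as.numeric(stderr),
                 temperature = temperature),
            class = "bindfe_pmf")
}

#' @export
print.bindfe_pmf <- function(x, ...) {
  cat(sprintf("<bindfe_pmf: %d bins on [%.3g, %.3g], T = %g K>\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
              x$temperature))
  invisible(x)
}

#' Construct a free-energy estimate record
#'
#' @param value free-energy difference, kcal mol^-1.
#' @param stderr standard error, kcal mol^-1 (>= 0).
#' @param method method tag (`"WHAM"`, `"BAR"`, `"mBAR"`, `"EXP"`).
#' @param diagnostics named list of method diagnostics.
#' @return An object of class `bindfe_fe_estimate`.
#' @export
fe_estimate <- function(value, stderr, method, diagnostics = list()) {
  .assert(stderr >= 0, "bindfe_input_error", "stderr must be >= 0")
  structure(list(value = value, stderr = stderr, method = method,
                 diagnostics = diagnostics),
            class = "bindfe_fe_estimate")
}

#' @export
print.bindfe_fe_estimate <- function(x, ...) {
  cat(sprintf("<%s estimate: %.4f +/- %.4f kcal/mol>\n",
              x$method, x$value, x$stderr))
  invisible(x)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' One-dimensional WHAM over umbrella windows
#'
#' Self-consistent weighted-histogram solution for the unbiased potential of
#' mean force from harmonically biased windows.  Histogramming uses shared
#' global bin edges across all windows.  Iteration stops when the maximum
#' change in the per-window free energies falls below `tol`.
#'
#' Per-bin standard errors are estimated as kT/sqrt(n_b) from the total
#' occupancy n_b of each bin (the counting-noise floor; block-average window
#' contributions with [block_error()] for correlated data).
#'
#' @param windows a [umbrella_window_set()].
#' @param bin_width histogram bin width in coordinate units (default 0.1).
#' @param tol convergence tolerance on window free energies, kcal mol^-1.
#' @param max_iter maximum number of iterations.
#' @param min_overlap adjacent-window Bhattacharyya overlap below which a
#'   warning (or error, see `on_disconnected`) is raised.
#' @param on_disconnected `"warn"` or `"error"` for non-overlapping windows.
#' @return A [pmf_profile()] with attributes `window_free_energies`,
#'   `iterations` and `converged`.
#' @export
wham_1d <- function(windows, bin_width = 0.1, tol = 1e-7, max_iter = 1e5,
                    min_overlap = 0, on_disconnected = c("warn", "error")) {
  on_disconnected <- match.arg(on_disconnected)
  .assert(inherits(windows, "bindfe_window_set"), "bindfe_input_error",
          "windows must be an umbrella_window_set")
  T <- windows$temperature
  beta <- .beta(T)
  samples <- windows$samples
  K <- length(samples)

  if (K >= 2L) {
    ov <- histogram_overlap(windows, bin_width = bin_width)
    if (any(ov <= min_overlap)) {
      msg <- sprintf("adjacent windows with overlap <= %g (pairs: %s)",
                     min_overlap, paste(which(ov <= min_overlap), collapse = ","))
      if (on_disconnected == "error")
        .bindfe_stop("bindfe_disconnected_error", msg)
      warning(msg)
    }
  }

  all_x <- unlist(samples)
  lo <- floor(min(all_x) / bin_width) * bin_width
  hi <- ceiling(max(all_x) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- head(edges, -1) + bin_width / 2
  B <- length(centers)

  counts <- vapply(samples, function(s)
    tabulate(pmin(B, pmax(1L, findInterval(s, edges, rightmost.closed = TRUE))),
             nbins = B), numeric(B))
  counts <- matrix(counts, nrow = B)          # B x K
  Nk <- colSums(counts)
  total <- rowSums(counts)

  # bias energy of each window at each bin center: B x K
  Ub <- vapply(windows$biases, function(b) bias_energy(b, centers), numeric(B))
  Ub <- matrix(Ub, nrow = B)
  expmbU <- exp(-beta * Ub)

  f <- rep(0, K)                               # window free energies, kcal/mol
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.vector(expmbU %*% (Nk * exp(beta * f)))    # length B
    p <- total / denom
    p[!is.finite(p)] <- 0
    fnew <- -log(colSums(p * expmbU)) / beta
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
    if (iter >= max_iter)
      .bindfe_stop("bindfe_convergence_error",
                   sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                           iter, delta), residual = delta)
  }

  keep <- total > 0
  p <- (total / as.vector(expmbU %*% (Nk * exp(beta * f))))[keep]
  G <- -log(p) / beta
  err <- (1 / beta) / sqrt(total[keep])
  prof <- pmf_profile(centers[keep], G, err, temperature = T)
  attr(prof, "window_free_energies") <- f
  attr(prof, "iterations") <- iter
  attr(prof, "converged") <- TRUE
  prof
}

#' Bennett acceptance ratio (BAR) free-energy difference
#'
#' Solves the Bennett self-consistency equation for the free-energy
#' difference between two states from forward and reverse energy-difference
#' samples: `du_forward` = U2 - U1 evaluated on state-1 samples, `du_reverse`
#' = U1 - U2 evaluated on state-2 samples (kcal mol^-1).
#'
#' @param du_forward,du_reverse numeric energy-difference series.
#' @param temperature temperature in K.
#' @param tol root-finding tolerance (kcal mol^-1).
#' @return A [fe_estimate()] with the BAR variance-based stderr.
#' @export
bar <- function(du_forward, du_reverse, temperature = 300, tol = 1e-10) {
  .assert(length(du_forward) >= 1L && length(du_reverse) >= 1L,
          "bindfe_input_error", "both series must be non-empty")
  beta <- .beta(temperature)
  n1 <- length(du_forward); n2 <- length(du_reverse)
  M <- log(n1 / n2)
  fermi <- function(x) 1 / (1 + exp(x))
  gap <- function(dF)
    sum(fermi(beta * (du_forward - dF) + M)) -
      sum(fermi(beta * (du_reverse + dF) - M))
  lo <- min(c(du_forward, -du_reverse)) - 1
  hi <- max(c(du_forward, -du_reverse)) + 1
  glo <- gap(lo); ghi <- gap(hi)
  tries <- 0L
  while (sign(glo) == sign(ghi) && tries < 60L) {
    span <- hi - lo
    lo <- lo - span; hi <- hi + span
    glo <- gap(lo); ghi <- gap(hi)
    tries <- tries + 1L
  }
  if (sign(glo) == sign(ghi))
    .bindfe_stop("bindfe_numerical_error",
                 "BAR self-consistency has no root in expanded bracket",
                 bracket = c(lo, hi), gap = c(glo, ghi))
  dF <- uniroot(gap, c(lo, hi), tol = tol)$root
  fF <- fermi(beta * (du_forward - dF) + M)
  fR <- fermi(beta * (du_reverse + dF) - M)
  relvar <- function(f) (mean(f^2) / mean(f)^2 - 1) / length(f)
  stderr <- sqrt(max(0, relvar(fF) + relvar(fR))) / beta
  fe_estimate(dF, stderr, "BAR",
              diagnostics = list(n_forward = n1, n_reverse = n2,
                                 overlap = mean(fF) + mean(fR)))
}

#' Multistate Bennett acceptance ratio (mBAR)
#'
#' Self-consistent solution of the mBAR equations for per-state reduced free
#' energies from a K x N matrix of reduced potentials (`u[k, n]` = beta *
#' U_k(x_n), dimensionless) where the N pooled samples were generated in the
#' K states with the given per-state `counts`.  The first state is pinned to
#' zero.
#'
#' Uncertainties are estimated by block resampling: each state's samples are
#' split into `n_blocks` consecutive blocks, the equations re-solved per
#' block, and the covariance of the block solutions divided by the block
#' count.  Set `n_blocks = 0` to skip.
#'
#' @param reduced_potentials K x N numeric matrix (dimensionless).
#' @param counts integer vector of per-state sample counts (sums to N);
#'   columns must be ordered by generating state.
#' @param tol convergence tolerance on the reduced free energies.
#' @param max_iter maximum self-consistent iterations.
#' @param n_blocks blocks for the covariance estimate (default 5).
#' @return A list with `f` (reduced free energies, first pinned to 0),
#'   `covariance` (K x K, reduced units; zero matrix if skipped),
#'   `iterations`.
#' @export
mbar <- function(reduced_potentials, counts, tol = 1e-10, max_iter = 1e5,
                 n_blocks = 5) {
  u <- as.matrix(reduced_potentials)
  K <- nrow(u); N <- ncol(u)
  .assert(all(is.finite(u)), "bindfe_input_error",
          "reduced potentials must be finite")
  .assert(sum(counts) == N, "bindfe_input_error", "counts must sum to N")
  f <- .mbar_solve(u, counts, tol, max_iter)
  covar <- matrix(0, K, K)
  if (n_blocks > 1) {
    starts <- c(0, cumsum(counts))
    fb <- matrix(NA_real_, n_blocks, K)
    for (b in seq_len(n_blocks)) {
      cols <- integer(0); cnt <- integer(K)
      for (k in seq_len(K)) {
        idx <- starts[k] + seq_len(counts[k])
        sz <- counts[k] %/% n_blocks
        if (sz < 1) next
        cols <- c(cols, idx[(b - 1) * sz + seq_len(sz)])
        cnt[k] <- sz
      }
      if (any(cnt == 0)) next
      fb[b, ] <- .mbar_solve(u[, cols, drop = FALSE], cnt, tol, max_iter)$f
    }
    ok <- complete.cases(fb)
    if (sum(ok) >= 2)
      covar <- stats::cov(fb[ok, , drop = FALSE]) / sum(ok)
  }
  list(f = f$f, covariance = covar, iterations = f$iterations)
}

.mbar_solve <- function(u, counts, tol, max_iter) {
  K <- nrow(u); N <- ncol(u)
  logN <- log(counts)
  f <- rep(0, K)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per sample: log sum_l N_l exp(f_l - u_ln)
    a <- logN + f - u                      # K x N (recycles by column)
    m <- apply(a, 2, max)
    logD <- m + log(colSums(exp(sweep(a, 2, m))))
    b <- -u - rep(logD, each = K)          # K x N
    mm <- apply(b, 1, max)
    fnew <- -(mm + log(rowSums(exp(b - mm))))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
    if (iter >= max_iter)
      .bindfe_stop("bindfe_convergence_error",
                   sprintf("mBAR did not converge (residual %.3g)", delta),
                   residual = delta)
  }
  list(f = f, iterations = iter)
}

#' Block-averaged standard error of a series mean
#'
#' Splits the series into `n_blocks` equal consecutive blocks (discarding any
#' trailing remainder) and returns the standard error of the block means,
#' sd(block means)/sqrt(n_blocks).
#'
#' @param series numeric vector, length >= `n_blocks`.
#' @param n_blocks number of blocks (default 10).
#' @return Standard error (scalar).
#' @export
block_error <- function(series, n_blocks = 10) {
  n <- length(series)
  .assert(n >= n_blocks && n_blocks >= 2, "bindfe_input_error",
          sprintf("series length %d shorter than n_blocks %d", n, n_blocks))
  sz <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(series[(b - 1) * sz + seq_len(sz)]), numeric(1))
  sd(means) / sqrt(n_blocks)
}

#' Adjacent-window histogram overlap
#'
#' Bhattacharyya coefficient of normalized adjacent-window histograms on
#' shared global edges; 1 for identical sample sets, 0 for disjoint support.
#'
#' @param windows a [umbrella_window_set()] with >= 2 windows.
#' @param bin_width histogram bin width (default 0.1).
#' @return Numeric vector of length (n windows - 1), values in `[0, 1]`.
#' @export
histogram_overlap <- function(windows, bin_width = 0.1) {
  samples <- windows$samples
  .assert(length(samples) >= 2L, "bindfe_input_error", "need >= 2 windows")
  all_x <- unlist(samples)
  lo <- floor(min(all_x) / bin_width) * bin_width
  hi <- ceiling(max(all_x) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  B <- length(edges) - 1L
  probs <- lapply(samples, function(s) {
    h <- tabulate(pmin(B, pmax(1L, findInterval(s, edges, rightmost.closed = TRUE))),
                  nbins = B)
    h / sum(h)
  })
  vapply(seq_len(length(probs) - 1L), function(i)
    min(1, sum(sqrt(probs[[i]] * probs[[i + 1L]]))), numeric(1))
}

#' Separation integral I* from a PMF profile
#'
#' I* = integral over the binding-site range of exp(-beta (W(r) - W(r_ref)))
#' dr, evaluated with the trapezoid rule on the profile grid (with linear
#' interpolation at the range endpoints and at r_ref).
#'
#' @param pmf a [pmf_profile()] along the separation coordinate.
#' @param site_range numeric length-2, `[r_min, r_max]` in Angstrom.
#' @param r_ref reference (bulk) separation in Angstrom, inside the profile.
#' @return I* in Angstrom.
#' @export
pmf_to_I_star <- function(pmf, site_range, r_ref) {
  r <- pmf$bin_centers; W <- pmf$free_energy
  .assert(r_ref >= min(r) && r_ref <= max(r), "bindfe_input_error",
          "r_ref outside profile")
  .assert(site_range[1] < site_range[2] &&
            site_range[1] >= min(r) && site_range[2] <= max(r),
          "bindfe_input_error", "site_range outside profile")
  beta <- .beta(pmf$temperature)
  Wref <- approx(r, W, xout = r_ref)$y
  inside <- r > site_range[1] & r < site_range[2]
  xs <- c(site_range[1], r[inside], site_range[2])
  Ws <- c(approx(r, W, xout = site_range[1])$y, W[inside],
          approx(r, W, xout = site_range[2])$y)
  y <- exp(-beta * (Ws - Wref))
  sum(diff(xs) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Exponential-averaging (Zwanzig) free energy of inserting a restraint
#'
#' Free energy of switching on a perturbation whose energies `u` were
#' evaluated on samples of the unperturbed ensemble:
#' dF = -kT ln < exp(-beta u) >.
#'
#' @param u perturbation energy series, kcal mol^-1.
#' @param temperature temperature in K.
#' @param n_blocks blocks for the stderr of the exponential mean.
#' @return A [fe_estimate()] with method tag `"EXP"`.
#' @export
exp_free_energy <- function(u, temperature = 300, n_blocks = 10) {
  .assert(length(u) >= 1L, "bindfe_input_error", "empty series")
  beta <- .beta(temperature)
  w <- exp(-beta * u)
  m <- mean(w)
  dF <- -log(m) / beta
  se <- if (length(u) >= n_blocks) block_error(w, n_blocks) / (beta * m) else 0
  ess <- sum(w)^2 / sum(w^2)
  fe_estimate(dF, se, "EXP", diagnostics = list(ess = ess, n = length(u)))
}
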