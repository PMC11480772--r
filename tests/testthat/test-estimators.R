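test_that("WHAM on a single unbiased window recovers a flat profile", {
  set.seed(3)
  u <- runif(1e5, 0, 10)
  w <- umbrella_window_set(list(bias_potential("harmonic_distance", 5, 0)),
                           list(u), 300)
  pmf <- wham_1d(w, bin_width = 0.2)
  dev <- pmf$free_energy - mean(pmf$free_energy)
  expect_lt(max(abs(dev)), 3 * max(pmf$stderr))
})

test_that("WHAM is invariant to a constant shift of the potential", {
  pot <- analytic_potential("polynomial", coefficients = c(0, 0, 2))
  pot_shift <- analytic_potential("polynomial", coefficients = c(7.3, 0, 2))
  ds1 <- generate_umbrella_dataset(pot, seq(-1, 1, 0.25), 8, "full", 800, seed = 5)
  ds2 <- generate_umbrella_dataset(pot_shift, seq(-1, 1, 0.25), 8, "full", 800, seed = 5)
  p1 <- wham_1d(ds1$windows)
  p2 <- wham_1d(ds2$windows)
  expect_equal(p1$free_energy, p2$free_energy, tolerance = 1e-10)
})

test_that("WHAM flags disconnected windows", {
  b <- lapply(c(0, 10), function(cen) bias_potential("harmonic_distance", cen, 50))
  w <- umbrella_window_set(b, list(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1)), 300)
  expect_error(wham_1d(w, on_disconnected = "error"),
               class = "bindfe_disconnected_error")
  expect_warning(wham_1d(w, on_disconnected = "warn"), "overlap")
})

test_that("BAR handles degenerate and closed-form cases", {
  # zero-width distributions: dF equals the constant work value
  b <- bar(rep(2.5, 100), rep(-2.5, 100), 300)
  expect_equal(b$value, 2.5, tolerance = 1e-8)

  # identical states
  set.seed(8)
  b0 <- bar(rnorm(2000, 0, 0.3), rnorm(2000, 0, 0.3), 300)
  expect_lt(abs(b0$value), 3 * max(b0$stderr, 0.01))

  # harmonic pair U1 = x^2, U2 = 4 x^2 (full convention):
  # dF = (kT/2) ln 4
  set.seed(5)
  n <- 1e5
  x1 <- rnorm(n, 0, sqrt(kB * 300 / 2))
  x2 <- rnorm(n, 0, sqrt(kB * 300 / 8))
  est <- bar(3 * x1^2, -3 * x2^2, 300)
  exact <- kB * 300 / 2 * log(4)
  expect_lt(abs(est$value - exact), 3 * est$stderr)
})

test_that("BAR stderr shrinks like 1/sqrt(N)", {
  sizes <- c(100, 400, 1600, 6400)
  se <- vapply(seq_along(sizes), function(i) {
    set.seed(100 + i)
    n <- sizes[i]
    x1 <- rnorm(n, 0, sqrt(kB * 300 / 2))
    x2 <- rnorm(n, 0, sqrt(kB * 300 / 8))
    bar(3 * x1^2, -3 * x2^2, 300)$stderr
  }, numeric(1))
  slope <- coef(lm(log(se) ~ log(sizes)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("mBAR matches BAR for two states and closed forms for three", {
  set.seed(5)
  n <- 2e4
  beta <- 1 / (kB * 300)
  x1 <- rnorm(n, 0, sqrt(kB * 300 / 2))
  x2 <- rnorm(n, 0, sqrt(kB * 300 / 8))
  xs <- c(x1, x2)
  u <- rbind(beta * xs^2, beta * 4 * xs^2)
  m <- mbar(u, c(n, n), n_blocks = 0)
  est_bar <- bar(3 * x1^2, -3 * x2^2, 300)
  expect_equal(m$f[2] * kB * 300, est_bar$value, tolerance = 1e-6)

  # three-state harmonic ladder U_k = a_k x^2
  a_k <- c(1, 2, 4)
  set.seed(9)
  Nk <- rep(3000, 3)
  xs3 <- unlist(lapply(a_k, function(a) rnorm(3000, 0, sqrt(kB * 300 / (2 * a)))))
  u3 <- do.call(rbind, lapply(a_k, function(a) beta * a * xs3^2))
  m3 <- mbar(u3, Nk)
  exact <- log(a_k / a_k[1]) / 2
  se <- sqrt(pmax(diag(m3$covariance), 1e-12))
  for (k in 2:3)
    expect_lt(abs(m3$f[k] - exact[k]), 3 * se[k])

  # duplicated states get identical free energies
  u_dup <- rbind(u3[1, ], u3[1, ], u3[2, ])
  m_dup <- mbar(u_dup, c(3000, 3000, 3000), n_blocks = 0)
  expect_equal(m_dup$f[1], m_dup$f[2], tolerance = 1e-8)
})

test_that("block error matches hand arithmetic and iid scaling", {
  expect_equal(block_error(rep(4, 50)), 0)
  expect_equal(block_error(1:10, 10), sd(1:10) / sqrt(10), tolerance = 1e-12)
  expect_error(block_error(1:5, 10), class = "bindfe_input_error")

  set.seed(44)
  x <- rnorm(1e4, 0, 2)
  se <- block_error(x, 10)
  expect_lt(abs(se - 2 / sqrt(1e4)) / (2 / sqrt(1e4)), 0.5)
})

test_that("histogram overlap spans its limits and matches quadrature", {
  s <- rnorm(5000)
  w_same <- umbrella_window_set(
    lapply(c(0, 1e-9), function(cen) bias_potential("harmonic_distance", cen, 0)),
    list(s, s), 300)
  expect_equal(histogram_overlap(w_same), 1, tolerance = 1e-12)

  w_disj <- umbrella_window_set(
    lapply(c(0, 100), function(cen) bias_potential("harmonic_distance", cen, 0)),
    list(rnorm(1000), rnorm(1000, 100)), 300)
  expect_equal(histogram_overlap(w_disj), 0)

  # unit-variance Gaussians one sigma apart vs binned-density quadrature
  set.seed(10)
  n <- 2e5
  w2 <- umbrella_window_set(
    lapply(c(0, 1), function(cen) bias_potential("harmonic_distance", cen, 0)),
    list(rnorm(n, 0), rnorm(n, 1)), 300)
  ov <- histogram_overlap(w2, bin_width = 0.1)
  edges <- seq(floor(min(qnorm(1e-9), 0)), 10, by = 0.1)
  p <- diff(pnorm(edges, 0)); q <- diff(pnorm(edges, 1))
  oracle <- sum(sqrt(p * q))
  expect_equal(ov, oracle, tolerance = 0.01)
})

test_that("separation integral I* has exact limits and converges on grid refinement", {
  r <- seq(0, 12, by = 0.05)
  flat <- pmf_profile(r, rep(0, length(r)))
  expect_equal(pmf_to_I_star(flat, c(1, 11), 6), 10, tolerance = 1e-9)

  # Gaussian well, wide range: sqrt(2 pi kT / k_w)
  r2 <- seq(0, 20, by = 0.02)
  W <- 0.5 * (r2 - 10)^2
  p <- pmf_profile(r2, W, temperature = 300)
  expect_equal(pmf_to_I_star(p, c(0.5, 19.5), 10), sqrt(2 * pi * kB * 300),
               tolerance = 1e-4)

  # Richardson: halving the grid changes the result by < 0.1 %
  r_c <- seq(0, 20, by = 0.08)
  p_c <- pmf_profile(r_c, 0.5 * (r_c - 10)^2, temperature = 300)
  r_f <- seq(0, 20, by = 0.04)
  p_f <- pmf_profile(r_f, 0.5 * (r_f - 10)^2, temperature = 300)
  I_c <- pmf_to_I_star(p_c, c(1, 19), 10)
  I_f <- pmf_to_I_star(p_f, c(1, 19), 10)
  expect_lt(abs(I_f - I_c) / I_f, 1e-3)

  # monotone non-decreasing in site width
  widths <- seq(1, 9, by = 1)
  vals <- vapply(widths, function(w) pmf_to_I_star(p, c(10 - w, 10 + w), 10),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(pmf_to_I_star(p, c(-5, 10), 10), class = "bindfe_input_error")
})

test_that("WHAM and mBAR agree on the same windows within combined error", {
  pot <- analytic_potential("polynomial", coefficients = c(0, 0, 2))
  centers <- seq(-1.5, 1.5, by = 0.3)
  ds <- generate_umbrella_dataset(pot, centers, 10, "full", 1500, seed = 13)
  pmf <- wham_1d(ds$windows, bin_width = 0.1)
  fw <- attr(pmf, "window_free_energies")

  beta <- 1 / (kB * 300)
  xs <- unlist(ds$windows$samples)
  u <- do.call(rbind, lapply(ds$windows$biases, function(b)
    beta * (2 * xs^2 + bias_energy(b, xs))))
  m <- mbar(u, vapply(ds$windows$samples, length, numeric(1)), n_blocks = 5)
  f_mbar <- m$f * kB * 300
  se <- sqrt(pmax(diag(m$covariance), 1e-10)) * kB * 300
  dev <- (fw - fw[1]) - (f_mbar - f_mbar[1])
  expect_lt(max(abs(dev[-1]) / pmax(3 * se[-1], 0.05)), 1)
})
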