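test_that("level density is the Gaussian with variance l' sigma^2", {
  expect_equal(level_pdf(0, 1, 1), 1 / sqrt(2 * pi))
  expect_equal(integrate(level_pdf, -Inf, Inf, l_prime = 8)$value, 1,
               tolerance = 1e-6)
  expect_error(level_pdf(0, 8, sigma_J = 0), "sigma_J")
})

test_that("density of states is n times the level density and integrates to n", {
  u <- seq(-10, 10, length.out = 11)
  expect_equal(density_of_states(u, 1, 8), level_pdf(u, 8))
  expect_equal(integrate(density_of_states, -Inf, Inf, n = 800,
                         l_prime = 8)$value, 800, tolerance = 1e-4)

  # Monte-Carlo oracle: binned level counts over realizations at n = 800
  p <- aa_params(master_seed = 17)
  m <- motif_map(p)
  counts <- 0
  breaks <- seq(-12, 12, by = 1)
  for (r in 1:100) {
    en <- srb:::draw_realization_energies(p, 20, 20, 17, r, m)$energies
    counts <- counts + hist(en, breaks = c(-Inf, breaks, Inf), plot = FALSE)$counts
  }
  counts <- counts[2:(length(breaks))] / 100  # drop the two overflow bins
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  expected <- density_of_states(mids, 800, 8)
  central <- abs(mids) < 6
  expect_lt(max(abs(counts[central] - expected[central]) / expected[central]),
            0.1)
})

test_that("Gumbel parameters match an independent numeric quantile oracle", {
  expect_equal(gumbel_params(2, 8)$location, 0)
  expect_error(gumbel_params(1, 8), "n")
  sd_u <- sqrt(8)
  for (n in c(8, 800, 80000)) {
    gp <- gumbel_params(n, 8)
    # invert the Gaussian CDF numerically, independently of qnorm
    q <- function(prob) uniroot(function(x) pnorm(x, 0, sd_u) - prob,
                                c(-60, 60), tol = 1e-12)$root
    expect_equal(gp$location, q(1 / n), tolerance = 1e-8)
    expect_equal(gp$scale, q(1 / n) - q(1 / (n * exp(1))), tolerance = 1e-7)
    expect_gt(gp$scale, 0)
    expect_lte(gp$location, 0)
    expect_equal(gp$phi, -gp$scale)
  }
})

test_that("simulated minima fit a min-Gumbel near the analytic parameters", {
  p <- aa_params(master_seed = 23)
  U <- simulate_nonspecific_minima(p, 20, 20, 5000, seed = 23)
  gp <- gumbel_params(800, 8)
  nll <- function(par) {
    z <- (U - par[1]) / exp(par[2])
    -sum(z - exp(z) - par[2])
  }
  fit <- optim(c(gp$location, log(gp$scale)), nll)
  expect_lt(abs(fit$par[1] / gp$location - 1), 0.05)
  expect_lt(abs(exp(fit$par[2]) / gp$scale - 1), 0.05)
})

test_that("nonspecific density is a normalized min-Gumbel peaked at mu", {
  gp <- gumbel_params(800, 8)
  expect_equal(integrate(nonspecific_pdf, -30, 10, gp = gp)$value, 1,
               tolerance = 1e-6)
  u <- seq(gp$location - 6, gp$location + 6, length.out = 4001)
  expect_equal(u[which.max(nonspecific_pdf(u, gp))], gp$location,
               tolerance = 1e-2)
  # negligible weight at U > 0 for realistic level counts
  expect_lt(1 - nonspecific_cdf(0, gp), 1e-3)
  expect_lt(1 - nonspecific_cdf(0, gumbel_params(80000, 8)), 1e-3)
})

test_that("mean nonspecific energy is mu - gamma beta, decreasing in n and l'", {
  gp <- gumbel_params(800, 8)
  gamma <- 0.5772156649
  expect_equal(mean_nonspecific(gp), gp$location - gamma * gp$scale,
               tolerance = 1e-9)
  for (lp in c(2, 6, 10, 14, 18)) {
    means <- vapply(c(8, 72, 800, 7200, 80000),
                    function(n) mean_nonspecific(gumbel_params(n, lp)),
                    numeric(1))
    expect_true(all(diff(means) < 0))
    expect_true(all(means < 0))
  }
  at_n <- vapply(c(2, 6, 10, 14, 18),
                 function(lp) mean_nonspecific(gumbel_params(800, lp)),
                 numeric(1))
  expect_true(all(diff(at_n) < 0))

  # Monte-Carlo: sample mean of simulated minima near the analytic mean
  # (asymptotic formula; agreement at the few-percent-of-beta level)
  p <- aa_params(master_seed = 29)
  U <- simulate_nonspecific_minima(p, 20, 20, 2000, seed = 29)
  expect_lt(abs(mean(U) - mean_nonspecific(gp)), 0.1)
})

test_that("the Gumbel formulas are asymptotic: exact finite-n error is resolved", {
  # order-statistic oracle for the minimum of n iid Gaussian levels
  n <- 800; sd_u <- sqrt(8)
  dens <- function(x) n * dnorm(x, 0, sd_u) * pnorm(x, 0, sd_u,
                                                    lower.tail = FALSE)^(n - 1)
  expect_equal(integrate(dens, -30, 10, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  exact_mean <- integrate(function(x) x * dens(x), -30, 10,
                          rel.tol = 1e-10)$value
  gp <- gumbel_params(n, 8)
  # the asymptotic mean overshoots the exact mean by ~0.04 sigma_J at n = 800
  expect_equal(exact_mean - mean_nonspecific(gp), 0.0405, tolerance = 0.002)
  # exact sup-distance between the true minimum law and the Gumbel ~ 0.015
  Fmin <- function(x) 1 - pnorm(x, 0, sd_u, lower.tail = FALSE)^n
  xs <- seq(-16, -3, length.out = 5001)
  D <- max(abs(Fmin(xs) - nonspecific_cdf(xs, gp)))
  expect_gt(D, 0.010)
  expect_lt(D, 0.020)
})

test_that("critical temperature follows the closed form and sqrt(l') scaling", {
  expect_equal(critical_temperature(exp(2), 2), sqrt(0.5), tolerance = 1e-12)
  expect_equal(critical_temperature(800, 8) / critical_temperature(800, 2), 2)
  # independent evaluation through logs, 12 digits
  n <- 800; lp <- 8
  expect_equal(critical_temperature(n, lp),
               exp(0.5 * (log(lp) - log(2) - log(log(n)))), tolerance = 1e-12)
  expect_error(critical_temperature(1, 8), "n")
})

test_that("REM participation limit is the broken line max(0, 1 - T/Tc)", {
  expect_equal(rem_participation_limit(1, 1), 0)
  expect_equal(rem_participation_limit(0, 1), 1)
  expect_equal(rem_participation_limit(0.5, 1), 0.5)
  expect_equal(rem_participation_limit(c(2, 3), 1), c(0, 0))
  expect_error(rem_participation_limit(-0.1, 1), "non-negative")
})

test_that("invertible fraction matches exhaustive enumeration", {
  expect_equal(invertible_fraction(4, 10, 1), 1)
  expect_equal(invertible_fraction(2, 3, 2), 0.5)
  expect_equal(invertible_fraction(4, 10, 3), 4^-14)
  expect_error(invertible_fraction(2, 3, 4), "xi")

  # ||A|| = 2, l = 3, xi = 2: 8 of the 16 motif sequences have a preimage
  p <- srb_params(alphabet_size = 2, peptide_length = 3, xi = 2)
  m <- motif_map(p)
  grid <- expand.grid(m1 = 0:3, m2 = 0:3)
  invertible <- vapply(seq_len(nrow(grid)), function(k) {
    !is.null(invert_secondary(c(grid$m1[k], grid$m2[k]), m))
  }, logical(1))
  expect_equal(sum(invertible), 8L)
  expect_equal(mean(invertible), invertible_fraction(2, 3, 2))
  # and every primary sequence round-trips through its image
  seqs <- expand.grid(rep(list(0:1), 3))
  for (k in seq_len(nrow(seqs))) {
    s <- as.integer(seqs[k, ])
    expect_identical(invert_secondary(encode_secondary(s, m), m), s)
  }
})
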