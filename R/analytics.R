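#' Density of a single epitope-pair binding energy
#'
#' An oriented peptide-pair energy is the sum of `l_prime` independent
#' Gaussian couplings, hence Gaussian with mean 0 and variance
#' \eqn{l' \sigma_J^2}.  With Gaussian couplings this holds exactly at
#' every `l_prime`, not just asymptotically.
#'
#' @param u energy (vectorized).
#' @param l_prime interaction length \eqn{l' \ge 1}.
#' @param sigma_J coupling scale, positive.
#' @return Density values.
#' @export
level_pdf <- function(u, l_prime, sigma_J = 1) {
  if (l_prime < 1) stop("l_prime must be at least 1")
  if (sigma_J <= 0) stop("sigma_J must be positive")
  dnorm(u, mean = 0, sd = sqrt(l_prime) * sigma_J)
}

#' Expected density of states of an n-level complex
#'
#' \eqn{\langle\rho(u)\rangle = n \, P(u)}: `n` iid levels drawn from the
#' pair-energy law.
#'
#' @param u energy (vectorized).
#' @param n number of levels, at least 1.
#' @inheritParams level_pdf
#' @return Expected state count density.
#' @export
density_of_states <- function(u, n, l_prime, sigma_J = 1) {
  if (n < 1) stop("n must be at least 1")
  n * level_pdf(u, l_prime, sigma_J)
}

#' Gumbel parameters of the nonspecific binding energy distribution
#'
#' The complex binding energy of two random proteins is the minimum of
#' `n` iid Gaussian levels; for large `n` it follows a min-type Gumbel
#' law.  The location is the lower `1/n` quantile of the level law,
#' \eqn{\mu = -\sqrt{2 l' \sigma_J^2}\,\mathrm{erf}^{-1}(1 - 2/n)}, and
#' the positive scale is the quantile spacing
#' \eqn{\beta = \sqrt{2 l' \sigma_J^2}\,[\mathrm{erf}^{-1}(1 - 2/(ne)) -
#' \mathrm{erf}^{-1}(1 - 2/n)]}, i.e. the distance between the `1/n` and
#' `1/(ne)` lower quantiles.  The field's customary scale parameter
#' \eqn{\phi = \mu - \sqrt{2 l' \sigma_J^2}\,\mathrm{erf}^{-1}(1 - 2/(ne))}
#' is negative; it is exposed as `phi = -beta` so the min-Gumbel mean can
#' be written either \eqn{\mu + \gamma\phi} or \eqn{\mu - \gamma\beta}.
#' These are asymptotic (large `n`) parameters, exposed for all
#' \eqn{n \ge 2}.
#'
#' @param n number of levels (\eqn{n = 2 n_P n_B} for a heterodimer), at
#'   least 2.
#' @inheritParams level_pdf
#' @return An object of class `srb_gumbel`: a list with `location`
#'   (\eqn{\mu}), `scale` (\eqn{\beta > 0}), `phi` (\eqn{-\beta}), `n`,
#'   `l_prime`, `sigma_J`.
#' @examples
#' gumbel_params(n = 800, l_prime = 8)
#' @export
gumbel_params <- function(n, l_prime, sigma_J = 1) {
  if (n < 2) stop("n must be at least 2")
  if (l_prime < 1) stop("l_prime must be at least 1")
  if (sigma_J <= 0) stop("sigma_J must be positive")
  sd_u <- sqrt(l_prime) * sigma_J
  mu <- qnorm(1 / n, mean = 0, sd = sd_u)
  beta <- mu - qnorm(1 / (n * exp(1)), mean = 0, sd = sd_u)
  structure(list(location = mu, scale = beta, phi = -beta,
                 n = n, l_prime = l_prime, sigma_J = sigma_J),
            class = "srb_gumbel")
}

#' @export
print.srb_gumbel <- function(x, ...) {
  cat(sprintf(
    "Nonspecific binding Gumbel law (n = %s, l' = %d, sigma_J = %g)\n",
    format(x$n), x$l_prime, x$sigma_J))
  cat(sprintf("  location mu = %.6f, scale beta = %.6f (phi = %.6f)\n",
              x$location, x$scale, x$phi))
  cat(sprintf("  mean <U>_NS = %.6f\n", mean_nonspecific(x)))
  invisible(x)
}

#' Density of the nonspecific complex binding energy
#'
#' Min-type Gumbel density
#' \eqn{P_{NS}(U) = \beta^{-1} \exp[z - e^{z}]} with
#' \eqn{z = (U - \mu)/\beta}.  Its mode sits at \eqn{U = \mu} and for the
#' level counts of realistic surfaces essentially all its weight lies at
#' \eqn{U < 0}: nonspecific binding is generic.
#'
#' @param U complex binding energy (vectorized).
#' @param gp an [gumbel_params()] object.
#' @return Density values.
#' @export
nonspecific_pdf <- function(U, gp) {
  stopifnot(inherits(gp, "srb_gumbel"))
  z <- (U - gp$location) / gp$scale
  exp(z - exp(z)) / gp$scale
}

#' Cumulative distribution of the nonspecific binding energy
#'
#' \eqn{F_{NS}(U) = 1 - \exp(-e^{(U - \mu)/\beta})}.
#'
#' @inheritParams nonspecific_pdf
#' @return CDF values.
#' @export
nonspecific_cdf <- function(U, gp) {
  stopifnot(inherits(gp, "srb_gumbel"))
  1 - exp(-exp((U - gp$location) / gp$scale))
}

#' Mean nonspecific binding energy
#'
#' Disorder-averaged complex binding energy of random proteins:
#' \eqn{\langle U\rangle_{NS} = \mu - \gamma\beta} (equivalently
#' \eqn{\mu + \gamma\phi}), with \eqn{\gamma} the Euler-Mascheroni
#' constant.  Strictly negative for \eqn{n \ge 3} and strictly decreasing
#' in `n`: larger surfaces bind more tightly even at zero mean coupling.
#'
#' @param gp an [gumbel_params()] object.
#' @return The mean \eqn{\langle U\rangle_{NS}}.
#' @export
mean_nonspecific <- function(gp) {
  stopifnot(inherits(gp, "srb_gumbel"))
  gp$location - (-digamma(1)) * gp$scale
}

#' Condensation (freezing) temperature
#'
#' Critical temperature of the random-energy-model condensation
#' transition for an `n`-level complex,
#' \eqn{T_c = \sigma_J \sqrt{l' / (2 \log n)}}; slowly varying in both
#' `n` and `l_prime`.
#'
#' @param n number of levels, at least 2.
#' @inheritParams level_pdf
#' @return The critical temperature (units of `sigma_J`).
#' @examples
#' critical_temperature(800, 8)
#' @export
critical_temperature <- function(n, l_prime, sigma_J = 1) {
  if (n < 2) stop("n must be at least 2")
  if (l_prime < 1) stop("l_prime must be at least 1")
  if (sigma_J <= 0) stop("sigma_J must be positive")
  sigma_J * sqrt(l_prime / (2 * log(n)))
}

#' Limiting mean participation ratio of the random energy model
#'
#' In the thermodynamic limit the disorder-averaged participation ratio is
#' \eqn{\langle Y(T)\rangle = \max(0, 1 - T/T_c)}: zero in the
#' high-temperature phase, rising linearly below the condensation
#' temperature to 1 in the frozen limit.
#'
#' @param temperature temperature(s), non-negative.
#' @param t_c critical temperature, positive.
#' @return \eqn{\langle Y\rangle} values.
#' @export
rem_participation_limit <- function(temperature, t_c) {
  if (any(temperature < 0)) stop("temperature must be non-negative")
  if (t_c <= 0) stop("t_c must be positive")
  pmax(0, 1 - temperature / t_c)
}

#' Fraction of motif sequences that are images of primary sequences
#'
#' Sliding windows overlap, so fixing one motif constrains its
#' neighbours: only a fraction \eqn{\|A\|^{\,l - (l - \xi + 1)\xi}} of all
#' motif sequences is invertible to a primary sequence.  At `xi = 1`
#' every motif sequence is invertible; for intermediate `xi` the
#' invertible set is exponentially small and sparse, which is what makes
#' affinity optimisation hard in that regime.
#'
#' @param alphabet_size primary alphabet size, at least 2.
#' @param l peptide length.
#' @param xi structural correlation length, in `1:l`.
#' @return The invertible fraction.
#' @examples
#' invertible_fraction(2, 3, 2)   # 1/2
#' invertible_fraction(4, 10, 3)  # 4^-14
#' @export
invertible_fraction <- function(alphabet_size, l, xi) {
  if (alphabet_size < 2) stop("alphabet_size must be at least 2")
  if (xi < 1 || xi > l) stop("xi must satisfy 1 <= xi <= l")
  as.numeric(alphabet_size)^(l - (l - xi + 1) * xi)
}
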