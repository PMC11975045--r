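spectrum_energies <- function(x) {
  if (inherits(x, "srb_spectrum")) x$energy
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected an srb_spectrum or a numeric vector of energies")
}

#' Participation ratio of the complex Boltzmann measure
#'
#' \eqn{Y(T) = \sum_k e^{-2u_k/T} / (\sum_k e^{-u_k/T})^2} over the
#' levels of one complex: the probability that two independent samples of
#' the complex occupy the same configuration, so `1/Y` counts the states
#' dominating the Boltzmann measure.  Boltzmann weights are computed
#' after shifting energies by the spectrum minimum (equivalent to
#' log-sum-exp), so there is no overflow even when \eqn{|u|/T} is large.
#'
#' @param x an `srb_spectrum` or numeric vector of level energies.
#' @param temperature positive temperature(s); vectorized.  The
#'   \eqn{T \to 0} value (ground-state degeneracy / number of levels) is
#'   a limit, not an admissible argument.
#' @return \eqn{Y(T)}, between `1/n_levels` and 1.
#' @examples
#' participation_ratio(c(0, 1), temperature = c(0.1, 1, 10))
#' @export
participation_ratio <- function(x, temperature) {
  u <- spectrum_energies(x)
  if (length(u) == 0) stop("empty spectrum")
  if (any(temperature <= 0)) stop("temperature must be positive (T = 0 is the degeneracy limit)")
  umin <- min(u)
  vapply(temperature, function(tt) {
    w <- exp(-(u - umin) / tt)
    sum(w^2) / sum(w)^2
  }, numeric(1))
}

#' Melting curve of a single complex
#'
#' Evaluates `Y(T)` on a temperature grid together with the central
#' finite-difference derivative; the melting temperature is reported as
#' the grid point where \eqn{-dY/dT} peaks (no interpolation).  Distinct
#' realizations drawn from the same coupling law can show very different
#' melting curves: below the condensation temperature the thermodynamics
#' is controlled by a handful of low-lying levels, so it is sensitive to
#' the realization's low-energy tail.
#'
#' @param x an `srb_spectrum` or numeric vector of level energies.
#' @param temperatures strictly increasing grid of at least 3 positive
#'   temperatures.
#' @return A data frame of class `srb_melting_curve` with columns
#'   `temperature`, `Y`, `dY_dT` (`NA` at the ends), and attribute
#'   `melting_temperature` (`NA` when the curve is flat).
#' @export
melting_curve <- function(x, temperatures) {
  u <- spectrum_energies(x)
  tt <- as.numeric(temperatures)
  if (length(tt) < 3 || any(tt <= 0) || any(diff(tt) <= 0))
    stop("temperatures must be >= 3 strictly increasing positive values")
  Y <- participation_ratio(u, tt)
  n <- length(tt)
  dY <- rep(NA_real_, n)
  dY[2:(n - 1)] <- (Y[3:n] - Y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  interior <- -dY[2:(n - 1)]
  tm <- if (max(abs(interior)) < 1e-12) NA_real_
        else tt[1L + which.max(interior)]
  structure(data.frame(temperature = tt, Y = Y, dY_dT = dY),
            class = c("srb_melting_curve", "data.frame"),
            melting_temperature = tm)
}

#' @export
print.srb_melting_curve <- function(x, ...) {
  tm <- attr(x, "melting_temperature")
  cat(sprintf("SRB melting curve: %d temperatures, melting T = %s\n",
              nrow(x), if (is.na(tm)) "undefined (flat)" else format(tm)))
  invisible(x)
}

# one heterodimer realization: fresh proteins and couplings from derived
# stream seeds; returns the oriented energy matrices
draw_realization_energies <- function(params, nP, nB, seed, index, map = NULL) {
  if (is.null(map)) map <- motif_map(params)
  sc <- srb_stream_seed(seed, "realization-coupling", index)
  sp <- srb_stream_seed(seed, "realization-protein-P", index)
  sb <- srb_stream_seed(seed, "realization-protein-B", index)
  P <- random_protein(params, nP, seed = sp)
  B <- random_protein(params, nB, seed = sb)
  en <- cpp_pair_energies(protein_motifs(P, map), protein_motifs(B, map),
                          sc, params$sigma_J)
  list(energies = c(en$parallel, en$antiparallel), coupling_seed = sc,
       P = P, B = B)
}

#' Disorder-averaged participation ratio
#'
#' Averages `Y(T)` over independent realizations of the quenched
#' randomness (fresh proteins and fresh couplings per realization) on a
#' grid of reduced temperatures \eqn{T/T_c}, with
#' \eqn{T_c} from [critical_temperature()] at \eqn{n = 2 n_P n_B}.  As
#' `n` grows the mean curve approaches the REM limit
#' \eqn{\max(0, 1 - T/T_c)}.
#'
#' @param params an [srb_params()] object.
#' @param nP,nB epitope counts of the two proteins.
#' @param t_over_tc grid of reduced temperatures (positive).
#' @param n_realizations number of disorder realizations, at least 1.
#' @param seed stream seed for the realization draws; defaults to the
#'   master seed.
#' @return A data frame with columns `t_over_tc`, `temperature`,
#'   `Y_mean`, `Y_se`; attributes `n`, `t_c`, `n_realizations`.
#' @export
ensemble_mean_participation <- function(params, nP, nB,
                                        t_over_tc = seq(0.05, 2, length.out = 64),
                                        n_realizations = 100, seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (n_realizations < 1) stop("n_realizations must be at least 1")
  if (any(t_over_tc <= 0)) stop("t_over_tc must be positive")
  if (is.null(seed)) seed <- params$master_seed
  n <- 2 * nP * nB
  tc <- critical_temperature(n, params$l_prime, params$sigma_J)
  temps <- t_over_tc * tc
  map <- motif_map(params)
  acc <- matrix(0, n_realizations, length(temps))
  for (r in seq_len(n_realizations)) {
    en <- draw_realization_energies(params, nP, nB, seed, r, map)$energies
    acc[r, ] <- participation_ratio(en, temps)
  }
  out <- data.frame(
    t_over_tc = t_over_tc,
    temperature = temps,
    Y_mean = colMeans(acc),
    Y_se = apply(acc, 2L, sd) / sqrt(n_realizations))
  structure(out, n = n, t_c = tc, n_realizations = n_realizations)
}

#' Simulate nonspecific complex binding energies
#'
#' Draws independent realizations of two random proteins plus fresh
#' couplings and records the complex binding energy (the spectrum
#' minimum) of each: the empirical counterpart of the analytic Gumbel law
#' of [gumbel_params()].
#'
#' @param params an [srb_params()] object.
#' @param nP,nB epitope counts.
#' @param n_realizations number of realizations.
#' @param seed stream seed; defaults to the master seed.
#' @return Numeric vector of `n_realizations` binding energies.
#' @export
simulate_nonspecific_minima <- function(params, nP, nB, n_realizations,
                                        seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (is.null(seed)) seed <- params$master_seed
  map <- motif_map(params)
  vapply(seq_len(n_realizations), function(r) {
    min(draw_realization_energies(params, nP, nB, seed, r, map)$energies)
  }, numeric(1))
}
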