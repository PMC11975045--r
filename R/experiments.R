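# Scripted experiments: each run_*() computes one of the model's headline
# simulations and writes TSV tables plus a JSON manifest (full configuration
# + seeds + package version) into `out_dir`.  The "smoke" profile finishes in
# seconds; "paper" is a desk-scale run taking minutes.

write_manifest <- function(out_dir, experiment, seed, profile, config) {
  jsonlite::write_json(
    list(experiment = experiment,
         package = "srb",
         version = as.character(packageVersion("srb")),
         seed = seed,
         profile = profile,
         config = config),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(seq_len(n) / n - Fx))
}

#' Experiment: nonspecific binding energy distribution
#'
#' Simulates complex binding energies of random proteins over a grid of
#' surface sizes and interaction lengths, and compares the empirical
#' minima with the analytic Gumbel law: location/scale, mean, and the
#' Kolmogorov-Smirnov distance.
#'
#' @param out_dir output directory (created if needed).
#' @param profile `"smoke"` (seconds) or `"paper"` (desk-scale).
#' @param seed master seed for the experiment.
#' @param l_prime_grid interaction lengths to scan (default
#'   `c(2, 6, 10, 14, 18)`; `xi` is held at 3 and the peptide length is
#'   `l_prime + xi - 1`).
#' @param n_pairs_grid per-protein epitope counts `nP = nB`; level count
#'   is `n = 2 * nP^2`.  `NULL` selects a profile-dependent default.
#' @param n_realizations minima per grid point; `NULL` for the profile
#'   default.
#' @return The summary data frame, invisibly; writes `summary.tsv` and
#'   `manifest.json`.
#' @export
run_nonspecific_distribution <- function(out_dir, profile = c("smoke", "paper"),
                                         seed = 1,
                                         l_prime_grid = c(2, 6, 10, 14, 18),
                                         n_pairs_grid = NULL,
                                         n_realizations = NULL) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(n_pairs_grid))
    n_pairs_grid <- if (profile == "smoke") c(2, 6, 20) else c(2, 6, 20, 60, 200)
  if (is.null(n_realizations))
    n_realizations <- if (profile == "smoke") 300 else 2000
  xi <- 3
  rows <- list()
  for (lp in l_prime_grid) {
    params <- srb_params(alphabet_size = 4, peptide_length = lp + xi - 1,
                         xi = xi, master_seed = seed)
    for (np in n_pairs_grid) {
      n <- 2 * np * np
      s <- srb_stream_seed(seed, sprintf("nonspecific-lp%d-np%d", lp, np))
      U <- simulate_nonspecific_minima(params, np, np, n_realizations, seed = s)
      gp <- gumbel_params(n, lp, params$sigma_J)
      rows[[length(rows) + 1L]] <- data.frame(
        l_prime = lp, n = n, n_realizations = n_realizations,
        empirical_mean = mean(U),
        empirical_se = sd(U) / sqrt(n_realizations),
        mu = gp$location, beta = gp$scale, phi = gp$phi,
        analytic_mean = mean_nonspecific(gp),
        ks_distance = if (n >= 4) ks_distance(U, function(x) nonspecific_cdf(x, gp))
                      else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  write_tsv(out, file.path(out_dir, "summary.tsv"))
  write_manifest(out_dir, "nonspecific_distribution", seed, profile,
                 list(l_prime_grid = l_prime_grid, n_pairs_grid = n_pairs_grid,
                      n_realizations = n_realizations, xi = xi))
  invisible(out)
}

#' Experiment: condensation transition
#'
#' Disorder-averaged participation-ratio curves on a reduced-temperature
#' grid for a range of level counts, approaching the REM limit
#' `1 - T/Tc`, together with a few single realizations illustrating
#' realization-to-realization chaos and their melting temperatures.
#'
#' @inheritParams run_nonspecific_distribution
#' @param n_pairs_grid per-protein epitope counts; `NULL` for the profile
#'   default (`n = 2 nP^2` spans 8 to 80000 in the paper profile).
#' @param n_realizations realizations per grid point.
#' @return Invisibly, the mean-curve data frame; writes
#'   `mean_participation.tsv`, `single_realizations.tsv`, `melting.tsv`
#'   and `manifest.json`.
#' @export
run_condensation <- function(out_dir, profile = c("smoke", "paper"), seed = 1,
                             n_pairs_grid = NULL, n_realizations = NULL) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(n_pairs_grid))
    n_pairs_grid <- if (profile == "smoke") c(2, 6, 20) else c(2, 6, 20, 60, 200)
  if (is.null(n_realizations))
    n_realizations <- if (profile == "smoke") 40 else 200
  grid_len <- if (profile == "smoke") 33 else 64
  t_over_tc <- seq(0.05, 2, length.out = grid_len)
  params <- srb_params(alphabet_size = 4, peptide_length = 10, xi = 3,
                       master_seed = seed)
  mean_rows <- list()
  for (np in n_pairs_grid) {
    s <- srb_stream_seed(seed, sprintf("condensation-np%d", np))
    m <- ensemble_mean_participation(params, np, np, t_over_tc,
                                     n_realizations, seed = s)
    m$n <- attr(m, "n")
    m$rem_limit <- rem_participation_limit(m$temperature, attr(m, "t_c"))
    mean_rows[[length(mean_rows) + 1L]] <- m
  }
  mean_df <- do.call(rbind, mean_rows)
  write_tsv(mean_df, file.path(out_dir, "mean_participation.tsv"))

  # four individual realizations at nP = nB = 20 (n = 800)
  np <- 20
  tc <- critical_temperature(2 * np * np, params$l_prime, params$sigma_J)
  single_rows <- list(); melt_rows <- list()
  s <- srb_stream_seed(seed, "condensation-single")
  for (r in 1:4) {
    re <- draw_realization_energies(params, np, np, s, r)
    mc <- melting_curve(re$energies, t_over_tc * tc)
    single_rows[[r]] <- data.frame(
      realization = r, temperature = mc$temperature,
      t_over_tc = mc$temperature / tc, Y = mc$Y, dY_dT = mc$dY_dT)
    melt_rows[[r]] <- data.frame(
      realization = r, U = min(re$energies),
      melting_temperature = attr(mc, "melting_temperature"))
  }
  write_tsv(do.call(rbind, single_rows),
            file.path(out_dir, "single_realizations.tsv"))
  write_tsv(do.call(rbind, melt_rows), file.path(out_dir, "melting.tsv"))
  write_manifest(out_dir, "condensation", seed, profile,
                 list(n_pairs_grid = n_pairs_grid,
                      n_realizations = n_realizations,
                      t_over_tc = range(t_over_tc), grid_len = grid_len))
  invisible(mean_df)
}

#' Experiment: affinity evolution across structural correlation lengths
#'
#' Doubly-averaged binding-energy trajectories of coevolving heterodimer
#' ensembles for a range of `xi`, plus a specificity assay at `xi = 3`.
#' Affinity gain is largest when `xi` is short, because short windows let
#' selection optimise the motif sequence almost term by term.
#'
#' @inheritParams run_nonspecific_distribution
#' @param xi_grid structural correlation lengths to scan.
#' @param generations,ensemble_size,n_realizations evolution scale;
#'   `NULL` for profile defaults.
#' @return Invisibly, the trajectory data frame; writes
#'   `trajectories.tsv`, `final.tsv`, `specificity.tsv`, `manifest.json`.
#' @export
run_evolution_sweep <- function(out_dir, profile = c("smoke", "paper"), seed = 1,
                                xi_grid = NULL, generations = NULL,
                                ensemble_size = NULL, n_realizations = NULL) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(xi_grid)) xi_grid <- if (profile == "smoke") c(2, 7) else 2:7
  if (is.null(generations)) generations <- if (profile == "smoke") 60 else 1000
  if (is.null(ensemble_size)) ensemble_size <- if (profile == "smoke") 100 else 1000
  if (is.null(n_realizations)) n_realizations <- if (profile == "smoke") 1 else 3
  traj_rows <- list(); final_rows <- list()
  assay_results <- list()
  for (xi in xi_grid) {
    params <- srb_params(alphabet_size = 4, peptide_length = 10, xi = xi,
                         master_seed = seed)
    acc <- matrix(0, n_realizations, generations)
    for (r in seq_len(n_realizations)) {
      evo <- evolution_params(ensemble_size = ensemble_size,
                              mutation_rate = 0.01,
                              generations = generations,
                              mode = "heterodimer",
                              seed = srb_stream_seed(seed,
                                sprintf("sweep-xi%d", xi), r))
      res <- evolve_population(params, evo, n_epitopes = 20)
      acc[r, ] <- res$trajectory$mean_U
      final_rows[[length(final_rows) + 1L]] <- data.frame(
        xi = xi, realization = r,
        final_mean_U = res$trajectory$mean_U[generations],
        final_min_U = min(res$final_U))
      if (xi == 3) assay_results[[length(assay_results) + 1L]] <- res
    }
    traj_rows[[length(traj_rows) + 1L]] <- data.frame(
      xi = xi, generation = seq_len(generations),
      mean_U = colMeans(acc))
  }
  traj_df <- do.call(rbind, traj_rows)
  write_tsv(traj_df, file.path(out_dir, "trajectories.tsv"))
  write_tsv(do.call(rbind, final_rows), file.path(out_dir, "final.tsv"))
  if (length(assay_results)) {
    assay <- specificity_assay(assay_results,
                               n_random_partners = if (profile == "smoke") 50 else 200,
                               seed = srb_stream_seed(seed, "sweep-assay"))
    write_tsv(data.frame(
      sample = c(rep("evolved", length(assay$evolved)),
                 rep("random_partner", length(assay$random))),
      U = c(assay$evolved, assay$random)),
      file.path(out_dir, "specificity.tsv"))
  }
  write_manifest(out_dir, "evolution_sweep", seed, profile,
                 list(xi_grid = xi_grid, generations = generations,
                      ensemble_size = ensemble_size,
                      n_realizations = n_realizations))
  invisible(traj_df)
}

#' Experiment: homodimer interface bias
#'
#' Estimates the variance doubling of antiparallel isologous
#' self-binding, the interface census of random homodimers, and the
#' census after affinity evolution.
#'
#' @inheritParams run_nonspecific_distribution
#' @param n_variance_peptides peptides for the variance-ratio estimate.
#' @param n_census random-census realizations.
#' @param n_evolved,generations,ensemble_size evolved-census scale;
#'   `NULL` for profile defaults.
#' @return Invisibly, a list with the three results; writes
#'   `variance.tsv`, `census_random.tsv`, `census_evolved.tsv`,
#'   `manifest.json`.
#' @export
run_homodimer_bias <- function(out_dir, profile = c("smoke", "paper"), seed = 1,
                               n_variance_peptides = NULL, n_census = NULL,
                               n_evolved = NULL, generations = NULL,
                               ensemble_size = NULL) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(n_variance_peptides))
    n_variance_peptides <- if (profile == "smoke") 2e4 else 1e5
  if (is.null(n_census)) n_census <- if (profile == "smoke") 1000 else 10000
  if (is.null(n_evolved)) n_evolved <- if (profile == "smoke") 4 else 50
  if (is.null(generations)) generations <- if (profile == "smoke") 120 else 1000
  if (is.null(ensemble_size)) ensemble_size <- if (profile == "smoke") 200 else 1000
  params <- srb_params(alphabet_size = 4, peptide_length = 10, xi = 3,
                       master_seed = seed)
  vr <- isologous_variance_ratio(params, n_variance_peptides,
                                 seed = srb_stream_seed(seed, "bias-variance"))
  write_tsv(data.frame(var_parallel = vr$var_parallel,
                       var_antiparallel = vr$var_antiparallel,
                       ratio = vr$ratio, n_peptides = vr$n_peptides),
            file.path(out_dir, "variance.tsv"))
  cen <- random_homodimer_census(params, 20, n_census,
                                 seed = srb_stream_seed(seed, "bias-census"))
  write_tsv(as.data.frame(cen), file.path(out_dir, "census_random.tsv"))
  evo <- evolution_params(ensemble_size = ensemble_size, mutation_rate = 0.01,
                          generations = generations, mode = "homodimer")
  ecen <- evolved_homodimer_census(params, evo, n_realizations = n_evolved,
                                   n_epitopes = 20,
                                   seed = srb_stream_seed(seed, "bias-evolved"))
  write_tsv(as.data.frame(ecen), file.path(out_dir, "census_evolved.tsv"))
  write_manifest(out_dir, "homodimer_bias", seed, profile,
                 list(n_variance_peptides = n_variance_peptides,
                      n_census = n_census, n_evolved = n_evolved,
                      generations = generations,
                      ensemble_size = ensemble_size))
  invisible(list(variance = vr, census_random = cen, census_evolved = ecen))
}
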