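#' Parameters for mutation-selection affinity evolution
#'
#' An ensemble of `ensemble_size` binary complexes, founded as identical
#' copies of one random complex, evolves by per-residue mutation followed
#' by selection with the Fermi survival probability of
#' [survival_probability()].  The selection threshold coevolves with the
#' ensemble: each generation it is set to the current (post-mutation,
#' pre-selection) ensemble mean binding energy, which maintains selection
#' pressure as affinities improve.  Survivors are resampled uniformly
#' with replacement back to the fixed ensemble size (a Wright-Fisher
#' style choice); if no member survives, the pre-selection ensemble is
#' retained for that generation.
#'
#' @param ensemble_size number of complexes `N`, at least 2.
#' @param mutation_rate per-residue substitution probability per
#'   generation, in `[0, 1]`.
#' @param generations number of generations to simulate.
#' @param selection_width energy width of the Fermi survival rule;
#'   `NULL` (default) means `sigma_J` of the model.
#' @param mode `"heterodimer"` (both proteins mutate) or `"homodimer"`
#'   (a single protein binding its own copy).
#' @param seed integer seed for founder, couplings and the stochastic
#'   dynamics.
#' @return An object of class `srb_evolution_params`.
#' @export
evolution_params <- function(ensemble_size = 1000, mutation_rate = 0.01,
                             generations = 1000, selection_width = NULL,
                             mode = c("heterodimer", "homodimer"), seed = 1) {
  mode <- match.arg(mode)
  ensemble_size <- as.integer(ensemble_size)
  generations <- as.integer(generations)
  if (is.na(ensemble_size) || ensemble_size < 2)
    stop("ensemble_size must be at least 2")
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (is.na(generations) || generations < 0)
    stop("generations must be non-negative")
  if (!is.null(selection_width) && selection_width <= 0)
    stop("selection_width must be positive")
  structure(list(ensemble_size = ensemble_size,
                 mutation_rate = mutation_rate,
                 generations = generations,
                 selection_width = selection_width,
                 mode = mode,
                 seed = as.integer(seed)),
            class = "srb_evolution_params")
}

#' Mutate a protein
#'
#' Each residue is independently substituted with probability `epsilon`;
#' a substitution draws uniformly from the other `alphabet_size - 1`
#' letters, so a mutated residue always changes.
#'
#' @param protein an `srb_protein`.
#' @param epsilon per-residue substitution probability in `[0, 1]`.
#' @param seed optional seed; by default the current RNG state is used.
#' @return The mutated `srb_protein`.
#' @export
mutate_protein <- function(protein, epsilon, seed = NULL) {
  stopifnot(inherits(protein, "srb_protein"))
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1]")
  A <- attr(protein, "alphabet_size")
  doit <- function() {
    res <- unclass(protein)
    hit <- which(runif(length(res)) < epsilon)
    if (length(hit))
      res[hit] <- (res[hit] + sample.int(A - 1L, length(hit), replace = TRUE)) %% A
    res
  }
  res <- if (is.null(seed)) doit() else with_seed(seed, doit())
  structure(res, class = "srb_protein", alphabet_size = A)
}

#' Fermi survival probability
#'
#' \eqn{\Theta(U; U_0) = 1 / (e^{(U - U_0)/w} + 1)}: a soft affinity
#' threshold of width `width` centred at `U0`, monotone decreasing in the
#' binding energy `U`.
#'
#' @param U binding energy (vectorized).
#' @param U0 selection threshold.
#' @param width Fermi width, positive (the model uses `sigma_J`).
#' @return Survival probabilities in `(0, 1)`.
#' @examples
#' survival_probability(0, 0, 1)      # 0.5
#' survival_probability(1, 0, 1)      # 1/(e + 1)
#' @export
survival_probability <- function(U, U0, width) {
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  1 / (exp((U - U0) / width) + 1)
}

#' Evolve an ensemble of binary complexes
#'
#' Runs the mutation-selection dynamics of [evolution_params()] in a
#' compiled kernel.  In heterodimer mode both proteins of each complex
#' mutate and the binding energy is the minimum over all `nP x nB`
#' epitope pairs in both orientations; in homodimer mode a single protein
#' mutates and the energy is the minimum of the homodimer level set of
#' [homodimer_spectrum()].
#'
#' @param params an [srb_params()] object.
#' @param evo an [evolution_params()] object.
#' @param n_epitopes epitopes per protein (default 20).
#' @param map optional [motif_map()]; identity by default.
#' @return An object of class `srb_evolution` with elements `trajectory`
#'   (data frame: `generation`, `U0`, `mean_U`, `min_U`, `survivors`,
#'   `mean_U_selected`), `final_U`, `best_index`, the founder proteins
#'   and book-keeping fields.  `U0` and `mean_U` both record the
#'   post-mutation, pre-selection ensemble mean (the threshold tracks it
#'   by construction); `mean_U_selected` is the mean after selection and
#'   resampling.
#' @examples
#' pr <- srb_params()
#' ev <- evolution_params(ensemble_size = 50, generations = 20,
#'                        mode = "homodimer", seed = 4)
#' res <- evolve_population(pr, ev, n_epitopes = 5)
#' tail(res$trajectory, 3)
#' @export
evolve_population <- function(params, evo, n_epitopes = 20, map = NULL) {
  stopifnot(inherits(params, "srb_params"),
            inherits(evo, "srb_evolution_params"))
  if (is.null(map)) map <- motif_map(params)
  homodimer <- evo$mode == "homodimer"
  seed_fP <- srb_stream_seed(evo$seed, "founder-P")
  seed_fB <- srb_stream_seed(evo$seed, "founder-B")
  seed_c <- srb_stream_seed(evo$seed, "coupling")
  seed_k <- srb_stream_seed(evo$seed, "kernel")
  founderP <- random_protein(params, n_epitopes, seed = seed_fP)
  founderB <- if (homodimer) matrix(integer(0), 0, 0)
              else random_protein(params, n_epitopes, seed = seed_fB)
  width <- evo$selection_width %||% params$sigma_J
  res <- with_seed(seed_k, cpp_evolve(
    unclass(founderP),
    if (homodimer) founderB else unclass(founderB),
    map$perm, params$alphabet_size, params$xi,
    evo$ensemble_size, evo$mutation_rate, evo$generations,
    seed_c, params$sigma_J, width, homodimer))
  g <- evo$generations
  trajectory <- data.frame(
    generation = seq_len(g),
    U0 = res$U0, mean_U = res$U0, min_U = res$min_U,
    survivors = res$survivors, mean_U_selected = res$mean_U_selected)
  structure(list(trajectory = trajectory,
                 final_U = res$final_U,
                 best_index = which.min(res$final_U),
                 final_residues = res$final,
                 founder_P = founderP,
                 founder_B = if (homodimer) NULL else founderB,
                 n_epitopes = as.integer(n_epitopes),
                 coupling_seed = seed_c,
                 params = params, evo = evo, map = map,
                 selection_width = width),
            class = "srb_evolution")
}

#' @export
print.srb_evolution <- function(x, ...) {
  g <- nrow(x$trajectory)
  cat(sprintf("SRB affinity evolution (%s): N = %d, %d generations\n",
              x$evo$mode, x$evo$ensemble_size, g))
  if (g > 0)
    cat(sprintf("  final <U> = %.4f, best U = %.4f\n",
                x$trajectory$mean_U[g], min(x$final_U)))
  invisible(x)
}

#' Extract one member of the final evolved population
#'
#' @param result an `srb_evolution` object.
#' @param index member index (defaults to the lowest-energy member).
#' @param role `"P"` or `"B"` (heterodimer mode only has both).
#' @return An `srb_protein`.
#' @export
population_protein <- function(result, index = result$best_index,
                               role = c("P", "B")) {
  stopifnot(inherits(result, "srb_evolution"))
  role <- match.arg(role)
  nP <- result$n_epitopes
  l <- result$params$peptide_length
  row <- result$final_residues[index, ]
  if (role == "B") {
    if (result$evo$mode == "homodimer")
      stop("homodimer populations contain a single protein")
    row <- row[(nP * l + 1):(2 * nP * l)]
  } else {
    row <- row[seq_len(nP * l)]
  }
  srb_protein(matrix(row, nrow = nP, byrow = TRUE), result$params)
}

#' Specificity assay of evolved complexes
#'
#' Compares the binding of evolved partners with the binding of evolved
#' proteins to fresh random proteins under the same couplings.  For each
#' supplied evolution result the lowest-energy final member provides the
#' evolved complex; each of its proteins is then put in complex with
#' `n_random_partners` fresh random proteins of the same surface size.
#'
#' @param results an `srb_evolution` or list of them (independent
#'   realizations).
#' @param n_random_partners random partners per evolved protein.
#' @param seed stream seed for the random partners.
#' @return A list with numeric vectors `evolved` (one energy per
#'   realization) and `random` (all evolved-vs-random energies).
#' @export
specificity_assay <- function(results, n_random_partners = 100, seed = 1) {
  if (inherits(results, "srb_evolution")) results <- list(results)
  evolved <- numeric(0)
  random <- numeric(0)
  for (k in seq_along(results)) {
    res <- results[[k]]
    stopifnot(inherits(res, "srb_evolution"))
    params <- res$params
    map <- res$map
    homodimer <- res$evo$mode == "homodimer"
    P <- population_protein(res, role = "P")
    MP <- protein_motifs(P, map)
    if (homodimer) {
      en <- cpp_pair_energies(MP, MP, res$coupling_seed, params$sigma_J)
      evolved <- c(evolved, min(en$parallel[upper.tri(en$parallel, TRUE)],
                                en$antiparallel[upper.tri(en$antiparallel, TRUE)]))
      mots <- list(MP)
    } else {
      B <- population_protein(res, role = "B")
      MB <- protein_motifs(B, map)
      en <- cpp_pair_energies(MP, MB, res$coupling_seed, params$sigma_J)
      evolved <- c(evolved, min(en$parallel, en$antiparallel))
      mots <- list(MP, MB)
    }
    for (m in seq_along(mots)) {
      for (j in seq_len(n_random_partners)) {
        sr <- srb_stream_seed(seed, sprintf("assay-partner-%d-%d", k, m), j)
        R <- random_protein(params, res$n_epitopes, seed = sr)
        enr <- cpp_pair_energies(mots[[m]], protein_motifs(R, map),
                                 res$coupling_seed, params$sigma_J)
        random <- c(random, min(enr$parallel, enr$antiparallel))
      }
    }
  }
  list(evolved = evolved, random = random)
}

#' Interface census of evolved homodimers
#'
#' Runs independent model realizations (fresh couplings and founder
#' protein each), evolves each homodimer ensemble for the requested
#' generations, classifies the minimal-energy interface of the
#' lowest-energy final member of each realization, and tallies the
#' interface categories.  With zero generations this reduces to the
#' random census of [random_homodimer_census()]; after sustained affinity
#' selection the antiparallel isologous interface dominates.
#'
#' @param params an [srb_params()] object.
#' @param evo an [evolution_params()] object with `mode = "homodimer"`.
#' @param n_realizations number of independent realizations.
#' @param n_epitopes epitopes per protein.
#' @param seed stream seed from which per-realization evolution seeds are
#'   derived.
#' @return An `srb_census` data frame (see [random_homodimer_census()])
#'   with an additional attribute `categories` holding the
#'   per-realization labels.
#' @export
evolved_homodimer_census <- function(params, evo, n_realizations = 50,
                                     n_epitopes = 20, seed = 1) {
  stopifnot(inherits(params, "srb_params"),
            inherits(evo, "srb_evolution_params"))
  if (evo$mode != "homodimer")
    stop("evolved_homodimer_census() requires homodimer mode")
  map <- motif_map(params)
  cats <- vapply(seq_len(n_realizations), function(r) {
    evo_r <- evo
    evo_r$seed <- srb_stream_seed(seed, "evolved-census", r)
    res <- evolve_population(params, evo_r, n_epitopes = n_epitopes, map = map)
    P <- population_protein(res, role = "P")
    en <- cpp_pair_energies(protein_motifs(P, map), protein_motifs(P, map),
                            res$coupling_seed, params$sigma_J)
    classify_min_energies(en$parallel, en$antiparallel)
  }, character(1))
  out <- srb_census(cats, n_realizations)
  attr(out, "categories") <- cats
  out
}
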