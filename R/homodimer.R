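#' Interface census of random homodimers
#'
#' Draws independent model realizations (fresh couplings and a fresh
#' random protein each), classifies the minimal-energy interface of each
#' homodimer, and tallies the three interface categories.  The
#' antiparallel isologous category is over-represented relative to its
#' share of states because its levels carry twice the energy variance.
#'
#' @param params an [srb_params()] object.
#' @param n_epitopes epitopes per protein.
#' @param n_realizations number of independent realizations.
#' @param seed stream seed; defaults to the master seed.
#' @return A data frame of class `srb_census` with columns `category`,
#'   `count`, `fraction` (rows in a fixed category order); attribute
#'   `n_realizations`.
#' @examples
#' random_homodimer_census(srb_params(), 20, n_realizations = 200, seed = 1)
#' @export
random_homodimer_census <- function(params, n_epitopes = 20, n_realizations = 10000,
                                    seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (n_realizations < 1) stop("n_realizations must be at least 1")
  if (is.null(seed)) seed <- params$master_seed
  map <- motif_map(params)
  cats <- vapply(seq_len(n_realizations), function(r) {
    sc <- srb_stream_seed(seed, "census-coupling", r)
    sp <- srb_stream_seed(seed, "census-protein", r)
    P <- random_protein(params, n_epitopes, seed = sp)
    en <- cpp_pair_energies(protein_motifs(P, map), protein_motifs(P, map),
                            sc, params$sigma_J)
    classify_min_energies(en$parallel, en$antiparallel)
  }, character(1))
  srb_census(cats, n_realizations)
}

census_categories <- c("antiparallel_isologous", "parallel_isologous",
                       "heterologous")

srb_census <- function(categories, n_realizations) {
  counts <- vapply(census_categories, function(k) sum(categories == k),
                   integer(1))
  structure(data.frame(category = census_categories,
                       count = unname(counts),
                       fraction = unname(counts) / n_realizations),
            class = c("srb_census", "data.frame"),
            n_realizations = n_realizations)
}

#' @export
print.srb_census <- function(x, ...) {
  cat(sprintf("Homodimer interface census over %d realizations\n",
              attr(x, "n_realizations")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %6d  (%.1f%%)\n", x$category[i], x$count[i],
                100 * x$fraction[i]))
  invisible(x)
}

#' Variance ratio of antiparallel vs parallel isologous self-binding
#'
#' Estimates \eqn{\mathrm{Var}[u_{\uparrow\downarrow}(p, p)] /
#' \mathrm{Var}[u_{\uparrow\uparrow}(p, p)]} over random peptides with
#' fresh couplings per draw.  In the antiparallel isologous geometry each
#' coupling is visited twice (motif `i` pairs with motif `l' - i + 1` and
#' vice versa), so for even `l_prime` the energy is twice a sum of
#' `l_prime / 2` couplings and the ratio tends to 2.  For odd `l_prime`
#' the middle motif pairs with itself once and the antiparallel variance
#' is \eqn{(2 l' - 1)\sigma_J^2}.
#'
#' @param params an [srb_params()] object.
#' @param n_peptides number of random peptides.
#' @param seed stream seed; defaults to the master seed.
#' @return A list with `var_parallel`, `var_antiparallel`, `ratio`,
#'   `n_peptides`.
#' @export
isologous_variance_ratio <- function(params, n_peptides = 1e5, seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (is.null(seed)) seed <- params$master_seed
  A <- params$alphabet_size; l <- params$peptide_length
  xi <- params$xi; lp <- params$l_prime
  n <- as.integer(n_peptides)
  res <- with_seed(srb_stream_seed(seed, "variance-peptides"),
                   matrix(sample.int(A, n * l, replace = TRUE) - 1L, nrow = n))
  # identity motif map: statistically equivalent to any bijection
  pw <- A^((xi - 1L):0L)
  mot <- matrix(0L, n, lp)
  for (i in seq_len(lp)) {
    idx <- integer(n)
    for (k in seq_len(xi)) idx <- idx + res[, i + k - 1L] * pw[k]
    mot[, i] <- idx
  }
  seeds <- srb_stream_seed(seed, "variance-couplings", seq_len(n))
  u_par <- numeric(n); u_anti <- numeric(n)
  for (i in seq_len(lp)) {
    u_par <- u_par + cpp_coupling(seeds, mot[, i], mot[, i], params$sigma_J)
    u_anti <- u_anti + cpp_coupling(seeds, mot[, lp - i + 1L], mot[, i],
                                    params$sigma_J)
  }
  list(var_parallel = var(u_par), var_antiparallel = var(u_anti),
       ratio = var(u_anti) / var(u_par), n_peptides = n)
}

#' Sample epitope-pair binding energies of random peptide pairs
#'
#' Draws `n_samples` independent (peptide, peptide, couplings)
#' realizations and returns the parallel binding energy of each pair:
#' the empirical counterpart of [level_pdf()].
#'
#' @param params an [srb_params()] object.
#' @param n_samples number of energies to draw.
#' @param seed stream seed; defaults to the master seed.
#' @return Numeric vector of `n_samples` energies.
#' @export
sample_level_energies <- function(params, n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (is.null(seed)) seed <- params$master_seed
  A <- params$alphabet_size; l <- params$peptide_length
  xi <- params$xi; lp <- params$l_prime
  n <- as.integer(n_samples)
  enc <- function(res) {
    pw <- A^((xi - 1L):0L)
    mot <- matrix(0L, n, lp)
    for (i in seq_len(lp)) {
      idx <- integer(n)
      for (k in seq_len(xi)) idx <- idx + res[, i + k - 1L] * pw[k]
      mot[, i] <- idx
    }
    mot
  }
  res_p <- with_seed(srb_stream_seed(seed, "level-peptide-p"),
                     matrix(sample.int(A, n * l, replace = TRUE) - 1L, nrow = n))
  res_b <- with_seed(srb_stream_seed(seed, "level-peptide-b"),
                     matrix(sample.int(A, n * l, replace = TRUE) - 1L, nrow = n))
  mp <- enc(res_p); mb <- enc(res_b)
  seeds <- srb_stream_seed(seed, "level-couplings", seq_len(n))
  u <- numeric(n)
  for (i in seq_len(lp))
    u <- u + cpp_coupling(seeds, mp[, i], mb[, i], params$sigma_J)
  u
}
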