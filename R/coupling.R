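#' Quenched random coupling table between structural motifs
#'
#' The motif-motif interaction matrix \eqn{J(m, m')} is a symmetric random
#' table whose entries over distinct unordered pairs are independent
#' Gaussian draws with mean 0 and variance \eqn{\sigma_J^2}; diagonal
#' entries follow the same law.  Entries are generated by a counter-based
#' deterministic hash of `(coupling_seed, min(m, m'), max(m, m'))`, so a
#' value can be produced lazily on demand without storing the table
#' (essential when \eqn{\|M\|} reaches tens of thousands, where a dense
#' table would need gigabytes).  The `"materialized"` mode tabulates the
#' same function into a dense matrix for fast repeated lookup; both modes
#' return identical values for identical inputs.
#'
#' @param params an [srb_params()] object.
#' @param coupling_seed integer seed of the coupling stream; defaults to
#'   the `"coupling"` stream of the master seed.
#' @param mode `"lazy"` (default) or `"materialized"`.
#' @return An object of class `srb_coupling_table`.
#' @examples
#' tab <- coupling_table(srb_params(), coupling_seed = 11)
#' coupling(tab, 0, 5) == coupling(tab, 5, 0)  # symmetric
#' @export
coupling_table <- function(params, coupling_seed = NULL,
                           mode = c("lazy", "materialized")) {
  stopifnot(inherits(params, "srb_params"))
  mode <- match.arg(mode)
  if (is.null(coupling_seed)) coupling_seed <- srb_stream_seed(params, "coupling")
  coupling_seed <- as.integer(coupling_seed)
  M <- params$n_motifs
  mat <- NULL
  if (mode == "materialized") {
    if (!is.integer(M) || M > 4096)
      stop("motif alphabet too large to materialize; use mode = \"lazy\"")
    mat <- cpp_coupling_matrix(M, coupling_seed, params$sigma_J)
  }
  structure(list(params = params, coupling_seed = coupling_seed,
                 mode = mode, matrix = mat),
            class = "srb_coupling_table")
}

#' @export
print.srb_coupling_table <- function(x, ...) {
  cat(sprintf("SRB coupling table: %s, ||M|| = %s, sigma_J = %g, seed = %d\n",
              x$mode, format(x$params$n_motifs), x$params$sigma_J,
              x$coupling_seed))
  invisible(x)
}

#' Motif-motif coupling energies
#'
#' Looks up \eqn{J(m, m')}; vectorized over motif codes (recycled to a
#' common length).
#'
#' @param table an [coupling_table()] object.
#' @param m,m_prime 0-based motif codes.
#' @return Numeric vector of coupling energies.
#' @export
coupling <- function(table, m, m_prime) {
  stopifnot(inherits(table, "srb_coupling_table"))
  M <- table$params$n_motifs
  m <- as.integer(m)
  m_prime <- as.integer(m_prime)
  if (any(is.na(m)) || any(is.na(m_prime)) ||
      any(m < 0L) || any(m >= M) || any(m_prime < 0L) || any(m_prime >= M))
    stop("motif code out of range")
  if (table$mode == "materialized") {
    n <- max(length(m), length(m_prime))
    i <- rep_len(m, n)
    j <- rep_len(m_prime, n)
    table$matrix[cbind(i + 1L, j + 1L)]
  } else {
    cpp_coupling(table$coupling_seed, m, m_prime, table$params$sigma_J)
  }
}
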