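#' Motif map: bijection from residue windows to structural motifs
#'
#' Builds the map \eqn{f} that assigns a structural motif to every
#' \eqn{\xi}-tuple of primary letters.  Tuples are indexed in base
#' \eqn{\|A\|} with the first residue as the most significant digit; the
#' map is a permutation of `0:(||M|| - 1)` over those tuple indices.  The
#' default is the identity permutation: because the couplings attached to
#' motifs are themselves exchangeable random variables, any bijection is
#' statistically equivalent, and the identity keeps encodings cheap.  A
#' seeded random permutation is available for explicit checks of that
#' equivalence.
#'
#' @param params an [srb_params()] object.
#' @param permutation `"identity"` (default) or `"random"`.
#' @param seed seed for the random permutation; defaults to the
#'   `"motif-map"` stream of the master seed.
#' @return An object of class `srb_motif_map` with fields `params`,
#'   `perm` (0-based motif code for tuple index + 1) and `inverse`.
#' @examples
#' m <- motif_map(srb_params(alphabet_size = 4, xi = 3))
#' length(m$perm)  # 64 motifs
#' @export
motif_map <- function(params, permutation = c("identity", "random"), seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  permutation <- match.arg(permutation)
  M <- params$n_motifs
  if (!is.integer(M) || M > 2^26)
    stop("motif alphabet too large to enumerate explicitly")
  perm <- if (permutation == "identity") {
    seq_len(M) - 1L
  } else {
    if (is.null(seed)) seed <- srb_stream_seed(params, "motif-map")
    with_seed(seed, sample.int(M)) - 1L
  }
  inverse <- integer(M)
  inverse[perm + 1L] <- seq_len(M) - 1L
  structure(list(params = params, perm = perm, inverse = inverse,
                 permutation = permutation),
            class = "srb_motif_map")
}

#' @export
print.srb_motif_map <- function(x, ...) {
  cat(sprintf("SRB motif map: %s permutation over %d motifs (xi = %d)\n",
              x$permutation, length(x$perm), x$params$xi))
  invisible(x)
}

# base-||A|| tuple index (0-based), first residue most significant
tuple_to_index <- function(tuple, alphabet_size) {
  idx <- 0L
  for (k in seq_along(tuple)) idx <- idx * alphabet_size + as.integer(tuple[k])
  idx
}

index_to_tuple <- function(index, alphabet_size, xi) {
  out <- integer(xi)
  index <- as.integer(index)
  for (k in rev(seq_len(xi))) {
    out[k] <- index %% alphabet_size
    index <- index %/% alphabet_size
  }
  out
}

#' Motif of a single residue window
#'
#' @param map an `srb_motif_map`.
#' @param tuple integer vector of `xi` letters in `0:(alphabet_size - 1)`.
#' @return The 0-based motif code.
#' @export
motif_of_tuple <- function(map, tuple) {
  p <- map$params
  tuple <- as.integer(tuple)
  if (length(tuple) != p$xi) stop("tuple must have length xi")
  if (any(tuple < 0L | tuple >= p$alphabet_size)) stop("letter out of range")
  map$perm[tuple_to_index(tuple, p$alphabet_size) + 1L]
}

#' Residue window of a motif (inverse of the motif map)
#'
#' @param map an `srb_motif_map`.
#' @param motif a 0-based motif code.
#' @return Integer vector of `xi` letters.
#' @export
tuple_of_motif <- function(map, motif) {
  p <- map$params
  motif <- as.integer(motif)
  if (length(motif) != 1 || motif < 0L || motif >= length(map$perm))
    stop("motif code out of range")
  index_to_tuple(map$inverse[motif + 1L], p$alphabet_size, p$xi)
}

#' Secondary structure of a peptide
#'
#' Applies the motif map to every sliding `xi`-window of the primary
#' sequence, returning the motif sequence of length
#' \eqn{l' = l - \xi + 1}.
#'
#' @param peptide integer vector of `peptide_length` letters in
#'   `0:(alphabet_size - 1)`.
#' @param map an `srb_motif_map`.
#' @return Integer vector of `l_prime` 0-based motif codes.
#' @examples
#' p <- srb_params(alphabet_size = 2, peptide_length = 4, xi = 2)
#' encode_secondary(c(0, 1, 1, 0), motif_map(p))
#' @export
encode_secondary <- function(peptide, map) {
  stopifnot(inherits(map, "srb_motif_map"))
  p <- map$params
  pep <- as.integer(peptide)
  if (length(pep) != p$peptide_length)
    stop("peptide length does not match the model's peptide_length")
  if (any(is.na(pep)) || any(pep < 0L | pep >= p$alphabet_size))
    stop("peptide letters must lie in 0:(alphabet_size - 1)")
  lp <- p$l_prime
  pw <- as.integer(p$alphabet_size)^((p$xi - 1L):0L)
  idx <- integer(lp)
  for (k in seq_len(p$xi)) idx <- idx + pep[k:(k + lp - 1L)] * pw[k]
  map$perm[idx + 1L]
}

# motif matrix of a protein: rows = epitopes, columns = window positions
protein_motifs <- function(protein, map) {
  p <- map$params
  res <- unclass(protein)
  if (ncol(res) != p$peptide_length) stop("epitope length mismatch")
  lp <- p$l_prime
  pw <- as.integer(p$alphabet_size)^((p$xi - 1L):0L)
  out <- matrix(0L, nrow(res), lp)
  for (i in seq_len(lp)) {
    idx <- integer(nrow(res))
    for (k in seq_len(p$xi)) idx <- idx + res[, i + k - 1L] * pw[k]
    out[, i] <- map$perm[idx + 1L]
  }
  out
}

#' Invert a motif sequence back to a primary sequence, if possible
#'
#' A motif sequence is invertible when the residue windows implied by
#' consecutive motifs agree on their \eqn{\xi - 1} overlapping letters.
#' Invertible sequences form a fraction
#' \eqn{\|A\|^{\,l - l'\xi}} of all motif sequences (see
#' [invertible_fraction()]), which is why affinity optimisation over motif
#' space is a constrained problem for intermediate `xi`.
#'
#' @param motifs integer vector of `l_prime` motif codes.
#' @param map an `srb_motif_map`.
#' @return The primary sequence (integer vector of length
#'   `peptide_length`), or `NULL` when the motif sequence has no preimage.
#' @export
invert_secondary <- function(motifs, map) {
  p <- map$params
  motifs <- as.integer(motifs)
  if (length(motifs) != p$l_prime) stop("motif sequence must have length l_prime")
  tuples <- lapply(motifs, function(m) tuple_of_motif(map, m))
  if (p$xi > 1L) {
    for (i in seq_len(length(tuples) - 1L)) {
      if (!identical(tuples[[i]][-1L], tuples[[i + 1L]][-p$xi])) return(NULL)
    }
  }
  out <- tuples[[1L]]
  if (length(tuples) > 1L)
    out <- c(out, vapply(tuples[-1L], function(t) t[p$xi], integer(1)))
  out
}
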