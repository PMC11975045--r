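#' Construct a protein from a residue matrix
#'
#' An SRB protein is a collection of peptide epitopes of common length
#' `peptide_length`, stored as an integer matrix with one epitope per row
#' and 0-based letters.
#'
#' @param residues integer matrix (epitopes x residues) with entries in
#'   `0:(alphabet_size - 1)`.
#' @param params an [srb_params()] object.
#' @return An object of class `srb_protein` (an integer matrix).
#' @export
srb_protein <- function(residues, params) {
  stopifnot(inherits(params, "srb_params"))
  res <- as.matrix(residues)
  storage.mode(res) <- "integer"
  if (nrow(res) < 1) stop("a protein needs at least one epitope")
  if (ncol(res) != params$peptide_length)
    stop("epitope length does not match peptide_length")
  if (any(is.na(res)) || any(res < 0L) || any(res >= params$alphabet_size))
    stop("residue letters must lie in 0:(alphabet_size - 1)")
  structure(res, class = "srb_protein", alphabet_size = params$alphabet_size)
}

#' @export
print.srb_protein <- function(x, ...) {
  cat(sprintf("SRB protein: %d epitopes of length %d (||A|| = %d)\n",
              nrow(x), ncol(x), attr(x, "alphabet_size")))
  invisible(x)
}

#' Number of epitopes of a protein
#' @param protein an `srb_protein`.
#' @return Integer epitope count.
#' @export
n_epitopes <- function(protein) nrow(protein)

#' Draw a random protein
#'
#' Epitopes are filled with independent uniform letters from the primary
#' alphabet, reproducibly from the given stream seed.
#'
#' @param params an [srb_params()] object.
#' @param n_epitopes number of epitopes (surface size), at least 1.
#' @param seed stream seed; defaults to the `"protein"` stream of the
#'   master seed.
#' @return An `srb_protein`.
#' @examples
#' P <- random_protein(srb_params(), n_epitopes = 20, seed = 3)
#' dim(P)  # 20 x 10
#' @export
random_protein <- function(params, n_epitopes, seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  n_epitopes <- as.integer(n_epitopes)
  if (is.na(n_epitopes) || n_epitopes < 1)
    stop("n_epitopes must be a positive integer")
  if (is.null(seed)) seed <- srb_stream_seed(params, "protein")
  res <- with_seed(seed, matrix(
    sample.int(params$alphabet_size, n_epitopes * params$peptide_length,
               replace = TRUE) - 1L,
    nrow = n_epitopes))
  srb_protein(res, params)
}

#' Draw a random peptide
#'
#' @param params an [srb_params()] object.
#' @param seed stream seed; defaults to the `"peptide"` stream.
#' @return Integer vector of `peptide_length` letters.
#' @export
random_peptide <- function(params, seed = NULL) {
  stopifnot(inherits(params, "srb_params"))
  if (is.null(seed)) seed <- srb_stream_seed(params, "peptide")
  with_seed(seed, sample.int(params$alphabet_size, params$peptide_length,
                             replace = TRUE) - 1L)
}

# letters used for FASTA text: ACGT for a 4-letter alphabet, otherwise
# consecutive uppercase letters
srb_letters <- function(alphabet_size) {
  if (alphabet_size == 4L) c("A", "C", "G", "T")
  else if (alphabet_size <= 26L) LETTERS[seq_len(alphabet_size)]
  else stop("FASTA export supports alphabets up to 26 letters")
}

#' Export proteins as FASTA
#'
#' Writes one record per epitope with headers
#' `protein_<id>_epitope_<k>`.  Letters 0-3 map to `A`, `C`, `G`, `T` for
#' a 4-letter alphabet and to consecutive uppercase letters otherwise.
#'
#' @param proteins an `srb_protein` or a (optionally named) list of them.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(proteins, file) {
  if (inherits(proteins, "srb_protein")) proteins <- list(proteins)
  if (is.null(names(proteins)) || any(names(proteins) == ""))
    names(proteins) <- seq_along(proteins)
  seqs <- character(0)
  for (id in names(proteins)) {
    P <- proteins[[id]]
    lets <- srb_letters(attr(P, "alphabet_size"))
    s <- apply(unclass(P) + 1L, 1L, function(r) paste(lets[r], collapse = ""))
    names(s) <- sprintf("protein_%s_epitope_%d", id, seq_len(nrow(P)))
    seqs <- c(seqs, s)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' Import proteins from FASTA
#'
#' Reads records written by [write_protein_fasta()], grouping epitopes by
#' the protein id embedded in the headers.
#'
#' @param file path to a FASTA file.
#' @param params an [srb_params()] object giving the alphabet and epitope
#'   length.
#' @return A named list of `srb_protein` objects.
#' @export
read_protein_fasta <- function(file, params) {
  stopifnot(inherits(params, "srb_params"))
  ss <- Biostrings::readBStringSet(file)
  lets <- srb_letters(params$alphabet_size)
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^protein_(.+)_epitope_([0-9]+)$", hdr))
  if (any(lengths(m) != 3)) stop("unrecognized FASTA header format")
  ids <- vapply(m, `[`, character(1), 2L)
  out <- list()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    res <- t(vapply(rows, function(i) {
      chars <- strsplit(as.character(ss[[i]]), "")[[1]]
      codes <- match(chars, lets) - 1L
      if (any(is.na(codes))) stop("letter outside the model alphabet")
      codes
    }, integer(params$peptide_length)))
    out[[id]] <- srb_protein(res, params)
  }
  out
}
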