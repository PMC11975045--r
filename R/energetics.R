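#' Oriented binding energy between two peptides
#'
#' The binding energy of an aligned peptide pair is the sum of the
#' couplings of their paired motifs: in parallel orientation
#' \eqn{u_{\uparrow\uparrow}(p, b) = \sum_{i=1}^{l'} J[f(p)_i, f(b)_i]},
#' and in antiparallel orientation the motif sequence of `p` is reversed,
#' \eqn{u_{\uparrow\downarrow}(p, b) = \sum_{i=1}^{l'}
#' J[f(p)_{l'-i+1}, f(b)_i]}.  Epitopes interact full-length and in
#' register; there are no shifted alignments.
#'
#' @param p,b integer peptides of length `peptide_length`.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param map an [motif_map()] object.
#' @param table an [coupling_table()] object.
#' @return The binding energy (scalar).
#' @examples
#' pr <- srb_params(master_seed = 5)
#' mp <- motif_map(pr); tb <- coupling_table(pr)
#' binding_energy(random_peptide(pr, seed = 1), random_peptide(pr, seed = 2),
#'                "antiparallel", mp, tb)
#' @export
binding_energy <- function(p, b, orientation = c("parallel", "antiparallel"),
                           map, table) {
  orientation <- match.arg(orientation)
  mp <- encode_secondary(p, map)
  mb <- encode_secondary(b, map)
  if (orientation == "antiparallel") mp <- rev(mp)
  sum(coupling(table, mp, mb))
}

orientation_levels <- c("parallel", "antiparallel")

new_spectrum <- function(df, type, params, coupling_seed) {
  # canonical level order: epitope_i, epitope_j, then orientation
  # alphabetically (antiparallel first) -- this is the tie-break order
  ord <- order(df$epitope_i, df$epitope_j, df$orientation)
  df <- df[ord, , drop = FALSE]
  df$level_index <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("level_index", "energy", "epitope_i", "epitope_j",
               "orientation", "category")]
  structure(df, class = c("srb_spectrum", "data.frame"), type = type,
            n_levels = nrow(df), params = params, coupling_seed = coupling_seed)
}

#' Full energy spectrum of a heterodimeric complex
#'
#' Enumerates all `n = 2 * nP * nB` configurations of the binary complex:
#' every epitope pair in both orientations, each tagged with its interface
#' configuration.  The level energies are iid draws from the peptide-pair
#' energy law, which is what makes the complex an `n`-level random energy
#' system.
#'
#' @param P,B `srb_protein` objects.
#' @param map an [motif_map()] object.
#' @param table an [coupling_table()] object.
#' @return An `srb_spectrum`: a data frame with columns `level_index`,
#'   `energy`, `epitope_i`, `epitope_j` (1-based epitope indices),
#'   `orientation` and `category`, ordered canonically.
#' @examples
#' pr <- srb_params(master_seed = 2)
#' sp <- complex_spectrum(random_protein(pr, 20, seed = 1),
#'                        random_protein(pr, 20, seed = 2),
#'                        motif_map(pr), coupling_table(pr))
#' attr(sp, "n_levels")  # 800
#' @export
complex_spectrum <- function(P, B, map, table) {
  stopifnot(inherits(P, "srb_protein"), inherits(B, "srb_protein"))
  en <- cpp_pair_energies(protein_motifs(P, map), protein_motifs(B, map),
                          table$coupling_seed, table$params$sigma_J)
  nP <- nrow(P); nB <- nrow(B)
  grid_i <- rep(seq_len(nP), times = nB)
  grid_j <- rep(seq_len(nB), each = nP)
  df <- data.frame(
    energy = c(as.vector(en$parallel), as.vector(en$antiparallel)),
    epitope_i = c(grid_i, grid_i),
    epitope_j = c(grid_j, grid_j),
    orientation = rep(orientation_levels, each = nP * nB),
    category = "heterodimer",
    stringsAsFactors = FALSE)
  new_spectrum(df, "heterodimer", table$params, table$coupling_seed)
}

#' Full energy spectrum of a homodimeric complex
#'
#' For a homodimer the state space counts each unordered distinct epitope
#' pair once per orientation (exchange symmetry of the couplings makes the
#' two orderings identical in energy), plus two isologous states per
#' epitope (an epitope facing its own copy, parallel or antiparallel).
#' For `nP` epitopes this gives `nP * (nP - 1) + 2 * nP` levels, e.g. 420
#' at `nP = 20`.  Antiparallel isologous states pair motif `i` with motif
#' `l' - i + 1`, so for even `l'` their energy is twice a sum of `l'/2`
#' couplings and carries twice the variance of the other categories — the
#' origin of the interface bias in random homodimers.
#'
#' @param P an `srb_protein`.
#' @param map an [motif_map()] object.
#' @param table an [coupling_table()] object.
#' @return An `srb_spectrum` with categories `antiparallel_isologous`,
#'   `parallel_isologous` and `heterologous`.
#' @export
homodimer_spectrum <- function(P, map, table) {
  stopifnot(inherits(P, "srb_protein"))
  MP <- protein_motifs(P, map)
  en <- cpp_pair_energies(MP, MP, table$coupling_seed, table$params$sigma_J)
  nP <- nrow(P)
  pairs <- which(upper.tri(en$parallel, diag = TRUE), arr.ind = TRUE)
  a <- pairs[, 1L]; b <- pairs[, 2L]
  iso <- a == b
  cat_par <- ifelse(iso, "parallel_isologous", "heterologous")
  cat_anti <- ifelse(iso, "antiparallel_isologous", "heterologous")
  df <- data.frame(
    energy = c(en$parallel[pairs], en$antiparallel[pairs]),
    epitope_i = c(a, a),
    epitope_j = c(b, b),
    orientation = rep(orientation_levels, each = length(a)),
    category = c(cat_par, cat_anti),
    stringsAsFactors = FALSE)
  new_spectrum(df, "homodimer", table$params, table$coupling_seed)
}

#' @export
print.srb_spectrum <- function(x, ...) {
  cat(sprintf("SRB %s spectrum: %d levels, ground state %.4f\n",
              attr(x, "type"), attr(x, "n_levels"), min(x$energy)))
  invisible(x)
}

#' Complex binding energy: the spectrum minimum and its configuration
#'
#' The low-temperature binding energy of the complex is the minimum level
#' energy over all interface configurations.  Exact ties (measure zero for
#' continuous couplings) are broken lexicographically on
#' `(epitope_i, epitope_j, orientation)`, so results are reproducible.
#'
#' @param spectrum an `srb_spectrum`.
#' @return A list with elements `U` (the minimum energy) and `config` (a
#'   one-row data frame with `epitope_i`, `epitope_j`, `orientation`,
#'   `category`).
#' @export
complex_binding_energy <- function(spectrum) {
  if (!inherits(spectrum, "srb_spectrum") || nrow(spectrum) == 0)
    stop("non-empty srb_spectrum required")
  k <- which.min(spectrum$energy)  # rows are already in tie-break order
  list(U = spectrum$energy[k],
       config = spectrum[k, c("epitope_i", "epitope_j", "orientation",
                              "category"), drop = FALSE])
}

#' Interface category of a homodimer's minimal-energy configuration
#'
#' @param spectrum a homodimer `srb_spectrum`.
#' @return One of `"antiparallel_isologous"`, `"parallel_isologous"`,
#'   `"heterologous"`.
#' @export
classify_interface <- function(spectrum) {
  if (!inherits(spectrum, "srb_spectrum") ||
      !identical(attr(spectrum, "type"), "homodimer"))
    stop("classify_interface() requires a homodimer spectrum")
  complex_binding_energy(spectrum)$config$category
}

# fast path used by the census loops: classify the argmin directly from the
# oriented energy matrices, without building a data frame
classify_min_energies <- function(par, anti) {
  ut <- upper.tri(par, diag = TRUE)
  pv <- par[ut]; av <- anti[ut]
  if (min(av) <= min(pv)) {
    idx <- which(ut, arr.ind = TRUE)[which.min(av), ]
    if (idx[1L] == idx[2L]) "antiparallel_isologous" else "heterologous"
  } else {
    idx <- which(ut, arr.ind = TRUE)[which.min(pv), ]
    if (idx[1L] == idx[2L]) "parallel_isologous" else "heterologous"
  }
}

#' Write a spectrum to a tab-separated file
#'
#' @param spectrum an `srb_spectrum`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "srb_spectrum"))
  write.table(as.data.frame(spectrum), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
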