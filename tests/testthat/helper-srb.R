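# shared fixtures: everything is generated in code, no stored data

default_params <- function(...) {
  args <- list(...)
  defaults <- list(alphabet_size = 4, peptide_length = 10, xi = 3,
                   sigma_J = 1, master_seed = 1)
  do.call(srb_params, utils::modifyList(defaults, args))
}

# amino-acid-sized alphabet: the generic setting for level statistics
aa_params <- function(...) default_params(alphabet_size = 20, ...)

# Kolmogorov-Smirnov sup distance between a sample and a reference CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(seq_len(n) / n - Fx))
}

# build an srb_spectrum by hand (for tie-break and argmin contracts)
fake_spectrum <- function(energy, epitope_i, epitope_j, orientation, category,
                          type = "homodimer") {
  df <- data.frame(level_index = seq_along(energy), energy = energy,
                   epitope_i = epitope_i, epitope_j = epitope_j,
                   orientation = orientation, category = category,
                   stringsAsFactors = FALSE)
  ord <- order(df$epitope_i, df$epitope_j, df$orientation)
  df <- df[ord, ]
  df$level_index <- seq_len(nrow(df))
  structure(df, class = c("srb_spectrum", "data.frame"), type = type,
            n_levels = nrow(df))
}
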