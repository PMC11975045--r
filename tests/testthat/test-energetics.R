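test_that("xi = l gives a single-coupling binding energy", {
  p <- srb_params(alphabet_size = 4, peptide_length = 5, xi = 5, master_seed = 2)
  m <- motif_map(p)
  tab <- coupling_table(p, coupling_seed = 7)
  a <- random_peptide(p, seed = 1); b <- random_peptide(p, seed = 2)
  for (o in c("parallel", "antiparallel")) {
    expect_equal(binding_energy(a, b, o, m, tab),
                 coupling(tab, encode_secondary(a, m), encode_secondary(b, m)))
  }
})

test_that("binding energy is exchange-symmetric in both orientations", {
  p <- default_params(master_seed = 5)
  m <- motif_map(p)
  tab <- coupling_table(p, coupling_seed = 3)
  for (r in 1:100) {
    a <- random_peptide(p, seed = srb_stream_seed(1, "exch-a", r))
    b <- random_peptide(p, seed = srb_stream_seed(1, "exch-b", r))
    # term-by-term oracle for the parallel case
    ma <- encode_secondary(a, m); mb <- encode_secondary(b, m)
    expect_equal(binding_energy(a, b, "parallel", m, tab),
                 sum(vapply(1:8, function(i) coupling(tab, ma[i], mb[i]),
                            numeric(1))))
    expect_equal(binding_energy(a, b, "parallel", m, tab),
                 binding_energy(b, a, "parallel", m, tab))
    expect_equal(binding_energy(a, b, "antiparallel", m, tab),
                 binding_energy(b, a, "antiparallel", m, tab))
  }
})

test_that("two-term binding energies match explicit table lookups", {
  # l' = 2: parallel J[m1,m1'] + J[m2,m2'], antiparallel J[m2,m1'] + J[m1,m2']
  p <- srb_params(alphabet_size = 4, peptide_length = 4, xi = 3, master_seed = 8)
  m <- motif_map(p)
  tab <- coupling_table(p, coupling_seed = 19, mode = "materialized")
  J <- tab$matrix
  for (r in 1:20) {
    a <- random_peptide(p, seed = srb_stream_seed(2, "h2-a", r))
    b <- random_peptide(p, seed = srb_stream_seed(2, "h2-b", r))
    ma <- encode_secondary(a, m) + 1L
    mb <- encode_secondary(b, m) + 1L
    expect_equal(binding_energy(a, b, "parallel", m, tab),
                 J[ma[1], mb[1]] + J[ma[2], mb[2]])
    expect_equal(binding_energy(a, b, "antiparallel", m, tab),
                 J[ma[2], mb[1]] + J[ma[1], mb[2]])
  }
})

test_that("spectrum level counts follow the state-space conventions", {
  p <- default_params(master_seed = 4)
  m <- motif_map(p); tab <- coupling_table(p)
  s1 <- complex_spectrum(random_protein(p, 1, seed = 1),
                         random_protein(p, 1, seed = 2), m, tab)
  expect_equal(attr(s1, "n_levels"), 2L)
  s <- complex_spectrum(random_protein(p, 20, seed = 3),
                        random_protein(p, 20, seed = 4), m, tab)
  expect_equal(attr(s, "n_levels"), 800L)
  expect_true(all(s$category == "heterodimer"))

  h1 <- homodimer_spectrum(random_protein(p, 1, seed = 5), m, tab)
  expect_equal(attr(h1, "n_levels"), 2L)
  expect_setequal(h1$category, c("parallel_isologous", "antiparallel_isologous"))
  h <- homodimer_spectrum(random_protein(p, 20, seed = 6), m, tab)
  expect_equal(attr(h, "n_levels"), 420L)
  expect_equal(sum(h$category == "antiparallel_isologous"), 20L)
  expect_equal(sum(h$category == "parallel_isologous"), 20L)
  expect_equal(sum(h$category == "heterologous"), 380L)
})

test_that("spectrum energies match per-pair recomputation", {
  p <- default_params(master_seed = 12)
  m <- motif_map(p); tab <- coupling_table(p, coupling_seed = 31)
  P <- random_protein(p, 3, seed = 1)
  B <- random_protein(p, 3, seed = 2)
  s <- complex_spectrum(P, B, m, tab)
  for (k in seq_len(nrow(s))) {
    expect_equal(s$energy[k],
                 binding_energy(unclass(P)[s$epitope_i[k], ],
                                unclass(B)[s$epitope_j[k], ],
                                s$orientation[k], m, tab))
  }
  h <- homodimer_spectrum(P, m, tab)
  for (k in seq_len(nrow(h))) {
    expect_equal(h$energy[k],
                 binding_energy(unclass(P)[h$epitope_i[k], ],
                                unclass(P)[h$epitope_j[k], ],
                                h$orientation[k], m, tab))
  }
})

test_that("complex binding energy is the sorted minimum with lexicographic ties", {
  p <- default_params(master_seed = 21)
  m <- motif_map(p); tab <- coupling_table(p)
  s <- complex_spectrum(random_protein(p, 4, seed = 1),
                        random_protein(p, 5, seed = 2), m, tab)
  res <- complex_binding_energy(s)
  expect_equal(res$U, sort(s$energy)[1])  # sort oracle
  k <- which(s$energy == res$U)
  expect_equal(s$category[k], res$config$category)

  one <- fake_spectrum(-1.5, 1, 1, "parallel", "parallel_isologous")
  expect_equal(complex_binding_energy(one)$U, -1.5)

  # exact tie: lexicographically first configuration wins
  tie <- fake_spectrum(energy = c(-2, -2, 0),
                       epitope_i = c(2, 1, 1), epitope_j = c(2, 3, 1),
                       orientation = c("parallel", "antiparallel", "parallel"),
                       category = c("parallel_isologous", "heterologous",
                                    "parallel_isologous"))
  res <- complex_binding_energy(tie)
  expect_equal(res$config$epitope_i, 1)
  expect_equal(res$config$epitope_j, 3)
  expect_equal(res$config$orientation, "antiparallel")
  expect_error(complex_binding_energy(tie[0, ]), "non-empty")
})

test_that("interface classification follows the argmin and rejects heterodimers", {
  p <- default_params(master_seed = 33)
  m <- motif_map(p); tab <- coupling_table(p)
  expect_error(classify_interface(
    complex_spectrum(random_protein(p, 2, seed = 1),
                     random_protein(p, 2, seed = 2), m, tab)), "homodimer")
  aniso <- fake_spectrum(energy = c(-3, 1), epitope_i = c(2, 1),
                         epitope_j = c(2, 2),
                         orientation = c("antiparallel", "parallel"),
                         category = c("antiparallel_isologous", "heterologous"))
  expect_equal(classify_interface(aniso), "antiparallel_isologous")
  het <- fake_spectrum(energy = c(-3, 1), epitope_i = c(1, 1),
                       epitope_j = c(2, 1),
                       orientation = c("parallel", "parallel"),
                       category = c("heterologous", "parallel_isologous"))
  expect_equal(classify_interface(het), "heterologous")

  # fast census path agrees with the spectrum-based classification
  for (r in 1:50) {
    sc <- srb_stream_seed(3, "cls-c", r)
    P <- random_protein(p, 8, seed = srb_stream_seed(3, "cls-p", r))
    tab_r <- coupling_table(p, coupling_seed = sc)
    en <- srb:::cpp_pair_energies(srb:::protein_motifs(P, m),
                                  srb:::protein_motifs(P, m), sc, p$sigma_J)
    expect_equal(srb:::classify_min_energies(en$parallel, en$antiparallel),
                 classify_interface(homodimer_spectrum(P, m, tab_r)))
  }
})

test_that("antiparallel self-binding doubles half the terms for even l'", {
  p <- default_params(master_seed = 44)  # l' = 8
  m <- motif_map(p); tab <- coupling_table(p, coupling_seed = 13)
  for (r in 1:25) {
    a <- random_peptide(p, seed = srb_stream_seed(4, "anti", r))
    ma <- encode_secondary(a, m)
    u <- binding_energy(a, a, "antiparallel", m, tab)
    half <- sum(vapply(1:4, function(i) coupling(tab, ma[8 - i + 1], ma[i]),
                       numeric(1)))
    expect_equal(u, 2 * half)
  }
})

test_that("isologous variances: ratio 2 for even l', (2l'-1) sigma^2 for odd l'", {
  # generic (amino-acid sized) alphabet, where window collisions are rare
  vr <- isologous_variance_ratio(aa_params(), n_peptides = 4e4, seed = 6)
  expect_lt(abs(vr$ratio - 2), 0.1)
  expect_lt(abs(vr$var_parallel - 8), 0.4)

  p_odd <- aa_params(peptide_length = 9)  # l' = 7
  vo <- isologous_variance_ratio(p_odd, n_peptides = 4e4, seed = 7)
  expect_lt(abs(vo$var_antiparallel - (2 * 7 - 1)), 0.6)
  expect_lt(abs(vo$var_parallel - 7), 0.4)

  # small-alphabet artifact: at ||A|| = 4 repeated windows double-count
  # diagonal couplings, inflating the parallel variance; the expected
  # inflation is 2 * C(8,2) / 64 = 0.875 (collision probability 1/64 per
  # window pair), pulling the ratio to ~1.83
  v4 <- isologous_variance_ratio(default_params(), n_peptides = 4e4, seed = 9)
  expect_lt(abs(v4$var_parallel - 8.875), 0.3)
  expect_lt(abs(v4$ratio - 1.83), 0.08)
})

test_that("pair energies are Gaussian with variance l' sigma^2", {
  u <- sample_level_energies(aa_params(), n_samples = 1e5, seed = 8)
  D <- ks_distance(u, function(x) pnorm(x, 0, sqrt(8)))
  expect_lt(D, 0.01)
})

test_that("spectrum TSV export has the documented columns", {
  p <- default_params()
  s <- homodimer_spectrum(random_protein(p, 3, seed = 1), motif_map(p),
                          coupling_table(p))
  f <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(s, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(back), c("level_index", "energy", "epitope_i",
                              "epitope_j", "orientation", "category"))
  expect_equal(nrow(back), 12L)
  expect_equal(back$energy, s$energy)
})
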