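poly_a <- "AAAAAAAAAACAAAAAAAAAA"
pad_only <- "XXXXXXXXXXCXXXXXXXXXX"

test_that("AAC counts residues over the window length and ignores X", {
  v <- encode_aac(poly_a)[1, ]
  expect_equal(unname(v["AAC.A"]), 20 / 21)
  expect_equal(unname(v["AAC.C"]), 1 / 21)
  expect_equal(sum(v), 1)

  v2 <- encode_aac(pad_only)[1, ]
  expect_equal(unname(v2["AAC.C"]), 1 / 21)
  expect_equal(sum(v2), 1 / 21)

  withr::with_seed(3, {
    for (nx in c(0, 4, 9)) {
      m <- random_motif(nx)
      expect_equal(sum(encode_aac(m)), (21 - nx) / 21)
    }
  })
})

test_that("CKSAAP matches the exhaustive pair-enumeration oracle", {
  k0 <- encode_cksaap(poly_a)[1, ]
  expect_equal(unname(k0["CKSAAP.k0.AA"]), 18 / 20)
  expect_equal(unname(k0["CKSAAP.k0.AC"]), 1 / 20)
  expect_equal(unname(k0["CKSAAP.k0.CA"]), 1 / 20)
  expect_equal(length(k0), 2400)

  expect_true(all(encode_cksaap(pad_only) == 0))

  withr::with_seed(11, {
    for (nx in c(0, 3, 12)) {
      m <- random_motif(nx)
      enc <- encode_cksaap(m)[1, ]
      expect_equal(enc, cksaap_oracle(m), tolerance = 1e-12)
    }
  })
})

test_that("CKSAAP values lie in [0,1] and X-free k-blocks sum to one", {
  withr::with_seed(5, {
    m <- random_motif(0)
    enc <- encode_cksaap(m)[1, ]
    expect_true(all(enc >= 0 & enc <= 1))
    for (k in 0:5)
      expect_equal(sum(enc[grepl(paste0("\\.k", k, "\\."), names(enc))]), 1)
  })
  expect_error(encode_cksaap(poly_a, k_max = 20), "too large")
})

test_that("binary encoding is one-hot over the 21-letter alphabet", {
  b <- encode_binary(pad_only)[1, ]
  expect_equal(length(b), 441)
  # central C: second slot of the 11th sub-vector
  centre <- b[(10 * 21 + 1):(11 * 21)]
  expect_equal(unname(centre),
               c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  # X: last slot of its sub-vector
  expect_equal(unname(b["BINARY.p01.X"]), 1)
  withr::with_seed(2, {
    m <- encode_binary(random_motif(3))[1, ]
    expect_equal(sum(m), 21)
    expect_true(all(m %in% c(0, 1)))
  })
})

test_that("BLOSUM62 rows come from the embedded matrix", {
  B <- blosum62_table()
  expect_equal(unname(B["C", "C"]), 9)
  enc <- encode_blosum62(poly_a)[1, ]
  expect_equal(length(enc), 441)
  expect_equal(unname(enc["BLOSUM62.p11.C"]), 9)
  expect_equal(unname(enc["BLOSUM62.p01.A"]), unname(B["A", "A"]))
})

test_that("position-local encoders only change columns of the edited position", {
  m1 <- "LKEDLKEDLKCLKEDLKEDLK"
  m2 <- sub("^L", "W", m1) # change position 1 only
  for (enc in list(encode_binary, encode_blosum62,
                   function(x) encode_aaindex(x))) {
    d <- enc(c(m1, m2))
    differing <- which(d[1, ] != d[2, ])
    expect_true(all(grepl("\\.p01\\.", colnames(d)[differing])))
    expect_gt(length(differing), 0)
  }
})

test_that("AAindex encoding has 1344 dimensions and X maps to the index mean", {
  tab <- aaindex_table()
  expect_equal(dim(tab), c(64, 21))
  expect_equal(tab[, "X"], rowMeans(tab[, 1:20]))
  enc <- encode_aaindex(c(poly_a, pad_only))
  expect_equal(ncol(enc), 1344)
  id1 <- rownames(tab)[1]
  expect_equal(unname(enc[2, paste0("AAindex.p01.", id1)]),
               unname(tab[id1, "X"]))
  expect_equal(unname(enc[1, paste0("AAindex.p01.", id1)]),
               unname(tab[id1, "A"]))
})

test_that("PSSM encoding honours width/terminal options and zero-pads", {
  d <- generate_dataset(synth_config(n_pos = 10, n_neg = 10, seed = 4))
  expect_equal(ncol(encode_pssm(d$dataset, d$store, encoder_config())), 441)
  expect_equal(ncol(encode_pssm(d$dataset, d$store,
                                encoder_config(pssm_width = 20))), 420)
  expect_equal(ncol(encode_pssm(d$dataset, d$store,
                                encoder_config(pssm_width = 20,
                                               pssm_drop_terminal = TRUE))),
               400)

  # a cysteine at position 1 of a short protein: left flank fully padded
  edge <- motif_dataset("E1", 1, pad_only, "unknown")
  st <- mock_annotations(c(E1 = "C"), seed = 1)
  enc <- encode_pssm(edge, st, encoder_config())
  expect_true(all(enc[1, 1:(10 * 21)] == 0))
})

test_that("disorder encoding excludes the centre and zero-pads termini", {
  prot <- paste(rep("A", 30), collapse = "")
  prot <- paste0(substr(prot, 1, 14), "C", substr(prot, 16, 30))
  st <- annotation_store(list(P = list(protein_id = "P", length = 30,
                                       disorder = rep(0.5, 30))))
  ds <- motif_dataset("P", 15, substr(prot, 5, 25), "unknown")
  enc <- encode_disorder(ds, st)
  expect_equal(ncol(enc), 20)
  expect_equal(unname(enc[1, ]), rep(0.5, 20))

  edge <- motif_dataset("E1", 1, pad_only, "unknown")
  st1 <- annotation_store(list(E1 = list(protein_id = "E1", length = 1,
                                         disorder = 0.9)))
  expect_equal(unname(encode_disorder(edge, st1)[1, ]), rep(0, 20))
})

test_that("secondary-structure encoding is 84-dim with coded classes", {
  L <- 21
  st <- annotation_store(list(P = list(
    protein_id = "P", length = L,
    ss = data.frame(class = rep("C", L), pC = rep(1, L),
                    pE = rep(0, L), pH = rep(0, L)))))
  ds <- motif_dataset("P", 11, pad_only, "unknown")
  enc <- encode_secondary_structure(ds, st)
  expect_equal(ncol(enc), 84)
  expect_equal(unname(enc[1, ]), rep(c(0, 1, 0, 0), 21))

  st_bad <- annotation_store(list(P = list(
    protein_id = "P", length = L,
    ss = data.frame(class = rep("H", L), pC = rep(1.4, L),
                    pE = rep(0, L), pH = rep(0, L)))))
  expect_error(encode_secondary_structure(ds, st_bad), "\\[0, 1\\]")
})

test_that("min-max normalization maps training min to 0 and max to 1", {
  p <- min_max_fit(cbind(s = c(0, 10)))
  expect_equal(unname(min_max_apply(cbind(s = 5), p)[1, 1]), 0.5)
  expect_equal(unname(min_max_apply(cbind(s = 0), p)[1, 1]), 0)
  expect_equal(unname(min_max_apply(cbind(s = 10), p)[1, 1]), 1)
  expect_equal(unname(min_max_apply(cbind(s = c(1, 3, 5)),
                                    min_max_fit(cbind(s = c(1, 3, 5))))[, 1]),
               c(0, 0.5, 1))
  expect_warning(pc <- min_max_fit(cbind(k = c(2, 2, 2))), "constant")
  expect_equal(unname(min_max_apply(cbind(k = 7), pc)[1, 1]), 0)
  expect_error(min_max_apply(cbind(s = 1), list(min = 0)), "min_max_fit")
})

test_that("surface-accessibility block is 147-dim, rescaled and clipped", {
  d <- generate_dataset(synth_config(n_pos = 12, n_neg = 12, seed = 9))
  norm <- acc_norm_fit(d$dataset, d$store)
  enc <- encode_surface_accessibility(d$dataset, d$store, norm)
  expect_equal(ncol(enc), 147)
  expect_true(all(enc >= 0 & enc <= 1))
  expect_error(encode_surface_accessibility(d$dataset, d$store),
               "not fitted")
})

test_that("assembled matrix reproduces the published block dimensions", {
  d <- generate_dataset(synth_config(n_pos = 10, n_neg = 10, seed = 2))
  table2 <- encoder_config(pssm_width = 20, pssm_drop_terminal = TRUE)
  fm <- assemble_feature_matrix(d$dataset, d$store, table2)
  dims <- vapply(fm$blocks, length, integer(1))
  expect_equal(unname(dims), c(20, 2400, 441, 400, 1344, 441, 20, 84, 147))
  expect_equal(ncol(fm$values), 5297)
  expect_false(anyDuplicated(colnames(fm$values)) > 0)

  # prose PSSM configuration: 441-column PSSM block
  fm441 <- assemble_feature_matrix(d$dataset, d$store, encoder_config())
  expect_equal(ncol(fm441$values), 5338)

  seq_only <- assemble_feature_matrix(
    d$dataset, blocks = c("AAC", "CKSAAP", "BLOSUM62", "AAindex", "BINARY"))
  expect_equal(ncol(seq_only$values), 20 + 2400 + 441 + 1344 + 441)

  # determinism: encoding twice is byte-identical
  fm_b <- assemble_feature_matrix(d$dataset, d$store, table2)
  expect_identical(fm$values, fm_b$values)
})
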