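# Fingerprints, SMILES encoding, molecular graphs, cell/condition features.

test_that("fingerprint blocks have the documented widths and layout", {
  fp <- fingerprint_concat(c("CCO", "c1ccccc1"),
                           c("maccs", "ecfp6", "fcfp4", "pcfp"))
  expect_equal(ncol(fp), 3095L)
  expect_equal(unname(attr(fp, "layout")), c(166L, 1024L, 1024L, 881L))
  expect_equal(names(attr(fp, "layout")),
               c("maccs", "ecfp6", "fcfp4", "pcfp"))
  expect_true(all(fp %in% c(0, 1)))
})

test_that("featurization is deterministic and canonicalization-invariant", {
  a <- fingerprint_concat("c1ccccc1", c("maccs", "ecfp6"))
  b <- fingerprint_concat("c1ccccc1", c("maccs", "ecfp6"))
  expect_equal(unname(a), unname(b))
  # same molecule written with different atom orders
  e1 <- morgan_fingerprint("CCO")
  e2 <- morgan_fingerprint("OCC")
  expect_equal(unname(e1[1, ]), unname(e2[1, ]))
})

test_that("tanimoto behaves as a similarity on random molecule pairs", {
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  sm <- gen_molecules(20, seed = 13)
  fp <- morgan_fingerprint(sm, 6, 1024, "connectivity")
  for (i in seq_len(nrow(fp))) {
    expect_equal(tanimoto(fp[i, ], fp[i, ]), 1)
    s <- tanimoto(fp[1, ], fp[i, ])
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("unparseable SMILES raise featurization errors", {
  expect_error(fingerprint_concat("C1CC", "maccs"),
               class = "digera_featurization_error")
  expect_error(featurize_graph("C1CC"),
               class = "digera_featurization_error")
})

test_that("mfbert slot requires a registered provider and uses it", {
  # a fresh name is never registered
  expect_error(get_embedding_provider("no_such_provider"),
               class = "digera_configuration_error")
  hash_embedding_provider(16)
  fp <- fingerprint_concat("CCO", c("maccs", "mfbert"))
  expect_equal(unname(attr(fp, "layout")), c(166L, 16L))
  # deterministic
  fp2 <- fingerprint_concat("CCO", c("maccs", "mfbert"))
  expect_equal(unname(fp), unname(fp2))
})

test_that("smiles one-hot encodes with specials and round-trips", {
  corpus <- gen_molecules(50, seed = 17)
  dict <- build_smiles_dictionary(corpus)
  enc <- smiles_one_hot("C", dict, max_len = 120, max_mw = Inf)
  expect_equal(dim(enc), c(120L, length(dict)))
  expect_true(all(rowSums(enc) == 1))         # exactly one 1 per row
  expect_equal(smiles_decode(enc), "C")
  for (s in corpus) {
    e <- smiles_one_hot(s, dict, max_len = 120, max_mw = Inf)
    expect_equal(smiles_decode(e), s)
  }
})

test_that("smiles encoding rejects over-length, over-weight and unknowns", {
  dict <- build_smiles_dictionary(c("CCO"))
  long <- strrep("C", 121)
  expect_error(smiles_one_hot(long, dict, max_mw = Inf), "tokens",
               class = "digera_validation_error")
  expect_error(smiles_one_hot("CCN", dict, max_mw = Inf), "N",
               class = "digera_encoding_error")
  heavy <- paste0("C", strrep("(F)(F)C", 15))
  dict2 <- build_smiles_dictionary(heavy)
  expect_error(smiles_one_hot(heavy, dict2, max_mw = 600),
               class = "digera_validation_error")
})

test_that("smiles dictionary persists through JSON", {
  dict <- build_smiles_dictionary(gen_molecules(20, seed = 19))
  path <- tempfile(fileext = ".json")
  write_smiles_dictionary(dict, path)
  back <- read_smiles_dictionary(path)
  expect_equal(unclass(back), unclass(dict))
})

test_that("molecular graphs have fixed 63/8 feature widths", {
  methane <- featurize_graph("C")
  expect_equal(dim(methane$atom_features), c(1L, 63L))
  expect_equal(nrow(methane$bond_features), 0L)

  ethane <- featurize_graph("CC")
  expect_equal(dim(ethane$atom_features), c(2L, 63L))
  expect_equal(ethane$bond_features[1, 1:4], c(1L, 0L, 0L, 0L))  # single

  benzene <- featurize_graph("c1ccccc1")
  expect_equal(nrow(benzene$atom_features), 6L)
  expect_equal(nrow(benzene$bond_features), 6L)
  # aromaticity flag: last two atom-feature columns are (non-aromatic,
  # aromatic)
  expect_true(all(benzene$atom_features[, 63] == 1))
  # all six ring bonds typed aromatic
  expect_true(all(benzene$bond_features[, 4] == 1))
  expect_true(all(benzene$bond_features[, 8] == 1))  # in ring
})

test_that("every atom row is one-hot within its blocks", {
  for (s in gen_molecules(10, seed = 23)) {
    g <- featurize_graph(s)
    blocks <- list(1:44, 45:50, 51:55, 56:61, 62:63)
    for (b in blocks) {
      expect_true(all(rowSums(g$atom_features[, b, drop = FALSE]) == 1))
    }
    if (nrow(g$bond_features)) {
      expect_true(all(rowSums(g$bond_features[, 1:4, drop = FALSE]) == 1))
    }
    expect_true(all(g$edges >= 1 & g$edges <= nrow(g$atom_features)))
  }
})

test_that("condition one-hot covers the dose/time vocabulary", {
  expect_equal(unname(condition_one_hot(10, 24)), c(0L, 1L, 0L, 1L))
  expect_equal(unname(condition_one_hot(5, 6)), c(1L, 0L, 1L, 0L))
  expect_error(condition_one_hot(7, 6), class = "digera_validation_error")
  v <- condition_one_hot(5, 24)
  expect_equal(sum(v), 2L)
})

test_that("cell-line PCA recovers exact low-rank structure", {
  ge <- gen_gene_effects(n_cell_lines = 40, n_genes = 100, rank = 2,
                         noise_sd = 0, seed = 2)
  fit <- cell_line_pca(ge$effects, n_components = 2)
  expect_gte(sum(fit$explained_variance[1:2]), 0.999)
  expect_equal(dim(fit$features), c(40L, 2L))
})

test_that("isotropic noise spreads variance evenly across components", {
  set.seed(4)
  m <- matrix(rnorm(6000 * 20), 6000, 20)
  rownames(m) <- paste0("CL", 1:6000)
  fit <- cell_line_pca(m, n_components = 10)
  expect_true(all(abs(fit$explained_variance - 1 / 20) < 0.01))
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_lte(sum(fit$explained_variance), 1 + 1e-8)
})

test_that("variance-targeted PCA recovers the planted factor count", {
  # scaled-down plant-and-recover: 10 factors against matched noise so the
  # factor subspace carries about half the total variance
  ge <- gen_gene_effects(n_cell_lines = 300, n_genes = 600, rank = 10,
                         noise_sd = sqrt(10), seed = 6)
  fit <- cell_line_pca(ge$effects, variance_target = 0.5)
  expect_gte(fit$n_components, 8)
  expect_lte(fit$n_components, 12)
})

test_that("PCA imputes missing effects and validates component counts", {
  ge <- gen_gene_effects(n_cell_lines = 30, n_genes = 50, rank = 3,
                         missing_frac = 0.05, seed = 7)
  fit <- cell_line_pca(ge$effects, n_components = 3)
  expect_false(anyNA(fit$features))
  expect_error(cell_line_pca(ge$effects, n_components = 40),
               class = "digera_validation_error")
})

test_that("feature bundles record their block layout", {
  chem <- matrix(1, 3, 5)
  cond <- matrix(0L, 3, 4)
  fb <- feature_bundle(chem, cond = cond)
  expect_equal(unname(attr(fb, "layout")), c(5L, 4L))
  expect_error(feature_bundle(chem, cond = matrix(0L, 2, 4)),
               class = "digera_validation_error")
})
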