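test_that("registry has exactly 200 uniquely named descriptors", {
  reg <- descriptor_registry()
  expect_equal(nrow(reg), 200L)
  expect_false(any(duplicated(reg$name)))
  expect_true(all(c("name", "family", "description") %in% names(reg)))
})

test_that("registry matches the frozen manifest shipped with the package", {
  manifest <- utils::read.csv(
    system.file("extdata", "descriptor_manifest.csv", package = "molgru"),
    stringsAsFactors = FALSE)
  reg <- descriptor_registry()
  expect_equal(reg$name, manifest$name)
  expect_equal(reg$family, manifest$family)
})

test_that("compute_descriptors returns all 200 columns, finite values", {
  smi <- c("c1ccccc1CCN", "CC(=O)OC1CCCCC1", "ClCCCl")
  d <- compute_descriptors(smi)
  expect_equal(nrow(d), 3L)
  expect_equal(ncol(d), 202L)  # id + smiles + 200
  X <- as.matrix(d[, descriptor_names()])
  expect_true(all(is.finite(X)))
})

test_that("hand-checked descriptor values on small molecules", {
  d <- compute_descriptors("c1ccccc1")       # benzene
  expect_equal(d$n_heavy, 6)
  expect_equal(d$n_aromatic_atoms, 6)
  expect_equal(d$n_rings, 1)
  d2 <- compute_descriptors("CC(=O)O")       # acetic acid
  expect_equal(d2$n_heavy, 4)
  expect_equal(d2$fg_carboxylic_acid, 1)
  d3 <- compute_descriptors("CCCCCCCCCC")    # decane
  expect_equal(d3$n_rings, 0)
  # Wiener index of the n-chain is n(n^2-1)/6; for decane 10*99/6 = 165
  expect_equal(d3$wiener, 165)
})

test_that("descriptors are invariant to SMILES form of the same molecule", {
  a <- compute_descriptors("OCC")
  b <- compute_descriptors("CCO")
  expect_equal(as.numeric(a[, descriptor_names()]),
               as.numeric(b[, descriptor_names()]))
})

test_that("invalid inputs are rejected with reasons, not described", {
  d <- compute_descriptors(c("CCO", "C("))
  expect_equal(nrow(d), 1L)
  rej <- attr(d, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$smiles, "C(")
  expect_true(nzchar(rej$reason))
})
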