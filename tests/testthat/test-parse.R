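test_that("valid SMILES parse with correct atom/bond counts", {
  m <- smiles_parse("CCO")
  expect_true(m$valid)
  expect_equal(heavy_atom_count(m), 3L)
  expect_equal(nrow(m$bonds), 2L)

  benz <- smiles_parse("c1ccccc1")
  expect_true(benz$valid)
  expect_equal(heavy_atom_count(benz), 6L)
  expect_true(all(benz$atoms$aromatic))

  chg <- smiles_parse("C[NH3+]")
  expect_true(chg$valid)
  expect_equal(chg$atoms$charge[2], 1L)
})

test_that("structural errors are rejected with reasons", {
  bad <- c(
    "C(",        # unbalanced parenthesis
    "C1CC",      # unclosed ring bond
    "CC)C",      # stray closing parenthesis
    "C=",        # dangling bond
    "",          # empty
    "C..C",      # misplaced dot
    "C1C1"       # two-membered ring
  )
  for (s in bad) {
    m <- smiles_parse(s)
    expect_false(m$valid, info = s)
    expect_true(nzchar(m$reason), info = s)
  }
})

test_that("valence violations are rejected", {
  expect_false(smiles_parse("C(C)(C)(C)(C)C")$valid)  # 5-valent carbon
  expect_false(smiles_parse("O=C=O2")$valid)          # unclosed ring
  expect_false(smiles_parse("FF(F)F")$valid)          # multivalent F
  expect_true(smiles_parse("O=C=O")$valid)
  expect_true(smiles_parse("C(C)(C)(C)C")$valid)
})

test_that("aromaticity requires a kekulizable aromatic ring", {
  expect_true(smiles_parse("c1ccncc1")$valid)    # pyridine
  expect_false(smiles_parse("c1ccc1")$valid)     # cyclobutadiene-like
  expect_false(smiles_parse("cc")$valid)         # aromatic atoms, no ring
  expect_false(smiles_parse("c1ccccc1c")$valid)  # dangling aromatic atom
})

test_that("smiles_is_valid is vectorized and never throws", {
  v <- smiles_is_valid(c("CCO", "C(", "c1ccccc1", "not smiles", ""))
  expect_equal(v, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("molecular weight matches hand-computed values", {
  # ethanol C2H6O = 2*12.011 + 6*1.008 + 15.999
  expect_equal(molecular_weight(smiles_parse("CCO")),
               2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 1e-6)
  # benzene C6H6
  expect_equal(molecular_weight(smiles_parse("c1ccccc1")),
               6 * 12.011 + 6 * 1.008, tolerance = 1e-6)
})

test_that("bracket atoms control hydrogens and stereo", {
  m <- smiles_parse("C[C@H](N)O")
  expect_true(m$valid)
  expect_equal(m$atoms$stereo[2], "@")
  expect_equal(m$atoms$hcount[2], 1L)
})
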