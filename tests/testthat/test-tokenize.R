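test_that("tokenizer splits multi-character tokens correctly", {
  expect_equal(smiles_tokenize("CCl"), c("C", "Cl"))
  expect_equal(smiles_tokenize("CBr"), c("C", "Br"))
  expect_equal(smiles_tokenize("[NH3+]C"), c("[NH3+]", "C"))
  expect_equal(smiles_tokenize("C[C@H](N)O"),
               c("C", "[C@H]", "(", "N", ")", "O"))
  expect_equal(smiles_tokenize("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(smiles_tokenize("C%12CC%12"),
               c("C", "%12", "C", "C", "%12"))
})

test_that("tokenizer covers the whole string or errors", {
  expect_error(smiles_tokenize("C~C"), "token")
  expect_error(smiles_tokenize(""), "empty")
})

test_that("vocabulary keeps specials distinct and first", {
  v <- smiles_vocabulary(c("CCO", "c1ccccc1Cl"))
  expect_s3_class(v, "smiles_vocabulary")
  expect_equal(v$tokens[1:3], c("<pad>", "<bos>", "<eos>"))
  expect_equal(v$pad, 1L)
  expect_equal(v$bos, 2L)
  expect_equal(v$eos, 3L)
  expect_false(any(duplicated(v$tokens)))
  # chemical tokens never collide with specials
  expect_false(any(c("<pad>", "<bos>", "<eos>") %in% v$tokens[-(1:3)]))
})

test_that("encode brackets with BOS/EOS and round-trips", {
  v <- smiles_vocabulary(c("CCO", "c1ccccc1", "C[C@@H](N)Cl"))
  idx <- smiles_encode("CCO", v)
  expect_equal(idx[1], v$bos)
  expect_equal(idx[length(idx)], v$eos)
  expect_equal(smiles_decode(idx, v), "CCO")
  for (s in c("c1ccccc1", "C[C@@H](N)Cl")) {
    expect_equal(smiles_decode(smiles_encode(s, v), v), s)
  }
})

test_that("out-of-vocabulary tokens are named in the error", {
  v <- smiles_vocabulary("CCO")
  expect_error(smiles_encode("CCS", v), "S")
})

test_that("encode_all maps a corpus", {
  v <- smiles_vocabulary(c("CCO", "CCN"))
  e <- smiles_encode_all(c("CCO", "CCN"), v)
  expect_length(e, 2L)
  expect_true(all(vapply(e, function(x) x[1] == v$bos, logical(1))))
})
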