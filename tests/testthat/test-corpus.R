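test_that("canonicalization is idempotent and validity-aware", {
  out <- canonicalize_smiles(c("OCC", "CCO", "C("))
  expect_false(is.na(out[1]))
  expect_equal(out[1], out[2])      # same molecule, same canonical form
  expect_true(is.na(out[3]))        # invalid input never canonicalized
  # idempotence
  expect_equal(canonicalize_smiles(out[1]), out[1])
})

test_that("smiles_records populates fields per contract", {
  r <- smiles_records(c("OCC", "C(", "c1ccccc1"))
  expect_equal(r$is_valid, c(TRUE, FALSE, TRUE))
  expect_equal(r$heavy_atoms[1], 3L)
  expect_true(is.na(r$canonical[2]))
  expect_true(all(r$heavy_atoms[r$is_valid] >= 1L))
})

test_that("filter_corpus applies every rule and reports counts", {
  raw <- c(
    "CCO",                                  # too small (3 heavy atoms)
    "C(",                                   # invalid
    strrep("C", 101),                       # too many heavy atoms
    "CCCCCCCCCC",                           # 10 heavy atoms: kept
    "CCCCCCCCCC",                           # duplicate
    "c1ccccc1CCCC"                          # kept
  )
  recs <- smiles_records(raw)
  kept <- filter_corpus(recs)
  expect_equal(nrow(kept), 2L)
  cur <- attr(kept, "curation")
  expect_true(cur$removed_invalid >= 1L)
  expect_true(cur$removed_heavy_atoms >= 2L)
  expect_true(cur$removed_duplicate >= 1L)

  # blocklist removal by canonical identity, independent of input form
  bl <- canonicalize_smiles("CCCCCCCCCC")
  kept2 <- filter_corpus(recs, blocklist = bl)
  expect_false(bl %in% kept2$canonical)
})

test_that("length filter uses the canonical string bound", {
  long <- paste0(strrep("C(Cl)", 40), "C")   # long string, < 100 heavy
  recs <- smiles_records(long)
  expect_true(recs$is_valid[1])
  kept <- filter_corpus(recs, max_len = 50L)
  expect_equal(nrow(kept), 0L)
})

test_that("read/write .smi round-trips", {
  p <- tempfile(fileext = ".smi")
  write_smi(c("CCO", "c1ccccc1"), p)
  expect_equal(read_smi(p)$smiles, c("CCO", "c1ccccc1"))
  unlink(p)
})

test_that("curation report is written as JSON", {
  recs <- smiles_records(c("CCCCCCCCCCCC", "C("))
  kept <- filter_corpus(recs)
  p <- tempfile(fileext = ".json")
  write_curation_report(kept, p)
  rep <- jsonlite::read_json(p)
  expect_true(rep$removed_invalid >= 1)
  unlink(p)
})
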