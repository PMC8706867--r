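test_that("gen_corpus yields n unique valid canonical strings", {
  recs <- gen_corpus(corpus_spec(n = 150L, seed = 21L))
  expect_equal(nrow(recs), 150L)
  expect_true(all(recs$is_valid))
  expect_false(any(duplicated(recs$canonical)))
  expect_true(all(smiles_is_valid(recs$canonical)))
  # canonical means canonicalization is a fixed point
  expect_equal(canonicalize_smiles(recs$canonical[1:10]),
               recs$canonical[1:10])
})

test_that("gen_corpus respects the heavy-atom range", {
  spec <- corpus_spec(n = 60L, seed = 22L, heavy_range = c(10L, 16L))
  recs <- gen_corpus(spec)
  expect_true(all(recs$heavy_atoms >= 10L & recs$heavy_atoms <= 16L))
})

test_that("feature flags are honored", {
  no_rings <- gen_corpus(corpus_spec(n = 40L, seed = 23L, rings = FALSE))
  pv <- property_vector(no_rings$canonical)
  expect_true(all(pv$aromatic_rings == 0 & pv$aliphatic_rings == 0))

  no_hal <- gen_corpus(corpus_spec(n = 40L, seed = 24L, halogens = FALSE))
  expect_false(any(grepl("F|Cl|Br|I", no_hal$canonical)))

  no_chg <- gen_corpus(corpus_spec(n = 40L, seed = 25L, charges = FALSE))
  expect_false(any(grepl("\\+|-", no_chg$canonical)))
})

test_that("generation is reproducible per seed", {
  a <- gen_corpus(corpus_spec(n = 50L, seed = 31L))
  b <- gen_corpus(corpus_spec(n = 50L, seed = 31L))
  expect_identical(a$canonical, b$canonical)
  c <- gen_corpus(corpus_spec(n = 50L, seed = 32L))
  expect_false(identical(a$canonical, c$canonical))
})

test_that("generated strings survive the curation pipeline", {
  recs <- gen_corpus(corpus_spec(n = 80L, seed = 26L))
  kept <- filter_corpus(recs)
  expect_equal(nrow(kept), 80L)  # nothing valid gets dropped
})

test_that("gen_focused biases the requested property and reports it", {
  spec <- corpus_spec(n = 40L, seed = 27L)
  foc <- gen_focused(spec, bias = "aromatic_rings", direction = "high")
  expect_equal(nrow(foc), 40L)
  rep <- attr(foc, "bias_report")
  expect_gt(rep$focused_mean, rep$baseline_mean)
  expect_length(rep$ci95, 2L)
  expect_error(gen_focused(spec, bias = "no_such_property"), "bias")
})

test_that("gen_labeled separability scales with effect size", {
  spec0 <- labeled_spec(n_pos = 30L, n_neg = 30L, effect_size = 0,
                        n_informative = 10L, seed = 5L)
  spec5 <- labeled_spec(n_pos = 30L, n_neg = 30L, effect_size = 5,
                        n_informative = 10L, seed = 5L)
  d0 <- gen_labeled(spec0)
  d5 <- gen_labeled(spec5)
  expect_equal(ncol(d0$descriptors), 200L)
  expect_equal(levels(d0$labels), c("negative", "positive"))
  gap0 <- abs(mean(as.matrix(d0$descriptors[d0$labels == "positive",
                                            d0$informative])) -
              mean(as.matrix(d0$descriptors[d0$labels == "negative",
                                            d0$informative])))
  gap5 <- abs(mean(as.matrix(d5$descriptors[d5$labels == "positive",
                                            d5$informative])) -
              mean(as.matrix(d5$descriptors[d5$labels == "negative",
                                            d5$informative])))
  expect_lt(gap0, 0.5)
  expect_gt(gap5, 4)
})

test_that("gen_complex encodes its ground truth", {
  ps <- gen_complex(5L, data.frame(residue = c(2L, 4L),
                                   distance = c(3, 4.5)), seed = 9L)
  expect_s3_class(ps, "pose_set")
  expect_length(ps$ligands, 2L)
  gt <- attr(ps, "ground_truth")
  # the construction puts each ligand at its requested min distance
  expect_equal(gt[[1]][["2"]], 3, tolerance = 0.2)
  expect_equal(gt[[2]][["4"]], 4.5, tolerance = 0.2)
  expect_error(gen_complex(3L, data.frame(residue = 9L, distance = 3)))
})
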