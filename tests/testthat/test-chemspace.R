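test_that("t-SNE embeds with deterministic seeded output", {
  set.seed(99)
  X <- rbind(matrix(rnorm(30 * 3), 30, 3),
             matrix(rnorm(30 * 3, mean = 6), 30, 3))
  Y1 <- tsne_embed(X, seed = 5L, perplexity = 10, max_iter = 150L)
  Y2 <- tsne_embed(X, seed = 5L, perplexity = 10, max_iter = 150L)
  expect_identical(Y1, Y2)
  expect_equal(dim(Y1), c(60L, 2L))
  expect_true(all(is.finite(Y1)))
  # two well-separated clusters stay separated in the embedding:
  # within-cluster distances are smaller than between-cluster ones
  d <- as.matrix(dist(Y1))
  within <- mean(d[1:30, 1:30])
  between <- mean(d[1:30, 31:60])
  expect_gt(between, within)
})

test_that("t-SNE validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(tsne_embed(X, perplexity = 10), "perplexity")
  expect_error(tsne_embed(X[1:2, , drop = FALSE]), "3 rows")
})

test_that("chemspace_embed returns tagged coordinates with properties", {
  recs <- gen_corpus(corpus_spec(n = 30L, seed = 61L))
  gen <- gen_corpus(corpus_spec(n = 10L, seed = 62L))
  emb <- chemspace_embed(c(recs$canonical, gen$canonical),
                         c(rep("known_train", 30), rep("generated", 10)),
                         seed = 3L, perplexity = 8, max_iter = 100L)
  expect_s3_class(emb, "chemspace_embedding")
  expect_equal(nrow(emb), 40L)
  expect_setequal(unique(emb$set), c("known_train", "generated"))
  Z <- attr(emb, "properties")
  expect_equal(dim(Z), c(40L, 7L))
})

test_that("duplicated molecules land on near-identical coordinates", {
  smi <- c(gen_corpus(corpus_spec(n = 20L, seed = 63L))$canonical)
  both <- c(smi, smi[1])   # duplicate the first molecule
  emb <- chemspace_embed(both, c(rep("known_train", 20), "generated"),
                         seed = 4L, perplexity = 6, max_iter = 200L)
  d_dup <- sqrt((emb$x[1] - emb$x[21])^2 + (emb$y[1] - emb$y[21])^2)
  spread <- max(dist(cbind(emb$x, emb$y)))
  # exact duplicates share the strongest affinity; they end up much
  # closer than the embedding's overall extent (t-SNE's residual
  # repulsion keeps even coincident inputs at a small finite distance)
  expect_lt(d_dup, 0.15 * spread)
})

test_that("overlap report quantifies property-space mixing", {
  known <- gen_corpus(corpus_spec(n = 25L, seed = 64L))
  # generated from the same distribution: high overlap expected
  gen_same <- gen_corpus(corpus_spec(n = 10L, seed = 65L))
  emb <- chemspace_embed(c(known$canonical, gen_same$canonical),
                         c(rep("known_train", 25), rep("generated", 10)),
                         seed = 5L, perplexity = 8, max_iter = 100L)
  ov <- overlap_report(emb, k = 5L)
  expect_true(ov$overlap_fraction >= 0 && ov$overlap_fraction <= 1)
  expect_gt(ov$overlap_fraction, 0.5)
  expect_true(all(c("set", "property", "mean", "sd") %in%
                    names(ov$property_summary)))
})

test_that("overlap report needs both tags", {
  recs <- gen_corpus(corpus_spec(n = 12L, seed = 66L))
  emb <- chemspace_embed(recs$canonical, rep("known_train", 12),
                         seed = 1L, perplexity = 4, max_iter = 60L)
  expect_error(overlap_report(emb), "generated")
})
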