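# Small-architecture LM tests (the full-size model is exercised in
# test-acceptance.R). Tiny dims keep each test in seconds.

.toy_smiles <- c("CCO", "CCN", "CCC", "CCCO", "CCCN", "OCCO",
                 "NCCN", "CCOC", "CCNC", "COC")
.toy_vocab <- smiles_vocabulary(.toy_smiles)
.toy_cfg <- gru_config(vocab_size = length(.toy_vocab$tokens),
                       embedding_dim = 12L, gru_layers = 2L,
                       hidden_units = 24L, max_length = 20L)

test_that("learning-rate schedule matches the closed form", {
  expect_equal(lr_at_step(0), 0.001)
  expect_equal(lr_at_step(299), 0.001)
  expect_equal(lr_at_step(300), 0.00095)
  expect_equal(lr_at_step(600), 0.0009025)
  expect_equal(lr_at_step(150, initial_lr = 0.01, decay_rate = 0.5,
                          decay_every = 50), 0.01 * 0.5^3)
})

test_that("model construction validates vocab/config agreement", {
  m <- gru_lm(.toy_vocab, .toy_cfg, seed = 1L)
  expect_s3_class(m, "gru_lm")
  expect_equal(m$step, 0L)
  bad_cfg <- gru_config(vocab_size = 99L)
  expect_error(gru_lm(.toy_vocab, bad_cfg), "vocab_size")
})

test_that("training reduces loss and records the schedule", {
  m <- gru_lm(.toy_vocab, .toy_cfg, seed = 2L)
  tc <- train_config(max_steps = 60L, batch_size = 8L, seed = 3L,
                     decay_every = 25L)
  m2 <- train_lm(m, .toy_smiles, tc)
  expect_equal(m2$step, 60L)
  expect_equal(nrow(m2$history), 60L)
  expect_lt(mean(tail(m2$history$loss, 10)),
            mean(head(m2$history$loss, 10)))
  expect_equal(m2$history$lr[1], 0.001)
  expect_equal(m2$history$lr[26], 0.001 * 0.95)
  expect_equal(m2$history$lr[51], 0.001 * 0.95^2)
  expect_true(all(m2$history$phase == "pretrain"))
  # the input model is untouched
  expect_equal(m$step, 0L)
})

test_that("training is deterministic given seeds", {
  tc <- train_config(max_steps = 20L, batch_size = 8L, seed = 5L)
  m1 <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 4L), .toy_smiles, tc)
  m2 <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 4L), .toy_smiles, tc)
  expect_identical(m1$history$loss, m2$history$loss)
  s1 <- sample_lm(m1, n = 30L, seed = 8L)
  s2 <- sample_lm(m2, n = 30L, seed = 8L)
  expect_identical(s1$strings, s2$strings)
  s3 <- sample_lm(m1, n = 30L, seed = 9L)
  expect_false(identical(s1$strings, s3$strings))
})

test_that("a memorizing model samples valid strings", {
  # 2 strings, enough steps: the model should nearly memorize
  m <- gru_lm(smiles_vocabulary(c("CCO", "CCN")),
              gru_config(vocab_size = 6L, embedding_dim = 8L,
                         gru_layers = 1L, hidden_units = 16L,
                         max_length = 10L), seed = 6L)
  tc <- train_config(max_steps = 500L, batch_size = 4L, seed = 7L)
  m <- train_lm(m, c("CCO", "CCN"), tc)
  sb <- sample_lm(m, n = 50L, seed = 10L)
  expect_gte(sb$valid_fraction, 0.9)
  expect_true(all(sb$strings[smiles_is_valid(sb$strings)] %in%
                    c("CCO", "CCN")) ||
                sb$valid_fraction >= 0.9)
})

test_that("fine_tune restarts the lr schedule and tags the phase", {
  tc <- train_config(max_steps = 40L, batch_size = 8L, seed = 5L,
                     decay_every = 10L)
  m <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 4L), .toy_smiles, tc)
  lr_end <- tail(m$history$lr, 1)
  expect_lt(lr_end, 0.001)
  m2 <- fine_tune_lm(m, c("CCO", "OCCO"), tc)
  ft <- m2$history[m2$history$phase == "fine_tune", ]
  expect_equal(nrow(ft), 40L)
  expect_equal(ft$lr[1], 0.001)     # schedule restarted
  expect_warning(fine_tune_lm(gru_lm(.toy_vocab, .toy_cfg), "CCO",
                              train_config(max_steps = 1L, batch_size = 2L)),
                 "pretrained")
})

test_that("fine-tuning on out-of-vocabulary strings names the tokens", {
  m <- gru_lm(.toy_vocab, .toy_cfg, seed = 1L)
  tc <- train_config(max_steps = 5L, batch_size = 2L)
  expect_error(suppressWarnings(fine_tune_lm(m, "CCS", tc)), "S")
})

test_that("lm_loss and next_token_probs are coherent", {
  m <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 2L), .toy_smiles,
                train_config(max_steps = 50L, batch_size = 8L, seed = 3L))
  nll <- lm_loss(m, .toy_smiles)
  expect_true(is.finite(nll) && nll > 0)
  p <- next_token_probs(m, "CC")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-5)
  expect_equal(colnames(p), .toy_vocab$tokens)
})

test_that("save/load round-trips sampling behavior", {
  m <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 2L), .toy_smiles,
                train_config(max_steps = 20L, batch_size = 8L, seed = 3L))
  path <- tempfile(fileext = ".rds")
  save_lm(m, path)
  m2 <- load_lm(path)
  expect_identical(sample_lm(m, 20L, seed = 1L)$strings,
                   sample_lm(m2, 20L, seed = 1L)$strings)
  unlink(path)
})

test_that("validity_fraction contracts", {
  expect_equal(validity_fraction(c("CCO", "C(", "CC")), 2 / 3)
  expect_error(validity_fraction(character(0)), "empty")
})

test_that("training log is written as CSV", {
  m <- train_lm(gru_lm(.toy_vocab, .toy_cfg, seed = 2L), .toy_smiles,
                train_config(max_steps = 5L, batch_size = 4L, seed = 3L))
  p <- tempfile(fileext = ".csv")
  write_training_log(m, p)
  log <- utils::read.csv(p)
  expect_equal(nrow(log), 5L)
  expect_true(all(c("step", "loss", "lr", "phase") %in% names(log)))
  unlink(p)
})
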