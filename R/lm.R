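# GRU SMILES language model: configuration, pretraining, transfer
# learning and validity-checked sampling.  The numerical core (teacher-
# forced BPTT, Adam, ancestral sampling) lives in src/gru_lm.cpp; this
# file owns the model object, the schedule and the bookkeeping.

#' Model architecture configuration
#'
#' Defaults follow the reference architecture: a 128-dimensional
#' embedding feeding three stacked GRU layers of 512 units each, with a
#' softmax output over the vocabulary.
#'
#' @param vocab_size Number of tokens including the three specials.
#' @param embedding_dim Embedding width.
#' @param gru_layers Number of stacked GRU layers (>= 1).
#' @param hidden_units Hidden state width per layer.
#' @param max_length Maximum sequence length at sampling time (token
#'   count excluding specials); default matches the 140-character corpus
#'   curation bound.
#' @return A `gru_config` list.
#' @export
gru_config <- function(vocab_size, embedding_dim = 128L, gru_layers = 3L,
                       hidden_units = 512L, max_length = 140L) {
  stopifnot(vocab_size >= 4L, gru_layers >= 1L, hidden_units >= 1L,
            embedding_dim >= 1L, max_length >= 1L)
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 gru_layers = as.integer(gru_layers),
                 hidden_units = as.integer(hidden_units),
                 max_length = as.integer(max_length)),
            class = "gru_config")
}

#' Optimisation configuration
#'
#' Adam with an initial learning rate of 0.001 decayed multiplicatively
#' by a factor of (1 - decay_rate) once every `decay_every` steps, batch
#' size 128, mean negative log likelihood loss.
#'
#' @param max_steps Number of optimisation steps to run.
#' @param initial_lr Initial learning rate.
#' @param decay_rate Fractional decay applied every `decay_every` steps;
#'   must lie in (0, 1).
#' @param decay_every Steps between decays.
#' @param batch_size Sequences per step (sampled with replacement).
#' @param seed Integer seed driving batch selection; mandatory for
#'   reproducibility.
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param bucket Draw each batch as a random window of the
#'   length-sorted corpus instead of fully independent draws; batches
#'   then contain similar-length sequences, which avoids spending most
#'   of the compute on padding. Sampling remains seeded and every
#'   sequence remains reachable each step.
#' @return A `train_config` list.
#' @export
train_config <- function(max_steps, initial_lr = 0.001, decay_rate = 0.05,
                         decay_every = 300L, batch_size = 128L,
                         seed = 1L, clip_norm = 5, bucket = TRUE) {
  stopifnot(max_steps >= 0L, decay_rate > 0, decay_rate < 1,
            batch_size >= 1L, decay_every >= 1L, initial_lr > 0)
  structure(list(max_steps = as.integer(max_steps),
                 initial_lr = initial_lr, decay_rate = decay_rate,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), clip_norm = clip_norm,
                 bucket = isTRUE(bucket)),
            class = "train_config")
}

#' Learning rate under the stepped decay schedule
#'
#' `lr(step) = initial_lr * (1 - decay_rate)^floor(step / decay_every)`,
#' so with the defaults the rate is 0.001 at step 0, 0.00095 at step
#' 300 and 0.0009025 at step 600.
#'
#' @param step Step number(s), 0-based.
#' @param initial_lr,decay_rate,decay_every Schedule parameters.
#' @return Numeric vector of learning rates.
#' @export
lr_at_step <- function(step, initial_lr = 0.001, decay_rate = 0.05,
                       decay_every = 300L) {
  initial_lr * (1 - decay_rate)^(floor(step / decay_every))
}

.init_params <- function(cfg, seed) {
  set.seed(seed)
  V <- cfg$vocab_size; D <- cfg$embedding_dim
  H <- cfg$hidden_units; L <- cfg$gru_layers
  r <- function(nr, nc, scale) matrix(stats::runif(nr * nc, -scale, scale),
                                      nr, nc)
  list(
    E = r(V, D, 0.08),
    Wx = lapply(seq_len(L), function(l) {
      nin <- if (l == 1L) D else H
      r(nin, 3L * H, sqrt(1 / nin))
    }),
    Wh = lapply(seq_len(L), function(l) r(H, 3L * H, sqrt(1 / H))),
    b = lapply(seq_len(L), function(l) matrix(0, 1L, 3L * H)),
    Wy = r(H, V, sqrt(1 / H)),
    by = matrix(0, 1L, V)
  )
}

#' Create an untrained GRU SMILES language model
#'
#' @param vocab A [smiles_vocabulary()].
#' @param config A [gru_config()]; `vocab_size` is taken from the
#'   vocabulary and must match if given.
#' @param seed Seed for weight initialisation.
#' @return A `gru_lm` object: vocabulary, configuration, parameters,
#'   optimiser state, global step counter and training history.
#' @export
gru_lm <- function(vocab, config = NULL, seed = 1L) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (is.null(config)) {
    config <- gru_config(vocab_size = length(vocab$tokens))
  }
  stopifnot(inherits(config, "gru_config"))
  if (config$vocab_size != length(vocab$tokens)) {
    stop("config vocab_size (", config$vocab_size,
         ") does not match vocabulary (", length(vocab$tokens), ")")
  }
  structure(list(vocab = vocab, config = config,
                 params = .init_params(config, seed), opt = NULL,
                 step = 0L,
                 history = data.frame(step = integer(0), loss = numeric(0),
                                      lr = numeric(0),
                                      phase = character(0),
                                      valid128 = numeric(0))),
            class = "gru_lm")
}

#' @export
print.gru_lm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "GRU SMILES LM: %d-dim embedding, %d x %d GRU, vocab %d, step %d\n",
    cfg$embedding_dim, cfg$gru_layers, cfg$hidden_units, cfg$vocab_size,
    x$step))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last loss %.4f (lr %.2e, phase %s)\n", last$loss,
                last$lr, last$phase))
  }
  invisible(x)
}

.encode_corpus <- function(model, corpus) {
  if (is.character(corpus)) {
    smiles_encode_all(corpus, model$vocab)
  } else if (is.list(corpus)) {
    corpus
  } else {
    stop("corpus must be a character vector or a list of index vectors")
  }
}

.run_training <- function(model, corpus, tc, phase, eval_every, eval_n,
                          eval_seed) {
  stopifnot(inherits(model, "gru_lm"), inherits(tc, "train_config"))
  seqs <- .encode_corpus(model, corpus)
  if (length(seqs) == 0L) stop("empty training corpus")
  vmax <- max(vapply(seqs, max, integer(1)))
  if (vmax > model$config$vocab_size) {
    stop("encoded corpus contains index ", vmax,
         " beyond vocab size ", model$config$vocab_size)
  }
  if (tc$max_steps == 0L) return(model)

  chunk <- if (is.null(eval_every)) tc$max_steps else as.integer(eval_every)
  done <- 0L
  while (done < tc$max_steps) {
    k <- min(chunk, tc$max_steps - done)
    res <- .cpp_gru_train(model$params, model$opt, seqs, k,
                          tc$batch_size, tc$initial_lr, tc$decay_rate,
                          tc$decay_every, model$vocab$pad, model$step,
                          tc$seed + done, tc$clip_norm,
                          isTRUE(tc$bucket))
    model$params <- res$params
    model$opt <- res$opt
    hist <- data.frame(step = model$step + seq_len(k), loss = res$loss,
                       lr = res$lr, phase = phase, valid128 = NA_real_)
    model$step <- model$step + k
    done <- done + k
    if (!is.null(eval_every)) {
      sb <- sample_lm(model, n = eval_n, seed = eval_seed + done)
      hist$valid128[nrow(hist)] <- sb$valid_fraction
    }
    model$history <- rbind(model$history, hist)
  }
  model
}

#' Pretrain the language model
#'
#' Teacher-forced next-token training with mean negative log likelihood
#' loss; the per-step loss and learning rate are appended to the model's
#' history with phase `"pretrain"`.
#'
#' @param model A [gru_lm()].
#' @param corpus Character vector of SMILES (encoded through the model's
#'   vocabulary; out-of-vocabulary tokens are an error that names them)
#'   or a pre-encoded list of index sequences.
#' @param tc A [train_config()].
#' @param eval_every If not `NULL`, sample `eval_n` strings every this
#'   many steps and record their valid fraction in the history.
#' @param eval_n Evaluation sample size (the conventional checkpoint
#'   batch of 128).
#' @param eval_seed Seed for evaluation sampling.
#' @return The updated model (input is not modified in place).
#' @export
train_lm <- function(model, corpus, tc, eval_every = NULL, eval_n = 128L,
                     eval_seed = 999L) {
  .run_training(model, corpus, tc, "pretrain", eval_every, eval_n,
                eval_seed)
}

#' Fine-tune a pretrained model on a focused set
#'
#' Transfer learning: continues optimisation of all weights on a small
#' focused corpus, restarting the learning-rate schedule at
#' `tc$initial_lr`.  History rows are tagged with phase `"fine_tune"`.
#' With `tc$max_steps = 0` the returned model is identical to the input.
#'
#' @inheritParams train_lm
#' @param focused Character vector of SMILES or encoded sequences; must
#'   be covered by the model's vocabulary (missing tokens are reported
#'   by name, never dropped).
#' @return The fine-tuned model; the original object is untouched.
#' @export
fine_tune_lm <- function(model, focused, tc, eval_every = NULL,
                         eval_n = 128L, eval_seed = 999L) {
  stopifnot(inherits(model, "gru_lm"))
  if (model$step == 0L) {
    warning("fine-tuning a model that has not been pretrained")
  }
  # restart the schedule: reset the global step for lr purposes but keep
  # Adam moments (standard warm-start transfer learning)
  model$step <- 0L
  .run_training(model, focused, tc, "fine_tune", eval_every, eval_n,
                eval_seed)
}

#' Sample SMILES strings from the model
#'
#' Ancestral sampling from BOS until EOS or `max_length` tokens; strings
#' that never emit EOS are truncated and validity-checked as-is.
#' Validity is judged by the strict parser.  The same seed always yields
#' the same batch.
#'
#' @param model A trained [gru_lm()].
#' @param n Number of strings to request.
#' @param seed Integer sampling seed.
#' @param temperature Softmax temperature (> 0); 1 samples the model
#'   distribution, smaller values concentrate it.
#' @param max_length Cap on generated token count; defaults to the model
#'   configuration.
#' @return A `sample_batch`: list with `strings`, `n_requested`,
#'   `n_valid`, `valid_fraction`.
#' @export
sample_lm <- function(model, n, seed = 1L, temperature = 1,
                      max_length = NULL) {
  stopifnot(inherits(model, "gru_lm"), n >= 1L, temperature > 0)
  if (is.null(max_length)) max_length <- model$config$max_length
  idx <- .cpp_gru_sample(model$params, as.integer(n),
                         as.integer(max_length), temperature,
                         model$vocab$bos, model$vocab$eos,
                         as.integer(seed))
  strings <- vapply(idx, function(v) {
    paste(model$vocab$tokens[v], collapse = "")
  }, character(1))
  nv <- sum(smiles_is_valid(strings))
  structure(list(strings = strings, n_requested = as.integer(n),
                 n_valid = as.integer(nv), valid_fraction = nv / n),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("sample batch: %d requested, %d valid (%.1f%%)\n",
              x$n_requested, x$n_valid, 100 * x$valid_fraction))
  utils::head(x$strings)
  invisible(x)
}

#' Fraction of parseable SMILES strings
#'
#' @param strings Character vector (must be nonempty).
#' @return Ratio in [0, 1].
#' @export
validity_fraction <- function(strings) {
  if (length(strings) == 0L) stop("empty string list")
  mean(smiles_is_valid(strings))
}

#' Mean negative log likelihood of the model on a set of strings
#' @param model A [gru_lm()].
#' @param smiles Character vector or encoded sequences.
#' @return Mean NLL per token (natural log).
#' @export
lm_loss <- function(model, smiles) {
  seqs <- .encode_corpus(model, smiles)
  .cpp_gru_nll(model$params, seqs, model$vocab$pad)
}

#' Next-token probability distributions along a prefix
#'
#' @param model A [gru_lm()].
#' @param smiles A SMILES prefix (BOS is prepended automatically).
#' @return Matrix (positions x vocabulary) of probabilities; each row
#'   sums to 1.
#' @export
next_token_probs <- function(model, smiles) {
  toks <- smiles_tokenize(smiles)
  idx <- c(model$vocab$bos, match(toks, model$vocab$tokens))
  if (anyNA(idx)) stop("prefix contains out-of-vocabulary tokens")
  p <- .cpp_gru_probs(model$params, as.integer(idx))
  colnames(p) <- model$vocab$tokens
  p
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration and vocabulary alongside the
#' weights, so a loaded model samples identically.
#'
#' @param model A [gru_lm()].
#' @param path File path.
#' @return `save_lm` the path, invisibly; `load_lm` the model.
#' @export
save_lm <- function(model, path) {
  stopifnot(inherits(model, "gru_lm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lm
#' @export
load_lm <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gru_lm"))
  model
}

#' Write the training history as CSV (step, loss, lr, phase, valid128)
#' @param model A trained [gru_lm()].
#' @param path Output path.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
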