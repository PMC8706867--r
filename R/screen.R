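# Descriptor-based binary classification of candidate molecules: the
# confusion-matrix metric suite (Acc/Spe/Sen/MCC/Random Acc/AUC), five
# classical classifiers behind one interface, the stratified 6:4
# train/validation protocol with repeats, k-fold cross-validation, and
# retrospective recall of held-out actives.

#' Confusion matrix constructor
#'
#' @param tp,fp,fn,tn Non-negative counts: true/false positives,
#'   false negatives, true negatives.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

.cm_from_pred <- function(truth, pred) {
  confusion_matrix(
    tp = sum(truth == "positive" & pred == "positive"),
    fp = sum(truth == "negative" & pred == "positive"),
    fn = sum(truth == "positive" & pred == "negative"),
    tn = sum(truth == "negative" & pred == "negative")
  )
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, specificity, sensitivity, the Matthews correlation
#' coefficient, and random accuracy -- the expected accuracy of a
#' predictor that matches the observed class and prediction marginals
#' by chance (the expected-agreement term of Cohen's kappa):
#' `[(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / total^2`.
#'
#' Metrics with a zero denominator are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return list with `acc`, `spe`, `sen`, `mcc`, `random_acc`.
#' @examples
#' metrics_from_cm(confusion_matrix(102, 49, 42, 451))
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = (tp + tn) / total,
    spe = div(tn, tn + fp),
    sen = div(tp, tp + fn),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    random_acc = ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  )
}

.methods_all <- c("svm", "knn", "gnb", "rf", "lr")

#' Stratified train/validation split
#'
#' Random 6:4 split within each class.
#'
#' @param labels Factor with levels `negative`, `positive`.
#' @param train_frac Training fraction (default 0.6).
#' @param seed Integer seed.
#' @return list with integer index vectors `train` and `validation`,
#'   disjoint and covering all samples.
#' @export
stratified_split <- function(labels, train_frac = 0.6, seed = 1L) {
  stopifnot(is.factor(labels), train_frac > 0, train_frac < 1)
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_tr <- round(length(idx) * train_frac)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

# fit one method and return positive-class scores for newdata
.fit_predict <- function(method, Xtr, ytr, Xte, seed) {
  set.seed(seed)
  pos <- "positive"
  switch(method,
    svm = {
      fit <- e1071::svm(x = Xtr, y = ytr, kernel = "radial", cost = 1,
                        gamma = 1 / ncol(Xtr), probability = TRUE)
      pr <- stats::predict(fit, Xte, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    knn = {
      mu <- colMeans(Xtr); sd <- apply(Xtr, 2, stats::sd)
      sd[sd == 0] <- 1
      Ztr <- scale(Xtr, mu, sd); Zte <- scale(Xte, mu, sd)
      pr <- class::knn(Ztr, Zte, ytr, k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    gnb = {
      fit <- e1071::naiveBayes(x = as.data.frame(Xtr), y = ytr)
      stats::predict(fit, as.data.frame(Xte), type = "raw")[, pos]
    },
    rf = {
      fit <- randomForest::randomForest(x = Xtr, y = ytr)
      stats::predict(fit, Xte, type = "prob")[, pos]
    },
    lr = {
      # L1-penalized logistic regression; inverse regularization
      # strength C = 0.5 maps to lambda = 1 / (C * n)
      fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                            lambda = 1 / (0.5 * nrow(Xtr)),
                            standardize = TRUE, maxit = 200000L)
      as.numeric(stats::predict(fit, Xte, type = "response"))
    },
    stop("unknown method: ", method)
  )
}

.report_one <- function(method, split_name, truth, score) {
  pred <- factor(ifelse(score >= 0.5, "positive", "negative"),
                 levels = c("negative", "positive"))
  cm <- .cm_from_pred(truth, pred)
  m <- metrics_from_cm(cm)
  auc <- if (nlevels(droplevels(truth)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                   levels = c("negative", "positive"),
                                   direction = "<")))
  } else NA_real_
  data.frame(method = method, split = split_name, auc = auc,
             mcc = m$mcc, acc = m$acc, spe = m$spe, sen = m$sen,
             random_acc = m$random_acc, tp = cm$tp, fp = cm$fp,
             fn = cm$fn, tn = cm$tn, stringsAsFactors = FALSE)
}

.descriptor_matrix <- function(table) {
  nm <- descriptor_names()
  miss <- setdiff(nm, names(table))
  if (length(miss)) {
    stop("descriptor table lacks registry columns: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  X <- as.matrix(table[, nm])
  X[is.na(X)] <- 0   # undefined fragment counts default to 0
  X
}

#' Fit classifiers on a labeled descriptor table
#'
#' Trains each requested method on the training indices and evaluates
#' on both training and validation indices, returning one metric row
#' per method per split.  Hyperparameters are fixed: SVM with an RBF
#' kernel, cost 1 and gamma `1/n_features`; L1-penalized logistic
#' regression at inverse regularization strength 0.5; defaults
#' elsewhere.
#'
#' @param table Descriptor data.frame containing the 200 registry
#'   columns (extra columns such as `id`/`smiles` are ignored).
#' @param labels Factor with levels `negative`, `positive`.
#' @param split A list with `train` and `validation` index vectors,
#'   e.g. from [stratified_split()].
#' @param methods Subset of `c("svm", "knn", "gnb", "rf", "lr")`.
#' @param seed Integer seed (controls any stochastic fitting step).
#' @return data.frame of reports (one row per method x split).
#' @export
fit_classifiers <- function(table, labels, split,
                            methods = .methods_all, seed = 1L) {
  stopifnot(is.factor(labels), all(methods %in% .methods_all),
            length(methods) >= 1L)
  X <- .descriptor_matrix(table)
  stopifnot(nrow(X) == length(labels))
  tr <- split$train; te <- split$validation
  if (nlevels(droplevels(labels[tr])) < 2L) {
    stop("training split contains a single class")
  }
  out <- list()
  for (m in methods) {
    sc_tr <- .fit_predict(m, X[tr, , drop = FALSE], labels[tr],
                          X[tr, , drop = FALSE], seed)
    sc_te <- .fit_predict(m, X[tr, , drop = FALSE], labels[tr],
                          X[te, , drop = FALSE], seed)
    out[[length(out) + 1L]] <- .report_one(m, "train", labels[tr], sc_tr)
    out[[length(out) + 1L]] <- .report_one(m, "validation", labels[te],
                                           sc_te)
  }
  do.call(rbind, out)
}

#' Repeat the 6:4 protocol and aggregate
#'
#' Runs [stratified_split()] + [fit_classifiers()] `n_repeats` times
#' with derived seeds and reports mean and standard deviation of each
#' metric per method and split.
#'
#' @inheritParams fit_classifiers
#' @param n_repeats Number of random splits (the conventional 10).
#' @return list with `runs` (all rows) and `summary` (mean/sd).
#' @export
repeat_classifiers <- function(table, labels, methods = .methods_all,
                               n_repeats = 10L, seed = 1L) {
  runs <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    sp <- stratified_split(labels, seed = seed + r)
    cbind(repeat_id = r,
          fit_classifiers(table, labels, sp, methods, seed = seed + r))
  }))
  metrics <- c("auc", "mcc", "acc", "spe", "sen", "random_acc")
  summary <- do.call(rbind, lapply(split(runs,
                                         list(runs$method, runs$split),
                                         drop = TRUE), function(d) {
    row <- data.frame(method = d$method[1], split = d$split[1])
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Stratified k-fold cross-validation
#'
#' @inheritParams fit_classifiers
#' @param k Number of folds (2 <= k <= n).
#' @return list with `folds` (per-fold reports on the held-out fold)
#'   and `summary` (mean/sd per metric per method).
#' @export
cross_validate <- function(table, labels, k = 5L,
                           methods = .methods_all, seed = 1L) {
  n <- length(labels)
  stopifnot(k >= 2L)
  if (k > n) stop("k = ", k, " exceeds sample size ", n)
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  rows <- list()
  X_ok <- .descriptor_matrix(table)  # validate columns early
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (nlevels(droplevels(labels[tr])) < 2L) {
      stop("fold ", f, " leaves a single-class training set; reduce k")
    }
    sp <- list(train = tr, validation = te)
    rep <- fit_classifiers(table, labels, sp, methods, seed = seed + f)
    rep <- rep[rep$split == "validation", , drop = FALSE]
    rep$split <- NULL
    rows[[f]] <- cbind(fold = f, rep)
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auc", "mcc", "acc", "spe", "sen", "random_acc")
  summary <- do.call(rbind, lapply(split(folds, folds$method),
                                   function(d) {
    row <- data.frame(method = d$method[1])
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row
  }))
  rownames(summary) <- NULL
  list(folds = folds, summary = summary)
}

#' Retrospective recall of held-out actives
#'
#' Fraction of held-out positives whose canonical string appears among
#' the generated strings -- optionally restricted to those generated
#' strings a classifier predicted positive (the usual screening gate).
#' Recall is monotone non-decreasing as the generated list grows.
#'
#' @param generated Character vector of canonical SMILES sampled from
#'   the generator.
#' @param held_out_positives Character vector of canonical SMILES of
#'   known actives never shown to the model (nonempty).
#' @param predicted_positive Optional logical vector along `generated`;
#'   when given, only generated strings flagged `TRUE` count.
#' @return Recall ratio in [0, 1].
#' @export
retrospective_recall <- function(generated, held_out_positives,
                                 predicted_positive = NULL) {
  if (length(held_out_positives) == 0L) {
    stop("empty held-out positive set")
  }
  if (!is.null(predicted_positive)) {
    stopifnot(length(predicted_positive) == length(generated))
    generated <- generated[predicted_positive]
  }
  mean(held_out_positives %in% generated)
}
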