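# Chemical-space analysis: the seven-property vector (graph.R) embedded
# in two dimensions with t-SNE, plus a quantitative overlap report
# between generated molecules and known actives.
#
# The embedding is an exact (dense) t-SNE: Gaussian input affinities
# calibrated per point to a target perplexity by binary search, Student-t
# output kernel, gradient descent with momentum and early exaggeration.
# Dense t-SNE is quadratic in n, which is fine at library-analysis
# scale (thousands of molecules).

#' Exact t-SNE embedding of a feature matrix
#'
#' @param X Numeric matrix (n x p), already standardized if the columns
#'   live on different scales.
#' @param seed Integer seed (initialisation is the only stochastic
#'   step, so the same seed gives the same embedding).
#' @param perplexity Target perplexity; must be < n.
#' @param max_iter Gradient-descent iterations.
#' @param learning_rate Step size.
#' @return n x 2 matrix of coordinates.
#' @export
tsne_embed <- function(X, seed = 1L, perplexity = 30,
                       max_iter = 500L, learning_rate = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows to embed")
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be smaller than n (", n, ")")
  }
  D2 <- as.matrix(stats::dist(X))^2

  # per-point precision by binary search on entropy
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sump
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {        # too flat: increase precision
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration <- 12
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed molecule sets in chemical space
#'
#' Builds the seven-property vector per molecule, z-scores each
#' property over the pooled sets, and embeds with t-SNE.  The returned
#' object keeps the standardized property matrix alongside the 2-D
#' coordinates so that overlap statistics can be computed in property
#' space (where they are meaningful) rather than embedded space.
#'
#' @param smiles Character vector of valid SMILES (all sets pooled).
#' @param set Character vector of set tags along `smiles`, e.g.
#'   `"generated"`, `"known_train"`, `"known_test"`.
#' @param seed,perplexity,max_iter Passed to [tsne_embed()].
#' @return A `chemspace_embedding`: data.frame with `id`, `set`, `x`,
#'   `y` plus attributes `properties` (standardized matrix) and
#'   `raw_properties`.
#' @export
chemspace_embed <- function(smiles, set, seed = 1L, perplexity = 30,
                            max_iter = 500L) {
  stopifnot(length(smiles) == length(set), length(smiles) >= 3L)
  props <- property_vector(smiles)
  Z <- scale(as.matrix(props))
  Z[, attr(Z, "scaled:scale") == 0] <- 0   # constant property: no signal
  Y <- tsne_embed(Z, seed = seed, perplexity = perplexity,
                  max_iter = max_iter)
  out <- data.frame(id = seq_along(smiles), set = set,
                    x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
  attr(out, "properties") <- Z
  attr(out, "raw_properties") <- props
  class(out) <- c("chemspace_embedding", "data.frame")
  out
}

#' Chemical-space overlap report
#'
#' Quantifies how much the generated set overlaps the known sets: the
#' fraction of generated molecules whose k nearest neighbours in
#' standardized property space include at least one known molecule,
#' plus per-set property means and standard deviations.  Neighbourhoods
#' are computed in property space, not in the embedded plane, so the
#' number does not depend on t-SNE's layout.
#'
#' @param embedding A [chemspace_embed()] result containing a
#'   `"generated"` tag and at least one other (known) tag, each
#'   nonempty.
#' @param k Neighbourhood size.
#' @return list with `overlap_fraction`, `k`, and `property_summary`
#'   (per set x property mean/sd).
#' @export
overlap_report <- function(embedding, k = 5L) {
  stopifnot(inherits(embedding, "chemspace_embedding"))
  set <- embedding$set
  gen <- which(set == "generated")
  known <- which(set != "generated")
  if (length(gen) == 0L) stop("no rows tagged 'generated'")
  if (length(known) == 0L) stop("no rows with a known-set tag")
  Z <- attr(embedding, "properties")
  D <- as.matrix(stats::dist(Z))
  hit <- vapply(gen, function(i) {
    nb <- order(D[i, -i])[seq_len(min(k, nrow(Z) - 1L))]
    nb <- setdiff(seq_len(nrow(Z)), i)[nb]
    any(set[nb] != "generated")
  }, logical(1))
  raw <- attr(embedding, "raw_properties")
  summ <- do.call(rbind, lapply(unique(set), function(s) {
    rows <- raw[set == s, , drop = FALSE]
    data.frame(set = s, property = names(rows),
               mean = vapply(rows, mean, numeric(1)),
               sd = vapply(rows, stats::sd, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(overlap_fraction = mean(hit), k = as.integer(k),
       property_summary = summ)
}
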