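# Seeded synthetic-data generators for every pipeline stage: a toy
# SMILES corpus built by molecular graph assembly (valid by
# construction, then canonicalized), a property-biased focused set for
# transfer-learning experiments, a two-class descriptor dataset with
# controllable separability, and toy protein/ligand pose sets with
# known ground-truth contacts.

#' Corpus generator specification
#'
#' @param n Number of unique molecules to generate.
#' @param seed Integer seed; the same spec always yields the same
#'   corpus.
#' @param rings,branches,halogens,charges,stereo Feature flags
#'   controlling the grammar richness of the corpus.
#' @param heavy_range Inclusive heavy-atom count range per molecule.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n, seed = 1L, rings = TRUE, branches = TRUE,
                        halogens = TRUE, charges = TRUE, stereo = TRUE,
                        heavy_range = c(10L, 16L)) {
  stopifnot(n >= 1L, length(heavy_range) == 2L,
            heavy_range[1] >= 1L, heavy_range[2] >= heavy_range[1])
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 rings = rings, branches = branches, halogens = halogens,
                 charges = charges, stereo = stereo,
                 heavy_range = as.integer(heavy_range)),
            class = "corpus_spec")
}

# -- molecule assembly ------------------------------------------------
# A molecule is built as an atom/bond graph under explicit valence
# bookkeeping and only then serialized to SMILES, so every emitted
# string is grammatically and chemically valid by construction.

.assemble_molecule <- function(spec, p_arom = 0.45, p_ali_ring = 0.25) {
  target <- sample(spec$heavy_range[1]:spec$heavy_range[2], 1L)
  el <- "C"; arom <- FALSE; chg <- 0L; stereo <- ""
  free <- 4L                         # remaining valence per atom
  b1 <- integer(0); b2 <- integer(0); bord <- integer(0)
  barom <- logical(0)

  add_atom <- function(e, aromatic = FALSE, charge = 0L, valence = NULL) {
    el <<- c(el, e); arom <<- c(arom, aromatic); chg <<- c(chg, charge)
    stereo <<- c(stereo, "")
    v <- if (!is.null(valence)) valence else
      switch(e, C = 4L, N = 3L, O = 2L, S = 2L, 1L)
    free <<- c(free, v)
    length(el)
  }
  add_bond <- function(x, y, order = 1L, aromatic = FALSE) {
    b1 <<- c(b1, x); b2 <<- c(b2, y); bord <<- c(bord, order)
    barom <<- c(barom, aromatic)
    use <- if (aromatic) 1L else order
    free[x] <<- free[x] - use
    free[y] <<- free[y] - use
  }

  attach_aromatic_ring <- function() {
    host <- which(free >= 1L & !arom)
    if (!length(host)) return(FALSE)
    host <- if (length(host) == 1L) host else sample(host, 1L)
    with_n <- runif(1) < 0.35
    ring <- integer(6)
    for (k in 1:6) {
      e <- if (with_n && k == 1L) "N" else "C"
      # aromatic ring atom: 2 ring bonds (1 each) + possibly 1 substituent
      ring[k] <- add_atom(e, aromatic = TRUE,
                          valence = if (e == "N") 2L else 3L)
    }
    for (k in 1:6) add_bond(ring[k], ring[k %% 6 + 1L], aromatic = TRUE)
    add_bond(host, ring[1L + (with_n)], 1L)   # never substitute the N
    TRUE
  }
  attach_aliphatic_ring <- function() {
    host <- which(free >= 1L & !arom)
    if (!length(host)) return(FALSE)
    host <- if (length(host) == 1L) host else sample(host, 1L)
    size <- sample(5:6, 1L)
    ring <- vapply(seq_len(size), function(k) add_atom("C"), integer(1))
    for (k in seq_len(size)) add_bond(ring[k], ring[k %% size + 1L])
    add_bond(host, ring[1], 1L)
    TRUE
  }

  while (length(el) < target) {
    room <- target - length(el)
    if (spec$rings && room >= 7L && runif(1) < p_arom) {
      if (attach_aromatic_ring()) next
    }
    if (spec$rings && room >= 6L && runif(1) < p_ali_ring) {
      if (attach_aliphatic_ring()) next
    }
    host <- which(free >= 1L)
    if (!length(host)) break
    # uniform host choice branches; always extending the newest atom
    # with free valence yields unbranched chains
    host <- if (spec$branches && length(host) > 1L) sample(host, 1L)
            else host[length(host)]
    e <- sample(c("C", "N", "O"), 1L, prob = c(0.72, 0.14, 0.14))
    a <- add_atom(e)
    # occasional double bond (carbonyl-style when O)
    ord <- if (free[host] >= 2L && free[a] >= 2L && runif(1) < 0.15) 2L
           else 1L
    add_bond(host, a, ord)
  }

  if (spec$halogens && runif(1) < 0.5) {
    host <- which(free >= 1L & el == "C")
    if (length(host)) {
      host <- if (length(host) == 1L) host else sample(host, 1L)
      x <- add_atom(sample(c("F", "Cl", "Br", "I"), 1L,
                           prob = c(0.35, 0.35, 0.2, 0.1)))
      add_bond(host, x)
    }
  }
  if (spec$charges && runif(1) < 0.35) {
    host <- which(free >= 1L & el == "C" & !arom)
    if (length(host)) {
      host <- if (length(host) == 1L) host else sample(host, 1L)
      if (runif(1) < 0.5) {
        a <- add_atom("N", charge = 1L, valence = 1L)  # terminal [NH3+]
      } else {
        a <- add_atom("O", charge = -1L, valence = 1L) # terminal [O-]
      }
      add_bond(host, a)
    }
  }
  if (spec$stereo) {
    # a carbon with >= 3 heavy neighbours and one implicit H
    deg <- tabulate(c(b1, b2), nbins = length(el))
    cand <- which(el == "C" & !arom & deg == 3L & free >= 1L & chg == 0L)
    if (length(cand) && runif(1) < 0.6) {
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      stereo[pick] <- sample(c("@", "@@"), 1L)
    }
  }
  list(el = el, arom = arom, chg = chg, stereo = stereo,
       bonds = data.frame(a1 = b1, a2 = b2, order = bord,
                          aromatic = barom))
}

# serialize the assembled graph to SMILES by DFS with ring-closure
# digits
.write_smiles <- function(m) {
  n <- length(m$el)
  bonds <- m$bonds
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- integer(0)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], i)
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], i)
  }
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  hcount <- integer(n)
  used <- vapply(seq_len(n), function(a) {
    idx <- adj[[a]]
    sum(ifelse(bonds$aromatic[idx], 1L, bonds$order[idx]))
  }, integer(1))

  atom_token <- function(a) {
    e <- m$el[a]
    sym <- if (m$arom[a]) tolower(e) else e
    base_val <- switch(e, C = 4L, N = 3L, O = 2L, S = 2L, 1L)
    if (m$chg[a] != 0L || nzchar(m$stereo[a])) {
      val <- base_val + (if (m$chg[a] > 0L) m$chg[a] else -abs(m$chg[a]))
      hh <- max(val - used[a], 0L)
      chg_s <- if (m$chg[a] > 0L) {
        if (m$chg[a] == 1L) "+" else paste0("+", m$chg[a])
      } else if (m$chg[a] < 0L) {
        if (m$chg[a] == -1L) "-" else paste0("-", abs(m$chg[a]))
      } else ""
      h_s <- if (hh == 0L) "" else if (hh == 1L) "H" else paste0("H", hh)
      paste0("[", sym, m$stereo[a], h_s, chg_s, "]")
    } else {
      sym
    }
  }
  bond_token <- function(i) {
    if (bonds$aromatic[i]) "" else switch(bonds$order[i], "", "=", "#")
  }

  visited <- logical(n)
  ring_digit <- list()       # bond index -> digit
  next_digit <- 0L
  digit_pool <- integer(0)
  opened <- character(n)     # ring-closure digits to print after atom

  # find non-tree (ring-closure) bonds via DFS
  closure <- logical(nrow(bonds))
  parent_bond <- integer(n)
  order_visit <- integer(0)
  dfs_mark <- function(a, frombond) {
    visited[a] <<- TRUE
    parent_bond[a] <<- frombond
    for (i in adj[[a]]) {
      if (i == frombond) next
      w <- if (bonds$a1[i] == a) bonds$a2[i] else bonds$a1[i]
      if (visited[w]) {
        if (!closure[i] && !identical(parent_bond[w], i)) closure[i] <<- TRUE
      } else {
        dfs_mark(w, i)
      }
    }
  }
  old <- options(expressions = 500000L); on.exit(options(old))
  comp_roots <- c()
  for (a in seq_len(n)) if (!visited[a]) { comp_roots <- c(comp_roots, a)
    dfs_mark(a, 0L) }

  # assign digits to closure bonds
  digits_of <- new.env(parent = emptyenv())
  pending <- vector("list", n)
  for (a in seq_len(n)) pending[[a]] <- character(0)
  digit_count <- 0L
  for (i in which(closure)) {
    digit_count <- digit_count + 1L
    d <- if (digit_count <= 9L) as.character(digit_count)
         else paste0("%", digit_count)
    pending[[bonds$a1[i]]] <- c(pending[[bonds$a1[i]]], d)
    pending[[bonds$a2[i]]] <- c(pending[[bonds$a2[i]]], d)
  }

  visited2 <- logical(n)
  emit <- function(a, frombond) {
    visited2[a] <<- TRUE
    s <- paste0(atom_token(a), paste(pending[[a]], collapse = ""))
    kids <- character(0)
    for (i in adj[[a]]) {
      if (i == frombond || closure[i]) next
      w <- if (bonds$a1[i] == a) bonds$a2[i] else bonds$a1[i]
      if (visited2[w]) next
      kids <- c(kids, paste0(bond_token(i), emit(w, i)))
    }
    if (length(kids) > 1L) {
      s <- paste0(s, paste0("(", kids[-length(kids)], ")", collapse = ""),
                  kids[length(kids)])
    } else if (length(kids) == 1L) {
      s <- paste0(s, kids)
    }
    s
  }
  paste(vapply(comp_roots, function(r) emit(r, 0L), character(1)),
        collapse = ".")
}

#' Generate a synthetic SMILES corpus
#'
#' Molecules are assembled as atom/bond graphs under explicit valence
#' bookkeeping (chains, branches, aromatic and aliphatic rings,
#' halogens, charged terminal groups, stereo centres per the spec's
#' flags), serialized to SMILES, checked by the strict parser and
#' canonicalized.  The result is `n` unique canonical strings; the
#' generator never emits an invalid string.
#'
#' @param spec A [corpus_spec()].
#' @param p_arom,p_ali_ring Ring-attachment probabilities (the focused
#'   generator raises `p_arom`).
#' @return data.frame in [smiles_records()] layout.
#' @export
gen_corpus <- function(spec, p_arom = 0.45, p_ali_ring = 0.25) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (!spec$rings) { p_arom <- 0; p_ali_ring <- 0 }
  set.seed(spec$seed)
  seen <- character(0)
  raws <- character(0)
  attempts <- 0L
  max_attempts <- 30L * spec$n + 1000L
  while (length(seen) < spec$n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not generate ", spec$n, " unique molecules in ",
           max_attempts, " attempts; relax the spec")
    }
    m <- .assemble_molecule(spec, p_arom, p_ali_ring)
    s <- .write_smiles(m)
    parsed <- smiles_parse(s)
    if (!parsed$valid) {
      stop("internal error: assembled molecule failed validation: ", s,
           " (", parsed$reason, ")")
    }
    if (!(s %in% raws)) raws <- c(raws, s)
    seen <- raws
  }
  in_range <- function(r) {
    r[r$is_valid & r$heavy_atoms >= spec$heavy_range[1] &
        r$heavy_atoms <= spec$heavy_range[2], , drop = FALSE]
  }
  rec <- in_range(smiles_records(raws))
  rec <- rec[!duplicated(rec$canonical), , drop = FALSE]
  while (nrow(rec) < spec$n) {
    extra <- character(0)
    need <- spec$n - nrow(rec)
    for (k in seq_len(3L * need)) {
      m <- .assemble_molecule(spec, p_arom, p_ali_ring)
      extra <- c(extra, .write_smiles(m))
    }
    re <- in_range(smiles_records(unique(extra)))
    rec <- rbind(rec, re)
    rec <- rec[!duplicated(rec$canonical), , drop = FALSE]
    attempts <- attempts + 3L * need
    if (attempts > max_attempts) {
      stop("could not reach ", spec$n, " unique canonical strings")
    }
  }
  rec <- rec[seq_len(spec$n), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Generate a property-biased focused set
#'
#' Emulates a focused fine-tuning library: generates a candidate pool
#' with generator knobs shifted toward the requested property, then
#' keeps the `n` molecules with the most extreme values.  The achieved
#' bias (focused vs. baseline mean, with a normal-theory 95% CI on the
#' difference) is attached as the `"bias_report"` attribute.
#'
#' @param spec A [corpus_spec()] for the focused set (its `n` is the
#'   focused-set size).
#' @param bias One of the seven property names of [property_vector()].
#' @param direction `"high"` or `"low"`.
#' @param pool_factor Candidate pool size as a multiple of `n`.
#' @return data.frame in [smiles_records()] layout with a
#'   `"bias_report"` attribute.
#' @export
gen_focused <- function(spec, bias = "aromatic_rings",
                        direction = "high", pool_factor = 4L) {
  props <- c("hba", "hbd", "rotatable_bonds", "aromatic_rings",
             "aliphatic_rings", "heteroatoms", "mol_weight")
  if (!bias %in% props) {
    stop("bias must be one of: ", paste(props, collapse = ", "))
  }
  stopifnot(direction %in% c("high", "low"))
  pool_spec <- spec
  pool_spec$n <- as.integer(spec$n * pool_factor)
  p_arom <- if (bias == "aromatic_rings" && direction == "high") 0.9
            else 0.45
  p_ali <- if (bias == "aliphatic_rings" && direction == "high") 0.9
           else 0.25
  pool <- gen_corpus(pool_spec, p_arom = p_arom, p_ali_ring = p_ali)
  pv <- property_vector(pool$canonical)[[bias]]
  ord <- order(pv, decreasing = (direction == "high"))
  keep <- ord[seq_len(spec$n)]
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL

  base_spec <- spec
  base_spec$n <- spec$n
  base_spec$seed <- spec$seed + 10000L
  baseline <- gen_corpus(base_spec)
  bv <- property_vector(baseline$canonical)[[bias]]
  fv <- pv[keep]
  se <- sqrt(stats::var(fv) / length(fv) + stats::var(bv) / length(bv))
  diff <- mean(fv) - mean(bv)
  attr(out, "bias_report") <- list(
    bias = bias, direction = direction,
    focused_mean = mean(fv), baseline_mean = mean(bv),
    difference = diff,
    ci95 = c(diff - 1.96 * se, diff + 1.96 * se)
  )
  out
}

#' Labeled two-class descriptor dataset specification
#'
#' @param n_pos,n_neg Class sizes.
#' @param effect_size Class-mean separation on informative columns, in
#'   units of the within-class standard deviation; 0 makes the classes
#'   statistically indistinguishable.
#' @param n_informative Number of informative descriptor columns
#'   (<= 200).
#' @param seed Integer seed.
#' @return A `labeled_spec` list.
#' @export
labeled_spec <- function(n_pos, n_neg, effect_size = 2,
                         n_informative = 20L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, effect_size >= 0,
            n_informative >= 1L, n_informative <= 200L)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect_size = effect_size,
                 n_informative = as.integer(n_informative),
                 seed = as.integer(seed)),
            class = "labeled_spec")
}

#' Generate a separable two-class descriptor dataset
#'
#' Two Gaussian clusters over the 200-column descriptor layout: the
#' first `n_informative` registry columns differ between classes by
#' `effect_size` standard deviations; all other columns are
#' uninformative unit-variance noise.
#'
#' @param spec A [labeled_spec()].
#' @return list with `descriptors` (data.frame, 200 registry columns),
#'   `labels` (factor, levels `negative`/`positive`) and `informative`
#'   (the informative column names).
#' @export
gen_labeled <- function(spec) {
  stopifnot(inherits(spec, "labeled_spec"))
  set.seed(spec$seed)
  nm <- descriptor_names()
  n <- spec$n_pos + spec$n_neg
  X <- matrix(stats::rnorm(n * length(nm)), n, length(nm))
  colnames(X) <- nm
  info <- nm[seq_len(spec$n_informative)]
  shift <- spec$effect_size / 2
  X[seq_len(spec$n_pos), info] <- X[seq_len(spec$n_pos), info] + shift
  X[spec$n_pos + seq_len(spec$n_neg), info] <-
    X[spec$n_pos + seq_len(spec$n_neg), info] - shift
  labels <- factor(rep(c("positive", "negative"),
                       c(spec$n_pos, spec$n_neg)),
                   levels = c("negative", "positive"))
  list(descriptors = as.data.frame(X), labels = labels,
       informative = info)
}

#' Generate a toy protein/ligand pose set with known contacts
#'
#' Residues (four pseudo-atoms each) are laid out along the x axis at
#' `spacing` angstroms; each ligand (three atoms) is placed
#' perpendicular to the axis at a controlled minimum distance from its
#' target residue, so the ground-truth contact set at a given cutoff is
#' known by construction and recorded in the `"ground_truth"`
#' attribute.
#'
#' @param n_residues Number of residues.
#' @param placements data.frame with columns `residue` (index) and
#'   `distance` (min heavy-atom distance, angstrom); one ligand per
#'   row.
#' @param seed Integer seed (residue jitter and ligand geometry).
#' @param spacing Residue spacing along the axis.
#' @return A `pose_set`: list with `protein` (data.frame: chain, resno,
#'   resname, elety, x, y, z) and `ligands` (named list of coordinate
#'   matrices), plus the ground-truth attribute.
#' @export
gen_complex <- function(n_residues, placements, seed = 1L,
                        spacing = 8) {
  stopifnot(n_residues >= 1L, is.data.frame(placements),
            all(c("residue", "distance") %in% names(placements)),
            all(placements$residue >= 1L),
            all(placements$residue <= n_residues))
  set.seed(seed)
  aa <- c("ALA", "VAL", "LEU", "SER", "THR", "TYR", "ARG", "HIS",
          "GLN", "CYS")
  prot <- do.call(rbind, lapply(seq_len(n_residues), function(r) {
    centre <- c((r - 1) * spacing, 0, 0)
    local <- rbind(c(0, 0, 0), c(0.8, 0.4, 0), c(-0.6, 0.5, 0.3),
                   c(0.2, -0.6, -0.4))
    data.frame(chain = "A", resno = r,
               resname = aa[(r - 1L) %% length(aa) + 1L],
               elety = c("N", "CA", "C", "O"),
               x = centre[1] + local[, 1], y = centre[2] + local[, 2],
               z = centre[3] + local[, 3], stringsAsFactors = FALSE)
  }))
  ligands <- list()
  for (i in seq_len(nrow(placements))) {
    r <- placements$residue[i]
    d <- placements$distance[i]
    # nearest residue atom to the ligand tip is the one with max y
    res_atoms <- prot[prot$resno == r, c("x", "y", "z")]
    top <- res_atoms[which.max(res_atoms$y), ]
    tip <- c(top$x, top$y + d, top$z)
    lig <- rbind(tip, tip + c(0.5, 0.7, 0), tip + c(-0.5, 0.9, 0.2))
    rownames(lig) <- NULL
    colnames(lig) <- c("x", "y", "z")
    ligands[[paste0("lig", i)]] <- lig
  }
  ps <- structure(list(protein = prot, ligands = ligands),
                  class = "pose_set")
  # ground truth from the construction record, by plain pairwise
  # distances (the independent oracle for the contacts module)
  gt <- lapply(ligands, function(lig) {
    res <- unique(prot$resno)
    hit <- vapply(res, function(r) {
      ra <- as.matrix(prot[prot$resno == r, c("x", "y", "z")])
      mind <- min(sqrt(outer(rowSums(ra^2), rowSums(lig^2), "+") -
                         2 * ra %*% t(lig)))
      mind
    }, numeric(1))
    names(hit) <- res
    hit
  })
  attr(ps, "ground_truth") <- gt
  ps
}

#' @export
print.pose_set <- function(x, ...) {
  cat("pose set:", length(unique(x$protein$resno)), "residues,",
      length(x$ligands), "ligand poses\n")
  invisible(x)
}
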