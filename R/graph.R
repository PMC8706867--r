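# Graph-level utilities over parsed molecules: ring perception, the
# topological distance matrix, and the seven-property vector used for
# chemical-space analysis.  Everything here is a pure function of the
# molecular graph, so any two SMILES of the same molecule give the same
# values.

# Heavy-atom view of a parsed molecule: drops explicit hydrogens and
# renumbers bonds accordingly.
.heavy_graph <- function(mol) {
  stopifnot(inherits(mol, "smiles_mol"), mol$valid)
  atoms <- mol$atoms
  bonds <- mol$bonds
  heavy <- which(atoms$element != "H")
  map <- match(seq_len(nrow(atoms)), heavy)
  # explicit H attached through a bond adds to the neighbour's H count
  hplus <- integer(nrow(atoms))
  if (nrow(bonds)) {
    isH <- atoms$element == "H"
    for (i in seq_len(nrow(bonds))) {
      if (isH[bonds$a1[i]] && !isH[bonds$a2[i]]) {
        hplus[bonds$a2[i]] <- hplus[bonds$a2[i]] + 1L
      } else if (isH[bonds$a2[i]] && !isH[bonds$a1[i]]) {
        hplus[bonds$a1[i]] <- hplus[bonds$a1[i]] + 1L
      }
    }
    keep <- !isH[bonds$a1] & !isH[bonds$a2]
    bonds <- bonds[keep, , drop = FALSE]
    bonds$a1 <- map[bonds$a1]
    bonds$a2 <- map[bonds$a2]
  }
  atoms <- atoms[heavy, , drop = FALSE]
  atoms$hcount <- atoms$hcount + hplus[heavy]
  rownames(atoms) <- NULL
  n <- nrow(atoms)
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- integer(0)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  list(atoms = atoms, bonds = bonds, n = n, degree = deg, adj = adj)
}

# bond-in-ring flags: a bond lies on a cycle iff its endpoints remain
# connected when it is removed
.ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  out <- logical(nb)
  for (i in seq_len(nb)) {
    a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
    # BFS from a to b avoiding bond i
    seen <- logical(g$n); seen[a] <- TRUE
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (j in seq_len(nb)) {
        if (j == i) next
        w <- if (g$bonds$a1[j] == v) g$bonds$a2[j]
             else if (g$bonds$a2[j] == v) g$bonds$a1[j]
             else next
        if (!seen[w]) {
          if (w == b) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[i] <- found
  }
  out
}

# unweighted topological distance matrix (Inf across components)
.topo_dist <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in g$adj[[v]]) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

.ring_counts <- function(g, ring_bond) {
  comp <- .components_of(g$n, g$bonds$a1, g$bonds$a2)
  n_rings <- nrow(g$bonds) - g$n + length(unique(comp))
  ar_b <- which(g$bonds$aromatic)
  n_ar <- 0L
  if (length(ar_b)) {
    ar_atoms <- sort(unique(c(g$bonds$a1[ar_b], g$bonds$a2[ar_b])))
    sub_a1 <- match(g$bonds$a1[ar_b], ar_atoms)
    sub_a2 <- match(g$bonds$a2[ar_b], ar_atoms)
    sub_comp <- .components_of(length(ar_atoms), sub_a1, sub_a2)
    n_ar <- length(ar_b) - length(ar_atoms) + length(unique(sub_comp))
  }
  list(total = as.integer(n_rings), aromatic = as.integer(n_ar),
       aliphatic = as.integer(n_rings - n_ar))
}

.rotatable_bonds <- function(g, ring_bond) {
  if (nrow(g$bonds) == 0L) return(0L)
  triple_atom <- unique(c(g$bonds$a1[g$bonds$order == 3L],
                          g$bonds$a2[g$bonds$order == 3L]))
  ok <- g$bonds$order == 1L & !g$bonds$aromatic & !ring_bond &
    g$degree[g$bonds$a1] >= 2L & g$degree[g$bonds$a2] >= 2L &
    !(g$bonds$a1 %in% triple_atom) & !(g$bonds$a2 %in% triple_atom)
  sum(ok)
}

#' Seven-property vector for chemical-space analysis
#'
#' Computes, per molecule: Lipinski hydrogen-bond acceptors (N + O
#' count) and donors (N/O bearing at least one hydrogen), rotatable
#' bonds (acyclic single bonds between non-terminal heavy atoms,
#' excluding bonds at triple-bond carbons), aromatic and aliphatic ring
#' counts (cycle-space counts of the aromatic subgraph and its
#' complement), heteroatom count (non-carbon, non-hydrogen) and
#' molecular weight.
#'
#' @param smiles Character vector of valid SMILES.
#' @return data.frame with columns `hba`, `hbd`, `rotatable_bonds`,
#'   `aromatic_rings`, `aliphatic_rings`, `heteroatoms`, `mol_weight`,
#'   one row per input.  Invalid SMILES raise an error naming the
#'   string.
#' @examples
#' property_vector(c("c1ccccc1", "CCO"))
#' @export
property_vector <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    mol <- smiles_parse(s)
    if (!mol$valid) stop("invalid SMILES: ", s, " (", mol$reason, ")")
    g <- .heavy_graph(mol)
    rb <- .ring_bonds(g)
    rc <- .ring_counts(g, rb)
    el <- g$atoms$element
    no <- el %in% c("N", "O")
    data.frame(
      hba = sum(no),
      hbd = sum(no & g$atoms$hcount > 0L),
      rotatable_bonds = .rotatable_bonds(g, rb),
      aromatic_rings = rc$aromatic,
      aliphatic_rings = rc$aliphatic,
      heteroatoms = sum(!el %in% c("C", "H")),
      mol_weight = molecular_weight(mol)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
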