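# A fixed registry of 200 fragmental and topological descriptors
# computed from the molecular graph.  The registry is frozen in
# inst/extdata/descriptor_manifest.csv so descriptor tables are
# reproducible across versions; compute_descriptors() always emits the
# 200 columns in manifest order.  Fragment counts that do not occur in a
# molecule are 0, so no value is ever missing.

.pair_elements <- c("C", "N", "O", "S", "P", "X")  # X = any halogen
.bond_classes <- c("single", "double", "triple", "aromatic")

.registry_build <- function() {
  fam <- function(name, family, description) {
    data.frame(name = name, family = family, description = description,
               stringsAsFactors = FALSE)
  }
  counts <- fam(
    c("n_heavy", "n_bonds", "mol_weight", "net_charge", "n_pos_charge",
      "n_neg_charge", "n_rings", "n_aromatic_rings", "n_aliphatic_rings",
      "n_ring_atoms", "n_ring_bonds", "frac_ring_atoms", "n_rotatable",
      "n_hba", "n_hbd", "n_hetero", "frac_hetero", "n_implicit_h",
      "n_single_bonds", "n_double_bonds", "n_triple_bonds",
      "n_aromatic_bonds", "n_branch_atoms", "n_terminal_atoms",
      "n_stereo_atoms", "mean_degree", "max_degree", "n_components",
      "n_aromatic_atoms", "frac_aromatic"),
    "global", "whole-molecule count or ratio")
  elements <- fam(
    c("n_C", "n_N", "n_O", "n_S", "n_P", "n_F", "n_Cl", "n_Br", "n_I",
      "n_B", "n_halogen", "n_other_element", "n_CH3", "n_quaternary_C"),
    "element", "atom count by element or hydrogen environment")
  degree <- fam(
    c("n_deg2", "n_deg3", "n_deg4", "n_h0_atoms", "n_h1_atoms",
      "n_h2_atoms", "n_h3_atoms"),
    "degree", "atom count by heavy degree / implicit hydrogen count")
  environment <- fam(
    c("n_aromatic_C", "n_aromatic_N", "n_aromatic_O", "n_aromatic_S",
      "n_pyridine_N", "n_pyrrole_N", "n_ring_C", "n_ring_N", "n_ring_O",
      "n_ring_S", "n_ring_substituted", "n_ring_fusion_atoms"),
    "environment", "ring / aromatic atom environment count")
  pairs <- expand.grid(j = seq_along(.pair_elements),
                       i = seq_along(.pair_elements))
  pairs <- pairs[pairs$i <= pairs$j, ]
  pair_names <- sprintf("bond_%s_%s",
                        .pair_elements[pairs$i], .pair_elements[pairs$j])
  bond_pairs <- fam(
    as.vector(vapply(pair_names, function(p) paste(p, .bond_classes,
                                                   sep = "_"),
                     character(4))),
    "bond_pair", "bonded element-pair count by bond class")
  groups <- fam(
    c("fg_carbonyl", "fg_carboxylic_acid", "fg_carboxylate", "fg_ester",
      "fg_amide", "fg_aldehyde", "fg_ketone", "fg_hydroxyl", "fg_phenol",
      "fg_ether", "fg_amine_primary", "fg_amine_secondary",
      "fg_amine_tertiary", "fg_amine_aromatic", "fg_nitrile", "fg_nitro",
      "fg_azo", "fg_imine", "fg_thiol", "fg_thioether", "fg_sulfonyl",
      "fg_sulfonamide", "fg_halide_aromatic", "fg_halide_aliphatic",
      "fg_ammonium", "fg_alkene", "fg_alkyne", "fg_methoxy",
      "fg_trifluoromethyl", "fg_urea"),
    "fragment", "functional group occurrence count")
  topo <- fam(
    c("wiener", "zagreb_m1", "zagreb_m2", "randic_chi1", "chi0", "platt",
      "balaban_j", "graph_radius", "graph_diameter",
      "mean_topo_distance", "kappa1", "kappa2", "paths_len2"),
    "topological", "topological index over the heavy-atom graph")
  distc <- fam(sprintf("n_pairs_dist%d", 2:11),
               "distance", "heavy-atom pairs at given topological distance")
  rbind(counts, elements, degree, environment, bond_pairs, groups, topo,
        distc)
}

.registry_cache <- new.env(parent = emptyenv())

#' The descriptor registry
#'
#' 200 named fragmental and topological descriptors with family tags
#' and one-line definitions.  The same table ships as a manifest file at
#' `system.file("extdata", "descriptor_manifest.csv", package =
#' "molgru")`.
#'
#' @return data.frame with columns `name`, `family`, `description`
#'   (200 rows).
#' @export
descriptor_registry <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- .registry_build()
  .registry_cache$reg
}

#' Descriptor names in table order
#' @return Character vector of length 200.
#' @export
descriptor_names <- function() descriptor_registry()$name

.pair_class_of <- function(el) {
  ifelse(el %in% c("F", "Cl", "Br", "I"), "X",
         ifelse(el %in% .pair_elements, el, NA_character_))
}

# descriptor vector for one parsed molecule
.descriptor_row <- function(mol) {
  g <- .heavy_graph(mol)
  a <- g$atoms; b <- g$bonds
  n <- g$n; deg <- g$degree
  rb <- .ring_bonds(g)
  rc <- .ring_counts(g, rb)
  ring_atom <- rep(FALSE, n)
  if (length(rb)) {
    ring_atom[unique(c(b$a1[rb], b$a2[rb]))] <- TRUE
  }
  ring_deg <- tabulate(c(b$a1[rb], b$a2[rb]), nbins = n)
  el <- a$element
  halogen <- el %in% c("F", "Cl", "Br", "I")
  arom <- a$aromatic
  h <- a$hcount
  D <- .topo_dist(g)
  dvals <- D[upper.tri(D)]
  dfin <- dvals[is.finite(dvals)]
  comp <- .components_of(n, b$a1, b$a2)

  out <- numeric(0)
  add <- function(x) out <<- c(out, as.numeric(x))

  nb <- nrow(b)
  # global
  add(n); add(nb); add(molecular_weight(mol)); add(sum(a$charge))
  add(sum(a$charge > 0)); add(sum(a$charge < 0))
  add(rc$total); add(rc$aromatic); add(rc$aliphatic)
  add(sum(ring_atom)); add(sum(rb)); add(sum(ring_atom) / n)
  add(.rotatable_bonds(g, rb))
  no <- el %in% c("N", "O")
  add(sum(no)); add(sum(no & h > 0L))
  hetero <- !el %in% c("C", "H")
  add(sum(hetero)); add(sum(hetero) / n); add(sum(h))
  add(sum(b$order == 1L & !b$aromatic)); add(sum(b$order == 2L))
  add(sum(b$order == 3L)); add(sum(b$aromatic))
  add(sum(deg >= 3L)); add(sum(deg == 1L)); add(sum(nzchar(a$stereo)))
  add(mean(deg)); add(if (n) max(deg) else 0); add(length(unique(comp)))
  add(sum(arom)); add(sum(arom) / n)
  # element
  for (e in c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")) {
    add(sum(el == e))
  }
  add(sum(halogen))
  add(sum(!el %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                     "H")))
  add(sum(el == "C" & h == 3L)); add(sum(el == "C" & deg == 4L & h == 0L))
  # degree / hydrogen environments
  add(sum(deg == 2L)); add(sum(deg == 3L)); add(sum(deg == 4L))
  add(sum(h == 0L)); add(sum(h == 1L)); add(sum(h == 2L)); add(sum(h == 3L))
  # ring / aromatic environment
  add(sum(arom & el == "C")); add(sum(arom & el == "N"))
  add(sum(arom & el == "O")); add(sum(arom & el == "S"))
  arom_deg <- tabulate(c(b$a1[b$aromatic], b$a2[b$aromatic]), nbins = n)
  conn <- deg + h
  add(sum(arom & el == "N" & conn == 2L))        # pyridine-type
  add(sum(arom & el == "N" & conn == 3L & a$charge == 0L))  # pyrrole-type
  add(sum(ring_atom & el == "C")); add(sum(ring_atom & el == "N"))
  add(sum(ring_atom & el == "O")); add(sum(ring_atom & el == "S"))
  add(sum(ring_atom & deg > ring_deg))   # ring atoms bearing substituents
  add(sum(ring_deg >= 3L))               # fusion / spiro atoms
  # bonded element pairs by bond class
  cls <- .pair_class_of(el)
  for (i in seq_along(.pair_elements)) {
    for (j in i:length(.pair_elements)) {
      e1 <- .pair_elements[i]; e2 <- .pair_elements[j]
      hit <- (cls[b$a1] == e1 & cls[b$a2] == e2) |
        (cls[b$a1] == e2 & cls[b$a2] == e1)
      hit[is.na(hit)] <- FALSE
      add(sum(hit & b$order == 1L & !b$aromatic))
      add(sum(hit & b$order == 2L & !b$aromatic))
      add(sum(hit & b$order == 3L))
      add(sum(hit & b$aromatic))
    }
  }
  # functional groups
  nb_of <- function(atom) g$adj[[atom]]
  bond_between <- function(x, y) {
    which((b$a1 == x & b$a2 == y) | (b$a1 == y & b$a2 == x))
  }
  dbl_O <- function(atom) {
    # neighbours that are =O
    Reduce(c, lapply(nb_of(atom), function(w) {
      i <- bond_between(atom, w)
      if (el[w] == "O" && length(i) && b$order[i] == 2L &&
          !b$aromatic[i]) w else integer(0)
    }), integer(0))
  }
  carbonyl_C <- which(vapply(seq_len(n), function(x) {
    el[x] == "C" && !arom[x] && length(dbl_O(x)) > 0
  }, logical(1)))
  single_nb <- function(atom, elem) {
    Reduce(c, lapply(nb_of(atom), function(w) {
      i <- bond_between(atom, w)
      if (el[w] == elem && length(i) && b$order[i] == 1L &&
          !b$aromatic[i]) w else integer(0)
    }), integer(0))
  }
  n_carboxylic <- sum(vapply(carbonyl_C, function(x) {
    any(vapply(single_nb(x, "O"), function(o) h[o] > 0L, logical(1)))
  }, logical(1)))
  n_carboxylate <- sum(vapply(carbonyl_C, function(x) {
    any(vapply(single_nb(x, "O"), function(o) a$charge[o] < 0L,
               logical(1)))
  }, logical(1)))
  n_ester <- sum(vapply(carbonyl_C, function(x) {
    any(vapply(single_nb(x, "O"), function(o) {
      h[o] == 0L && a$charge[o] == 0L && deg[o] == 2L
    }, logical(1)))
  }, logical(1)))
  amide_N <- unique(Reduce(c, lapply(carbonyl_C, function(x) {
    single_nb(x, "N")
  }), integer(0)))
  n_amide <- sum(vapply(carbonyl_C, function(x) {
    length(single_nb(x, "N")) > 0
  }, logical(1)))
  n_aldehyde <- sum(h[carbonyl_C] > 0L)
  n_ketone <- sum(vapply(carbonyl_C, function(x) {
    h[x] == 0L && sum(el[nb_of(x)] == "C") >= 2L
  }, logical(1)))
  o_atoms <- which(el == "O" & !arom)
  oh <- o_atoms[h[o_atoms] > 0L & a$charge[o_atoms] == 0L]
  n_phenol <- sum(vapply(oh, function(o) {
    any(arom[nb_of(o)])
  }, logical(1)))
  in_carbonyl_O <- unique(Reduce(c, lapply(carbonyl_C, dbl_O), integer(0)))
  n_hydroxyl <- sum(vapply(oh, function(o) {
    nbs <- nb_of(o)
    length(nbs) == 1L && el[nbs] == "C" && !arom[nbs] &&
      !(nbs %in% carbonyl_C)
  }, logical(1)))
  n_ether <- sum(vapply(o_atoms, function(o) {
    deg[o] == 2L && h[o] == 0L && all(el[nb_of(o)] == "C") &&
      !any(nb_of(o) %in% carbonyl_C) && !(o %in% in_carbonyl_O)
  }, logical(1)))
  amine_N <- which(el == "N" & !arom & a$charge == 0L)
  amine_N <- setdiff(amine_N, amide_N)
  amine_N <- amine_N[vapply(amine_N, function(x) {
    i <- c(which(b$a1 == x), which(b$a2 == x))
    all(b$order[i] == 1L & !b$aromatic[i])
  }, logical(1))]
  n_primary <- sum(deg[amine_N] == 1L & h[amine_N] == 2L)
  n_secondary <- sum(deg[amine_N] == 2L & h[amine_N] == 1L)
  n_tertiary <- sum(deg[amine_N] == 3L & h[amine_N] == 0L)
  n_arom_amine <- sum(vapply(amine_N, function(x) {
    any(arom[nb_of(x)])
  }, logical(1)))
  n_nitrile <- sum(b$order == 3L &
                     ((el[b$a1] == "C" & el[b$a2] == "N") |
                        (el[b$a1] == "N" & el[b$a2] == "C")))
  nitro_N <- which(el == "N" & a$charge == 1L)
  n_nitro <- sum(vapply(nitro_N, function(x) {
    length(dbl_O(x)) >= 1L &&
      any(a$charge[single_nb(x, "O")] < 0L)
  }, logical(1)))
  n_azo <- sum(b$order == 2L & !b$aromatic &
                 el[b$a1] == "N" & el[b$a2] == "N")
  n_imine <- sum(b$order == 2L & !b$aromatic &
                   ((el[b$a1] == "C" & el[b$a2] == "N") |
                      (el[b$a1] == "N" & el[b$a2] == "C")))
  s_atoms <- which(el == "S" & !arom)
  n_thiol <- sum(h[s_atoms] > 0L)
  sulfonyl_S <- s_atoms[vapply(s_atoms, function(x) {
    length(dbl_O(x)) >= 2L
  }, logical(1))]
  n_thioether <- sum(vapply(s_atoms, function(x) {
    deg[x] == 2L && h[x] == 0L && length(dbl_O(x)) == 0L
  }, logical(1)))
  n_sulfonamide <- sum(vapply(sulfonyl_S, function(x) {
    length(single_nb(x, "N")) > 0L
  }, logical(1)))
  xa <- which(halogen)
  n_hal_ar <- sum(vapply(xa, function(x) any(arom[nb_of(x)]), logical(1)))
  n_hal_al <- length(xa) - n_hal_ar
  n_ammonium <- sum(el == "N" & a$charge > 0L & !arom)
  n_alkene <- sum(b$order == 2L & !b$aromatic &
                    el[b$a1] == "C" & el[b$a2] == "C")
  n_alkyne <- sum(b$order == 3L & el[b$a1] == "C" & el[b$a2] == "C")
  n_methoxy <- sum(vapply(o_atoms, function(o) {
    nbs <- nb_of(o)
    deg[o] == 2L && any(el[nbs] == "C" & h[nbs] == 3L)
  }, logical(1)))
  n_cf3 <- sum(vapply(which(el == "C"), function(x) {
    sum(el[nb_of(x)] == "F") >= 3L
  }, logical(1)))
  n_urea <- sum(vapply(carbonyl_C, function(x) {
    length(single_nb(x, "N")) >= 2L
  }, logical(1)))
  for (v in c(length(carbonyl_C), n_carboxylic, n_carboxylate, n_ester,
              n_amide, n_aldehyde, n_ketone, n_hydroxyl, n_phenol,
              n_ether, n_primary, n_secondary, n_tertiary, n_arom_amine,
              n_nitrile, n_nitro, n_azo, n_imine, n_thiol, n_thioether,
              length(sulfonyl_S), n_sulfonamide, n_hal_ar, n_hal_al,
              n_ammonium, n_alkene, n_alkyne, n_methoxy, n_cf3, n_urea)) {
    add(v)
  }
  # topological indices
  wiener <- sum(dfin)
  add(wiener)
  add(sum(deg^2)); add(sum(deg[b$a1] * deg[b$a2]))
  add(sum(1 / sqrt(pmax(deg[b$a1] * deg[b$a2], 1))))
  add(sum(1 / sqrt(pmax(deg, 1))))
  add(sum(deg[b$a1] + deg[b$a2] - 2))
  gamma <- nb - n + length(unique(comp))
  if (nb > 0) {
    s <- rowSums(ifelse(is.finite(D), D, 0))
    bj <- nb / (gamma + 1) *
      sum(1 / sqrt(pmax(s[b$a1] * s[b$a2], 1)))
  } else bj <- 0
  add(bj)
  ecc <- apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) max(f) else 0
  })
  add(min(ecc)); add(max(ecc))
  add(if (length(dfin)) mean(dfin) else 0)
  p1 <- nb
  p2 <- sum(choose(deg, 2))
  add(if (p1 > 0) n * (n - 1)^2 / p1^2 else 0)
  add(if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0)
  add(p2)
  # distance pair counts
  for (d in 2:11) add(sum(dfin == d))
  out
}

#' Compute the 200-descriptor table
#'
#' One row per unique canonical SMILES string; identical strings always
#' give identical rows.  Unparseable inputs are excluded from the table
#' and reported in the `"rejected"` attribute (id + reason) rather than
#' raising.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional identifiers (defaults to the strings themselves).
#' @return data.frame with columns `id`, `smiles` and the 200 registry
#'   descriptors, plus a `"rejected"` attribute.
#' @export
compute_descriptors <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(ids)) ids <- smiles
  stopifnot(length(ids) == length(smiles))
  nm <- descriptor_names()
  rows <- vector("list", length(smiles))
  rejected <- data.frame(id = character(0), smiles = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(smiles)) {
    mol <- smiles_parse(smiles[i])
    if (!mol$valid) {
      rejected <- rbind(rejected, data.frame(
        id = as.character(ids[i]), smiles = smiles[i],
        reason = mol$reason, stringsAsFactors = FALSE))
      next
    }
    rows[[i]] <- .descriptor_row(mol)
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  if (is.null(mat)) stop("no valid molecules to describe")
  if (ncol(mat) != length(nm)) {
    stop("internal error: descriptor count ", ncol(mat), " != ",
         length(nm))
  }
  colnames(mat) <- nm
  out <- cbind(data.frame(id = as.character(ids[keep]),
                          smiles = smiles[keep],
                          stringsAsFactors = FALSE),
               as.data.frame(mat))
  attr(out, "rejected") <- rejected
  out
}
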