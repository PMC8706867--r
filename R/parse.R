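# Strict SMILES parser and validity checker.
#
# General-purpose SMILES readers in cheminformatics toolkits are tolerant
# by design: they silently repair unmatched parentheses and accept
# hypervalent atoms.  A generative model's validity metric needs the
# opposite: a checker that rejects anything a chemistry-aware parser
# would reject.  This parser enforces the grammar (balanced branches,
# matched ring closures with compatible bond orders, well-formed bracket
# atoms), kekulizes aromatic systems (perfect matching + a 4n+2 pi
# electron count per aromatic component), and checks valences against a
# standard charge-adjusted valence table.

.default_valence <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.atomic_weight <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45,
  Se = 78.971, Br = 79.904, I = 126.904
)

.allowed_valences <- function(element, charge) {
  base <- .default_valence[[element]]
  if (is.null(base)) return(NULL)  # uncommon element: no valence check
  if (charge == 0) return(base)
  if (element == "C") return(max(4 - abs(charge), 0))
  if (charge > 0 && element %in% c("N", "O", "P", "S")) return(base + charge)
  if (charge < 0) return(pmax(base - abs(charge), 0))
  base
}

.parse_bracket <- function(tok) {
  m <- regexec(
    "^\\[([0-9]+)?([A-Z][a-z]?|[bcnops]|\\*)(@@|@)?(H([0-9]*))?(\\+[0-9]+|-[0-9]+|\\++|-+)?\\]$",
    tok)
  g <- regmatches(tok, m)[[1]]
  if (length(g) == 0L) return(NULL)
  sym <- g[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  hcount <- if (g[5] == "") 0L else if (g[6] == "") 1L else as.integer(g[6])
  chg_s <- g[7]
  charge <- if (chg_s == "") {
    0L
  } else if (grepl("^[+-][0-9]+$", chg_s)) {
    as.integer(chg_s)
  } else {
    nchar(chg_s) * (if (substr(chg_s, 1, 1) == "+") 1L else -1L)
  }
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, stereo = g[4],
       isotope = if (g[2] == "") NA_integer_ else as.integer(g[2]))
}

#' Parse a SMILES string into a molecular graph
#'
#' Runs the strict grammar parser, kekulizes aromatic systems and checks
#' valences.  On success returns atom and bond tables with kekulized
#' bond orders and implicit hydrogen counts; on failure returns
#' `valid = FALSE` and the first reason found.  Never raises on
#' malformed input.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `smiles_mol` with elements `valid` (logical),
#'   `reason` (character, `NA` when valid), `atoms` (data.frame: element,
#'   aromatic, charge, hcount, stereo, bracket), `bonds` (data.frame:
#'   a1, a2, order, aromatic), `smiles` (the input).
#' @examples
#' m <- smiles_parse("c1ccccc1O")
#' m$valid
#' sum(m$atoms$element != "H")
#' @export
smiles_parse <- function(smiles) {
  fail <- function(reason) {
    structure(list(valid = FALSE, reason = reason, atoms = NULL,
                   bonds = NULL, smiles = smiles), class = "smiles_mol")
  }
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(fail("empty input"))
  }
  toks <- .try_tokenize(smiles)
  if (is.null(toks)) return(fail("untokenizable characters"))

  el <- character(0); ar <- logical(0); chg <- integer(0)
  hx <- integer(0)   # explicit H (bracket atoms), NA = implicit
  st <- character(0); br <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bsym <- character(0)

  prev <- NA_integer_
  pending <- ""            # pending bond symbol
  stack <- integer(0)
  natoms_at_push <- integer(0)
  rings <- list()          # digit -> list(atom, bond)
  bond_syms <- c("-", "=", "#", ":", "/", "\\")

  add_atom <- function(element, aromatic, charge, hcount, stereo, bracket) {
    el <<- c(el, element); ar <<- c(ar, aromatic); chg <<- c(chg, charge)
    hx <<- c(hx, hcount); st <<- c(st, stereo); br <<- c(br, bracket)
    length(el)
  }
  add_bond <- function(a, b, sym) {
    if (a == b) return("ring bond to self")
    if (any((b1 == a & b2 == b) | (b1 == b & b2 == a))) {
      return("duplicate bond")
    }
    b1 <<- c(b1, a); b2 <<- c(b2, b); bsym <<- c(bsym, sym)
    NULL
  }

  for (tok in toks) {
    if (tok %in% bond_syms) {
      if (is.na(prev)) return(fail("bond with no preceding atom"))
      if (nzchar(pending)) return(fail("two consecutive bond symbols"))
      pending <- tok
    } else if (tok == "(") {
      if (is.na(prev)) return(fail("branch with no preceding atom"))
      if (nzchar(pending)) return(fail("bond before branch open"))
      stack <- c(stack, prev)
      natoms_at_push <- c(natoms_at_push, length(el))
    } else if (tok == ")") {
      if (length(stack) == 0L) return(fail("unmatched closing parenthesis"))
      if (nzchar(pending)) return(fail("dangling bond before branch close"))
      if (length(el) == natoms_at_push[length(natoms_at_push)]) {
        return(fail("empty branch"))
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      natoms_at_push <- natoms_at_push[-length(natoms_at_push)]
    } else if (tok == ".") {
      if (nzchar(pending)) return(fail("bond before dot disconnect"))
      if (is.na(prev)) return(fail("misplaced dot disconnect"))
      prev <- NA_integer_
    } else if (grepl("^[0-9]$", tok) || grepl("^%[0-9]{2}$", tok)) {
      if (is.na(prev)) return(fail("ring closure with no preceding atom"))
      key <- sub("^%", "", tok)
      if (!is.null(rings[[key]])) {
        open <- rings[[key]]
        sym <- if (nzchar(pending)) pending else open$bond
        if (nzchar(pending) && nzchar(open$bond) && pending != open$bond) {
          return(fail("conflicting ring bond orders"))
        }
        err <- add_bond(open$atom, prev, sym)
        if (!is.null(err)) return(fail(err))
        rings[[key]] <- NULL
        pending <- ""
      } else {
        rings[[key]] <- list(atom = prev, bond = pending)
        pending <- ""
      }
    } else {
      # atom token
      if (startsWith(tok, "[")) {
        info <- .parse_bracket(tok)
        if (is.null(info)) return(fail(paste("malformed bracket atom", tok)))
        a <- add_atom(info$element, info$aromatic, info$charge,
                      info$hcount, info$stereo, TRUE)
      } else {
        aromatic <- tok %in% c("b", "c", "n", "o", "s", "p")
        a <- add_atom(if (aromatic) toupper(tok) else tok, aromatic,
                      0L, NA_integer_, "", FALSE)
      }
      if (!is.na(prev)) {
        err <- add_bond(prev, a, pending)
        if (!is.null(err)) return(fail(err))
      }
      pending <- ""
      prev <- a
    }
  }
  if (toks[length(toks)] == ".") return(fail("trailing dot disconnect"))
  if (nzchar(pending)) return(fail("dangling bond at end of string"))
  if (length(stack) > 0L) return(fail("unclosed branch"))
  if (length(rings) > 0L) return(fail("unmatched ring closure"))
  if (length(el) == 0L) return(fail("no atoms"))

  atoms <- data.frame(element = el, aromatic = ar, charge = chg,
                      hcount = hx, stereo = st, bracket = br,
                      stringsAsFactors = FALSE)
  bonds <- if (length(b1)) {
    data.frame(a1 = b1, a2 = b2, sym = bsym, stringsAsFactors = FALSE)
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), sym = character(0))
  }

  # resolve bond orders; aromatic when ':' or both ends aromatic and no
  # symbol given
  n <- nrow(atoms)
  border <- integer(nrow(bonds))
  barom <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    s <- bonds$sym[i]
    if (s == ":") {
      barom[i] <- TRUE
    } else if (s == "" && atoms$aromatic[bonds$a1[i]] &&
               atoms$aromatic[bonds$a2[i]]) {
      barom[i] <- TRUE
    } else {
      border[i] <- switch(s, "=" = 2L, "#" = 3L, 1L)  # -, /, \, "" -> 1
    }
  }
  bonds$order <- border
  bonds$aromatic <- barom

  kek <- .kekulize(atoms, bonds)
  if (!isTRUE(kek$ok)) return(fail(kek$reason))
  bonds$order <- kek$order

  val <- .check_valences(atoms, bonds)
  if (!isTRUE(val$ok)) return(fail(val$reason))
  atoms$hcount <- val$hcount

  structure(list(valid = TRUE, reason = NA_character_, atoms = atoms,
                 bonds = bonds, smiles = smiles), class = "smiles_mol")
}

#' @export
print.smiles_mol <- function(x, ...) {
  if (x$valid) {
    cat("valid SMILES:", x$smiles, "-", nrow(x$atoms), "heavy atoms,",
        nrow(x$bonds), "bonds\n")
  } else {
    cat("invalid SMILES:", x$smiles, "-", x$reason, "\n")
  }
  invisible(x)
}

# Kekulize the aromatic subsystem: every aromatic atom must sit in an
# aromatic ring (>= 2 aromatic bonds); atoms requiring one double bond
# must admit a perfect matching over aromatic bonds; each connected
# aromatic component must carry 4n+2 pi electrons.
.kekulize <- function(atoms, bonds) {
  order <- bonds$order
  ai <- which(atoms$aromatic)
  if (length(ai) == 0L) return(list(ok = TRUE, order = order))
  abm <- which(bonds$aromatic)
  deg_ar <- tabulate(c(bonds$a1[abm], bonds$a2[abm]), nbins = nrow(atoms))
  if (any(deg_ar[ai] < 2L)) {
    return(list(ok = FALSE, reason = "aromatic atom outside aromatic ring"))
  }
  if (any(deg_ar[ai] > 3L)) {
    return(list(ok = FALSE, reason = "aromatic atom with >3 aromatic bonds"))
  }
  conn <- tabulate(c(bonds$a1, bonds$a2), nbins = nrow(atoms))

  needs <- logical(nrow(atoms))   # needs one double bond in kekule form
  pi_e <- numeric(nrow(atoms))
  for (a in ai) {
    e <- atoms$element[a]; ch <- atoms$charge[a]
    hx <- atoms$hcount[a]
    h <- if (is.na(hx)) {
      # implicit H on aromatic organic-subset atom: c with 2 ring bonds
      # gets one, everything else none (resolved exactly after kekulize)
      if (e == "C" && conn[a] == 2L) 1L else 0L
    } else hx
    total_conn <- conn[a] + h
    if (e == "C") {
      if (ch == 0) {
        # exocyclic double bond (quinoid) satisfies the need
        exo <- any((bonds$a1 == a | bonds$a2 == a) & !bonds$aromatic &
                     bonds$order == 2L)
        needs[a] <- !exo
        pi_e[a] <- 1
      } else if (ch < 0) { needs[a] <- FALSE; pi_e[a] <- 2 }
      else { needs[a] <- FALSE; pi_e[a] <- 0 }
    } else if (e %in% c("N", "P")) {
      if (ch == 0) {
        needs[a] <- total_conn == 2L
        pi_e[a] <- if (total_conn == 2L) 1 else 2
      } else if (ch == 1) {
        needs[a] <- total_conn == 3L
        pi_e[a] <- if (total_conn == 3L) 1 else 2
      } else { needs[a] <- FALSE; pi_e[a] <- 2 }
    } else if (e %in% c("O", "S")) {
      if (ch == 1) { needs[a] <- TRUE; pi_e[a] <- 1 }
      else { needs[a] <- FALSE; pi_e[a] <- 2 }
    } else if (e == "B") {
      needs[a] <- FALSE; pi_e[a] <- 0
    } else {
      needs[a] <- FALSE; pi_e[a] <- 2
    }
  }

  # Hueckel count per connected aromatic component
  comp <- .components_of(nrow(atoms), bonds$a1[abm], bonds$a2[abm])
  for (cc in unique(comp[ai])) {
    members <- which(comp == cc & atoms$aromatic)
    ne <- sum(pi_e[members])
    if (ne %% 4 != 2) {
      return(list(ok = FALSE,
                  reason = sprintf("aromatic system with %d pi electrons", ne)))
    }
  }

  # perfect matching over atoms with needs=TRUE restricted to aromatic
  # bonds, by backtracking (aromatic systems are small)
  need_idx <- which(needs)
  if (length(need_idx) %% 2L == 1L) {
    return(list(ok = FALSE, reason = "kekulization failure"))
  }
  adj <- lapply(seq_len(nrow(atoms)), function(a) integer(0))
  for (i in abm) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    if (needs[a] && needs[b]) {
      adj[[a]] <- c(adj[[a]], i)
      adj[[b]] <- c(adj[[b]], i)
    }
  }
  matched_bond <- integer(0)
  unmatched <- needs
  match_rec <- function() {
    a <- which(unmatched)
    if (length(a) == 0L) return(TRUE)
    a <- a[1]
    for (i in adj[[a]]) {
      b <- if (bonds$a1[i] == a) bonds$a2[i] else bonds$a1[i]
      if (!unmatched[b]) next
      unmatched[c(a, b)] <<- FALSE
      matched_bond <<- c(matched_bond, i)
      if (match_rec()) return(TRUE)
      unmatched[c(a, b)] <<- TRUE
      matched_bond <<- matched_bond[-length(matched_bond)]
    }
    FALSE
  }
  if (!match_rec()) {
    return(list(ok = FALSE, reason = "kekulization failure"))
  }
  order[abm] <- 1L
  order[matched_bond] <- 2L
  list(ok = TRUE, order = order)
}

# connected components over n nodes given edge lists
.components_of <- function(n, a1, a2) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_along(a1)) {
      m <- min(comp[a1[i]], comp[a2[i]])
      if (comp[a1[i]] != m || comp[a2[i]] != m) {
        comp[c(a1[i], a2[i])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

.check_valences <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$order[i]
    bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + o
    bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + o
  }
  hcount <- integer(n)
  for (a in seq_len(n)) {
    e <- atoms$element[a]
    if (e == "H") {
      if (bsum[a] > 1) return(list(ok = FALSE, reason = "hypervalent H"))
      next
    }
    allowed <- .allowed_valences(e, atoms$charge[a])
    if (atoms$bracket[a]) {
      hcount[a] <- atoms$hcount[a]
      if (!is.null(allowed) &&
          bsum[a] + atoms$hcount[a] > max(allowed)) {
        return(list(ok = FALSE,
                    reason = sprintf("valence %d exceeds maximum for %s%+d",
                                     as.integer(bsum[a] + atoms$hcount[a]),
                                     e, atoms$charge[a])))
      }
    } else {
      fit <- allowed[allowed >= bsum[a]]
      if (length(fit) == 0L) {
        return(list(ok = FALSE,
                    reason = sprintf("valence %d exceeds maximum for %s",
                                     as.integer(bsum[a]), e)))
      }
      hcount[a] <- as.integer(min(fit) - bsum[a])
    }
  }
  list(ok = TRUE, hcount = hcount)
}

#' Check SMILES validity
#'
#' Vectorized wrapper around [smiles_parse()].
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @examples
#' smiles_is_valid(c("CCO", "C(", "c1ccc1"))
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) smiles_parse(s)$valid, logical(1),
         USE.NAMES = FALSE)
}

#' Count heavy (non-hydrogen) atoms
#'
#' @param mol A `smiles_mol` from [smiles_parse()].
#' @return Integer count.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "smiles_mol"), mol$valid)
  sum(mol$atoms$element != "H")
}

#' Molecular weight (average atomic masses, implicit H included)
#' @param mol A valid `smiles_mol`.
#' @return Weight in daltons.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "smiles_mol"), mol$valid)
  w <- .atomic_weight[mol$atoms$element]
  w[is.na(w)] <- 0
  sum(w) + sum(mol$atoms$hcount) * .atomic_weight[["H"]]
}
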