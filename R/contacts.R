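# Protein-ligand contact analysis: per-residue occurrence frequencies
# of heavy-atom contacts across a set of docked poses, at an inclusive
# distance cutoff (default 5 angstroms).
#
# Two interchangeable distance engines are provided: a naive all-pairs
# scan (the oracle) and a cell-list grid (cells of cutoff width; only
# the 27 neighbouring cells of each ligand atom are scanned).  Both
# return exactly the same contact sets.

# --- ingestion ------------------------------------------------------

#' Read a protein structure from PDB
#'
#' @param path PDB file.
#' @return data.frame with columns `chain`, `resno`, `resname`,
#'   `elety`, `element`, `x`, `y`, `z` (ATOM records only).
#' @export
read_protein_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  ch <- a$chain
  ch[is.na(ch) | ch == ""] <- "A"
  data.frame(chain = ch, resno = a$resno, resname = a$resid,
             elety = a$elety, element = .element_of(a$elesy, a$elety),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# element symbol from the PDB element column, falling back to the atom
# name's leading letters
.element_of <- function(elesy, elety) {
  out <- toupper(trimws(as.character(elesy)))
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(as.character(elety[miss])))
    # two-letter symbols that occur in structures; else first letter
    two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE")
    nm <- toupper(nm)
    out[miss] <- ifelse(substr(nm, 1, 2) %in% two,
                        substr(nm, 1, 2), substr(nm, 1, 1))
  }
  out
}

#' Read ligand poses from SDF or PDB
#'
#' SDF (V2000) files may hold several poses; each becomes one
#' coordinate matrix named after its title line (or `pose<i>`).  A PDB
#' file yields a single pose from its HETATM/ATOM coordinates.
#'
#' @param path SDF or PDB file (format by extension: `.sdf`/`.mol`
#'   vs `.pdb`).
#' @param include_h Keep hydrogens? Default drops them.
#' @return Named list of n x 3 coordinate matrices.
#' @export
read_poses <- function(path, include_h = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    poses <- .read_sdf_poses(path)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    el <- .element_of(a$elesy, a$elety)
    m <- cbind(x = a$x, y = a$y, z = a$z)
    attr(m, "element") <- el
    poses <- list(pose1 = m)
  } else {
    stop("unsupported pose format: .", ext)
  }
  if (!include_h) {
    poses <- lapply(poses, function(m) {
      el <- attr(m, "element")
      keep <- if (is.null(el)) rep(TRUE, nrow(m)) else el != "H"
      out <- m[keep, , drop = FALSE]
      attr(out, "element") <- el[keep]
      out
    })
  }
  poses
}

# minimal V2000 SDF reader: title line, counts line, atom block
.read_sdf_poses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on $$$$ delimiters
  ends <- c(grep("^\\$\\$\\$\\$", lines), length(lines) + 1L)
  starts <- c(1L, ends[-length(ends)] + 1L)
  poses <- list()
  for (b in seq_along(starts)) {
    blk <- lines[starts[b]:min(ends[b] - 1L, length(lines))]
    blk <- blk[cumsum(nzchar(trimws(blk))) > 0 | nzchar(trimws(blk))]
    if (length(blk) < 4L || !any(nzchar(trimws(blk)))) next
    title <- trimws(blk[1])
    counts <- blk[4]
    natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    if (is.na(natoms)) stop("malformed SDF counts line in ", path)
    at <- blk[5:(4 + natoms)]
    xyz <- t(vapply(at, function(l) {
      as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30)))
    }, numeric(3)))
    el <- toupper(trimws(substr(at, 32, 34)))
    rownames(xyz) <- NULL
    colnames(xyz) <- c("x", "y", "z")
    attr(xyz, "element") <- el
    nm <- if (nzchar(title)) title else paste0("pose", length(poses) + 1L)
    poses[[nm]] <- xyz
  }
  if (length(poses) == 0L) stop("no poses found in ", path)
  poses
}

#' Assemble a pose set from protein and ligand coordinates
#'
#' @param protein data.frame as from [read_protein_pdb()] (columns
#'   `chain`, `resno`, `resname`, `x`, `y`, `z`; `element` optional).
#' @param ligands Named list of n x 3 coordinate matrices.
#' @return A `pose_set`.
#' @export
pose_set <- function(protein, ligands) {
  stopifnot(is.data.frame(protein),
            all(c("chain", "resno", "resname", "x", "y", "z") %in%
                  names(protein)),
            is.list(ligands), length(ligands) >= 1L)
  coords <- as.matrix(protein[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("protein coordinates must be finite")
  for (m in ligands) {
    if (!all(is.finite(as.matrix(m)[, 1:3]))) {
      stop("ligand coordinates must be finite")
    }
  }
  structure(list(protein = protein, ligands = ligands),
            class = "pose_set")
}

# --- distance engines -----------------------------------------------

# heavy-atom protein view: rows to use plus residue keys
.protein_view <- function(protein, include_h) {
  keep <- rep(TRUE, nrow(protein))
  if (!include_h && "element" %in% names(protein)) {
    keep <- protein$element != "H"
  }
  p <- protein[keep, , drop = FALSE]
  list(xyz = as.matrix(p[, c("x", "y", "z")]),
       key = paste(p$chain, p$resno, sep = ":"),
       resname = p$resname, chain = p$chain, resno = p$resno)
}

.ligand_xyz <- function(ligand, include_h) {
  m <- as.matrix(ligand)[, 1:3, drop = FALSE]
  el <- attr(ligand, "element")
  if (!include_h && !is.null(el)) m <- m[el != "H", , drop = FALSE]
  if (nrow(m) == 0L) stop("ligand pose has no atoms after filtering")
  m
}

# naive all-pairs: which residue keys have an atom within cutoff
.contacts_naive <- function(pv, lig, cutoff) {
  hit <- logical(nrow(pv$xyz))
  for (i in seq_len(nrow(lig))) {
    d2 <- (pv$xyz[, 1] - lig[i, 1])^2 + (pv$xyz[, 2] - lig[i, 2])^2 +
      (pv$xyz[, 3] - lig[i, 3])^2
    hit <- hit | d2 <= cutoff^2
  }
  unique(pv$key[hit])
}

# cell-list grid with cells of cutoff width
.contacts_grid <- function(pv, lig, cutoff) {
  cell <- function(xyz) floor(xyz / cutoff)
  pc <- cell(pv$xyz)
  pk <- paste(pc[, 1], pc[, 2], pc[, 3])
  bins <- split(seq_len(nrow(pv$xyz)), pk)
  hit <- logical(nrow(pv$xyz))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(lig))) {
    lc <- floor(lig[i, ] / cutoff)
    for (o in seq_len(nrow(off))) {
      key <- paste(lc[1] + off[o, 1], lc[2] + off[o, 2], lc[3] + off[o, 3])
      idx <- bins[[key]]
      if (is.null(idx)) next
      d2 <- (pv$xyz[idx, 1] - lig[i, 1])^2 +
        (pv$xyz[idx, 2] - lig[i, 2])^2 +
        (pv$xyz[idx, 3] - lig[i, 3])^2
      hit[idx[d2 <= cutoff^2]] <- TRUE
    }
  }
  unique(pv$key[hit])
}

# --- public operations ----------------------------------------------

#' Residues in contact with one ligand pose
#'
#' A residue is in contact when any of its heavy atoms lies within
#' `cutoff` (inclusive, `<=`) of any ligand heavy atom.
#'
#' @param protein Protein data.frame (see [pose_set()]).
#' @param ligand n x 3 coordinate matrix; an `"element"` attribute, if
#'   present, is used to drop hydrogens.
#' @param cutoff Distance cutoff in angstroms; must be > 0.
#' @param include_h Include hydrogens on both sides (default FALSE).
#' @param method `"grid"` (cell list) or `"naive"` (all pairs); both
#'   give identical results.
#' @return data.frame of contacted residues: `chain`, `resno`,
#'   `resname`.
#' @export
contact_residues <- function(protein, ligand, cutoff = 5,
                             include_h = FALSE,
                             method = c("grid", "naive")) {
  method <- match.arg(method)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(dim(ligand)) || nrow(ligand) == 0L) {
    stop("ligand pose is empty")
  }
  pv <- .protein_view(protein, include_h)
  lig <- .ligand_xyz(ligand, include_h)
  keys <- if (method == "naive") .contacts_naive(pv, lig, cutoff)
          else .contacts_grid(pv, lig, cutoff)
  idx <- match(keys, pv$key)
  out <- data.frame(chain = pv$chain[idx], resno = pv$resno[idx],
                    resname = pv$resname[idx], stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Per-residue contact occurrence frequencies over a pose set
#'
#' For each residue, the fraction of ligand poses with at least one
#' heavy-atom contact within the cutoff.
#'
#' @param ps A `pose_set`.
#' @param cutoff Distance cutoff in angstroms.
#' @param include_h Include hydrogens (default FALSE).
#' @param method Distance engine, as in [contact_residues()].
#' @return A `contact_profile`: data.frame (`chain`, `resno`,
#'   `resname`, `frequency`) over all residues, sorted by chain and
#'   residue number, with attributes `n_ligands` and `cutoff`.
#' @export
contact_frequencies <- function(ps, cutoff = 5, include_h = FALSE,
                                method = c("grid", "naive")) {
  method <- match.arg(method)
  stopifnot(inherits(ps, "pose_set"))
  if (length(ps$ligands) == 0L) stop("pose set has no ligands")
  prot <- ps$protein
  res <- unique(data.frame(chain = prot$chain, resno = prot$resno,
                           resname = prot$resname,
                           stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  key <- paste(res$chain, res$resno, sep = ":")
  counts <- integer(length(key))
  for (lig in ps$ligands) {
    cr <- contact_residues(prot, lig, cutoff = cutoff,
                           include_h = include_h, method = method)
    counts <- counts +
      as.integer(key %in% paste(cr$chain, cr$resno, sep = ":"))
  }
  res$frequency <- counts / length(ps$ligands)
  attr(res, "n_ligands") <- length(ps$ligands)
  attr(res, "cutoff") <- cutoff
  class(res) <- c("contact_profile", "data.frame")
  res
}

#' Hotspot residues above a frequency threshold
#'
#' Residues whose contact frequency is strictly greater than
#' `threshold` (so 0.50 itself is excluded at the default), sorted by
#' frequency, highest first.
#'
#' @param profile A `contact_profile`.
#' @param threshold Frequency threshold in [0, 1].
#' @return data.frame subset of the profile, sorted by descending
#'   frequency.
#' @export
hotspot_filter <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "contact_profile"),
            threshold >= 0, threshold <= 1)
  out <- as.data.frame(profile)[profile$frequency > threshold, ,
                                drop = FALSE]
  out <- out[order(-out$frequency, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson similarity of two contact profiles
#'
#' Correlates the frequency vectors of two profiles over the union of
#' their residues (a residue absent from one profile counts as
#' frequency 0 there).  Reported as a number, not a verdict.
#'
#' @param p1,p2 `contact_profile` objects.
#' @return Pearson correlation coefficient (NA if either vector is
#'   constant).
#' @export
profile_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "contact_profile"),
            inherits(p2, "contact_profile"))
  k1 <- paste(p1$chain, p1$resno, sep = ":")
  k2 <- paste(p2$chain, p2$resno, sep = ":")
  keys <- union(k1, k2)
  f1 <- ifelse(keys %in% k1, p1$frequency[match(keys, k1)], 0)
  f2 <- ifelse(keys %in% k2, p2$frequency[match(keys, k2)], 0)
  if (stats::sd(f1) == 0 || stats::sd(f2) == 0) return(NA_real_)
  stats::cor(f1, f2)
}

#' Write a contact profile to CSV and/or JSON
#'
#' @param profile A `contact_profile`.
#' @param csv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, the profile.
#' @export
write_contact_profile <- function(profile, csv_path = NULL,
                                  json_path = NULL) {
  stopifnot(inherits(profile, "contact_profile"))
  df <- as.data.frame(profile)
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(cutoff = attr(profile, "cutoff"),
           n_ligands = attr(profile, "n_ligands"),
           residues = df),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(profile)
}
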