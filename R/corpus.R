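# Corpus curation: canonicalization, the heavy-atom/length/blocklist
# filter, and line-delimited SMILES IO.
#
# Validity is decided by the package's strict parser; canonical strings
# come from OpenBabel (via ChemmineOB), which is deterministic and
# idempotent.  A string is only sent to the canonicalizer after it has
# passed the strict parser, and the canonical form is re-checked, so
# every canonical string in a record table is itself parseable.

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of raw SMILES.
#' @return Character vector of canonical SMILES; `NA` where the input is
#'   not valid.  Canonicalization is idempotent: applying it to its own
#'   output returns the same strings.
#' @examples
#' \donttest{canonicalize_smiles(c("OCC", "C("))}
#' @export
canonicalize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  ok <- smiles_is_valid(smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(out)
  block <- paste(sprintf("%s m%d", smiles[idx], seq_along(idx)),
                 collapse = "\n")
  res <- ChemmineOB::convertFormat("SMI", "CAN", block)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[2] else "",
                character(1))
  pos <- as.integer(sub("^m", "", trimws(ids)))
  keep <- !is.na(pos) & nzchar(can)
  out[idx[pos[keep]]] <- trimws(can[keep])
  # the canonical form must itself pass the strict parser
  got <- !is.na(out)
  if (any(got)) {
    still <- smiles_is_valid(out[got])
    out[got][!still] <- NA_character_
  }
  out
}

#' Build a SMILES record table
#'
#' One row per input molecule: the raw string, its canonical form, the
#' heavy-atom count and a validity flag.  Unparseable strings get
#' `is_valid = FALSE` and `NA` fields; no input ever raises.
#'
#' @param raw Character vector of SMILES.
#' @param source_id Optional character vector of identifiers.
#' @return A data.frame with columns `raw`, `canonical`, `heavy_atoms`,
#'   `is_valid`, `source_id`.
#' @export
smiles_records <- function(raw, source_id = NULL) {
  stopifnot(is.character(raw))
  if (is.null(source_id)) source_id <- rep(NA_character_, length(raw))
  stopifnot(length(source_id) == length(raw))
  canonical <- canonicalize_smiles(raw)
  is_valid <- !is.na(canonical)
  heavy <- rep(NA_integer_, length(raw))
  heavy[is_valid] <- vapply(raw[is_valid], function(s) {
    heavy_atom_count(smiles_parse(s))
  }, integer(1), USE.NAMES = FALSE)
  data.frame(raw = raw, canonical = canonical, heavy_atoms = heavy,
             is_valid = is_valid, source_id = source_id,
             stringsAsFactors = FALSE)
}

#' Filter a SMILES record table for language-model training
#'
#' Retains valid records whose heavy-atom count lies in
#' `[min_heavy, max_heavy]` and whose canonical string is shorter than
#' `max_len` characters, drops any canonical string present in the
#' blocklist (compared in canonical form), and deduplicates on the
#' canonical string.  The defaults are the curation rules used for the
#' pretraining corpus: 10 to 100 heavy atoms and canonical length under
#' 140.  A per-rule removal count is attached as the `"curation"`
#' attribute and is idempotent: filtering a filtered table removes
#' nothing further.
#'
#' @param records A data.frame from [smiles_records()].
#' @param blocklist Character vector of SMILES to exclude (canonicalized
#'   before comparison), e.g. known actives that must not leak into
#'   pretraining.
#' @param min_heavy,max_heavy Inclusive heavy-atom bounds.
#' @param max_len Exclusive upper bound on canonical string length.
#' @return Filtered data.frame with a `"curation"` attribute listing
#'   counts removed per rule.
#' @export
filter_corpus <- function(records, blocklist = character(0),
                          min_heavy = 10L, max_heavy = 100L,
                          max_len = 140L) {
  stopifnot(is.data.frame(records),
            all(c("canonical", "heavy_atoms", "is_valid") %in%
                  names(records)))
  n0 <- nrow(records)
  bl <- character(0)
  if (length(blocklist)) {
    bl <- canonicalize_smiles(blocklist)
    bl <- bl[!is.na(bl)]
  }
  valid <- records$is_valid & !is.na(records$canonical)
  r1 <- records[valid, , drop = FALSE]
  in_range <- r1$heavy_atoms >= min_heavy & r1$heavy_atoms <= max_heavy
  r2 <- r1[in_range, , drop = FALSE]
  short <- nchar(r2$canonical) < max_len
  r3 <- r2[short, , drop = FALSE]
  blocked <- r3$canonical %in% bl
  r4 <- r3[!blocked, , drop = FALSE]
  dup <- duplicated(r4$canonical)
  out <- r4[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curation") <- list(
    n_input = n0,
    removed_invalid = n0 - nrow(r1),
    removed_heavy_atoms = nrow(r1) - nrow(r2),
    removed_length = nrow(r2) - nrow(r3),
    removed_blocklist = nrow(r3) - nrow(r4),
    removed_duplicate = nrow(r4) - nrow(out),
    n_retained = nrow(out)
  )
  out
}

#' Read a line-delimited SMILES file
#'
#' Each line is `SMILES` or `SMILES<ws>id`.
#'
#' @param path File path.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2] else
      NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a line-delimited SMILES file
#' @param smiles Character vector.
#' @param path File path.
#' @param id Optional identifiers (second column).
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a curation report as JSON
#' @param filtered A filtered record table from [filter_corpus()].
#' @param path Output path.
#' @export
write_curation_report <- function(filtered, path) {
  rep <- attr(filtered, "curation")
  if (is.null(rep)) stop("no curation attribute; run filter_corpus() first")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
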