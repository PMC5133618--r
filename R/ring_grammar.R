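# RING-H2 motif grammar: identification of ATL-type E3 ligase domains.
#
# The ATL domain signature is eight zinc-coordinating ligands in the order
# C-C-C-H-H-C-C-C with constrained spacing, a proline one or two residues
# before the third cysteine (PC / PxC), and (in most members) a tryptophan
# three residues after the fourth cysteine.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Define a RING-H2 spacing grammar
#'
#' A grammar fixes the ligand order of the ATL-type RING-H2 zinc finger
#' (C-C-C-H-H-C-C-C), the permitted number of residues between consecutive
#' ligands, the placement of the conserved proline relative to the third
#' cysteine, and the optional tryptophan checks.
#'
#' The two variable-length stretches of the family consensus
#' (between the second cysteine and the proline, and between the
#' post-C6 tryptophan and the seventh ligand) default to 4--30 residues,
#' bracketing the canonical seed motif's fixed 13 and 7. Spacer ranges are
#' expressed as inter-ligand gap lengths, so the gap between C2 and C3
#' includes the `Px`/`P` prefix and the gap between C6 and C7 includes the
#' `xxxW` prefix.
#'
#' @param ligand_pattern Character vector of eight ligand symbols; only
#'   `"C"` and `"H"` are meaningful. Default is the RING-H2 order.
#' @param spacer_ranges 7 x 2 integer matrix of (min, max) residues between
#'   consecutive ligands.
#' @param proline_rule One of `"either"` (default; the family admits both
#'   subtypes), `"PxC"` (proline two residues before the third cysteine) or
#'   `"PC"` (immediately adjacent).
#' @param require_w4 Require tryptophan exactly three residues after the
#'   fourth cysteine-class ligand (pattern `CxxxW`). Default `TRUE`.
#' @param require_trailing_w Require tryptophan immediately after the last
#'   ligand. Default `FALSE` (absent from the general family consensus).
#' @return An object of class `motif_grammar`.
#' @seealso [seed_grammar()] for the fixed-spacer canonical motif,
#'   [scan_ring_h2()] to apply a grammar to a protein.
#' @export
motif_grammar <- function(ligand_pattern = c("C", "C", "C", "H", "H", "C", "C", "C"),
                          spacer_ranges = default_spacer_ranges(),
                          proline_rule = c("either", "PxC", "PC"),
                          require_w4 = TRUE,
                          require_trailing_w = FALSE) {
  proline_rule <- match.arg(proline_rule)
  spacer_ranges <- as.matrix(spacer_ranges)
  if (length(ligand_pattern) != 8L)
    stop("a RING-H2 grammar requires exactly 8 ligands")
  if (!all(ligand_pattern %in% c("C", "H")))
    stop("ligand symbols must be 'C' or 'H'")
  if (!identical(dim(spacer_ranges), c(7L, 2L)))
    stop("spacer_ranges must be a 7 x 2 (min, max) matrix")
  storage.mode(spacer_ranges) <- "integer"
  if (any(spacer_ranges < 0L)) stop("spacer ranges must be non-negative")
  if (any(spacer_ranges[, 1L] > spacer_ranges[, 2L]))
    stop("spacer min must not exceed max")
  min_p_offset <- switch(proline_rule, PC = 1L, PxC = 2L, either = 1L)
  if (spacer_ranges[2L, 1L] < min_p_offset)
    stop("gap C2->C3 too short to contain the proline")
  if (require_w4 && spacer_ranges[6L, 1L] < 4L)
    stop("gap C6->C7 too short to contain the CxxxW tryptophan")
  structure(
    list(ligand_pattern = ligand_pattern,
         spacer_ranges = spacer_ranges,
         proline_rule = proline_rule,
         require_w4 = require_w4,
         require_trailing_w = require_trailing_w),
    class = "motif_grammar")
}

default_spacer_ranges <- function(var_min = 4L, var_max = 30L) {
  cbind(c(2L, var_min + 2L, 1L, 2L, 2L, var_min + 4L, 2L),
        c(2L, var_max + 2L, 1L, 2L, 2L, var_max + 4L, 2L))
}

#' Canonical seed grammar with fixed spacers
#'
#' The fixed-spacing form `CxxC(13x)PxCxHxxHxxCxxxW(7x)CxxCW` used to seed
#' the family search: gaps 2, 15, 1, 2, 2, 11, 2 with a PxC proline and both
#' tryptophan checks.
#'
#' @return A `motif_grammar`.
#' @export
seed_grammar <- function() {
  motif_grammar(
    spacer_ranges = cbind(c(2L, 15L, 1L, 2L, 2L, 11L, 2L),
                          c(2L, 15L, 1L, 2L, 2L, 11L, 2L)),
    proline_rule = "PxC",
    require_w4 = TRUE,
    require_trailing_w = TRUE)
}

#' @export
print.motif_grammar <- function(x, ...) {
  gaps <- apply(x$spacer_ranges, 1L, function(r)
    if (r[1L] == r[2L]) as.character(r[1L]) else paste0(r[1L], "-", r[2L]))
  cat("RING-H2 motif grammar\n")
  cat("  ligands:", paste(x$ligand_pattern, collapse = " "), "\n")
  cat("  gaps:   ", paste(gaps, collapse = ", "), "\n")
  cat("  proline:", x$proline_rule,
      "| W after C6+3:", x$require_w4,
      "| trailing W:", x$require_trailing_w, "\n")
  invisible(x)
}

#' Create a protein record
#'
#' @param id Unique identifier.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus `X`.
#' @param description Optional free-text description.
#' @return A `protein_record` (named list).
#' @export
protein_record <- function(id, sequence, description = "") {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("record '", id, "' contains invalid residue(s): ",
         paste(bad, collapse = ", "))
  structure(list(id = as.character(id), sequence = sequence,
                 description = as.character(description)),
            class = "protein_record")
}

as_protein_record <- function(x, id = "seq") {
  if (inherits(x, "protein_record")) x else protein_record(id, x)
}

#' Scan a protein for ATL-type RING-H2 matches
#'
#' Exhaustively enumerates every placement of the eight ligands that
#' satisfies the grammar's spacing, proline and tryptophan constraints.
#' `X` never matches a ligand, the proline or a required tryptophan.
#'
#' @param protein A `protein_record`, or a plain sequence string.
#' @param grammar A [motif_grammar()].
#' @return List of `ring_h2_match` objects ordered by first-ligand position
#'   (then lexicographically); empty list if no placement matches. Each
#'   match carries 1-based `ligand_positions` (length 8), `spacer_lengths`
#'   (length 7), `proline_position`, `subtype` (`"PxC"` or `"PC"`),
#'   `w4_position` (or `NA`), `start` and `end`.
#' @export
scan_ring_h2 <- function(protein, grammar = motif_grammar()) {
  stopifnot(inherits(grammar, "motif_grammar"))
  protein <- as_protein_record(protein)
  chars <- strsplit(protein$sequence, "")[[1L]]
  n <- length(chars)
  lig <- grammar$ligand_pattern
  rng <- grammar$spacer_ranges
  # minimal residues needed from ligand k to the end of the motif
  min_tail <- rev(cumsum(rev(c(rng[, 1L] + 1L, 0L))))

  placements <- list()
  extend <- function(pos) {
    k <- length(pos)
    if (k == 8L) {
      placements[[length(placements) + 1L]] <<- pos
      return(invisible())
    }
    last <- pos[k]
    for (gap in rng[k, 1L]:rng[k, 2L]) {
      nxt <- last + gap + 1L
      if (nxt > n) break
      if (chars[nxt] == lig[k + 1L]) extend(c(pos, nxt))
    }
    invisible()
  }
  for (i in seq_len(max(0L, n - min_tail[1L] + 1L))) {
    if (chars[i] == lig[1L]) extend(i)
  }

  out <- list()
  for (pos in placements) {
    c3 <- pos[3L]
    p_pos <- NA_integer_
    subtype <- NA_character_
    has_pc <- c3 - 1L > pos[2L] && chars[c3 - 1L] == "P"
    has_pxc <- c3 - 2L > pos[2L] && chars[c3 - 2L] == "P"
    ok <- switch(grammar$proline_rule,
                 PC = has_pc,
                 PxC = has_pxc,
                 either = has_pc || has_pxc)
    if (!ok) next
    # adjacency takes precedence when both offsets carry a proline
    if (grammar$proline_rule != "PxC" && has_pc) {
      p_pos <- c3 - 1L; subtype <- "PC"
    } else {
      p_pos <- c3 - 2L; subtype <- "PxC"
    }
    w4 <- NA_integer_
    if (grammar$require_w4) {
      cand <- pos[6L] + 4L
      if (cand >= pos[7L] || chars[cand] != "W") next
      w4 <- cand
    }
    if (grammar$require_trailing_w) {
      tw <- pos[8L] + 1L
      if (tw > n || chars[tw] != "W") next
    }
    out[[length(out) + 1L]] <- structure(
      list(ligand_positions = pos,
           spacer_lengths = diff(pos) - 1L,
           proline_position = p_pos,
           subtype = subtype,
           w4_position = w4,
           start = pos[1L],
           end = pos[8L],
           protein_id = protein$id),
      class = "ring_h2_match")
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(m)
      paste(formatC(m$ligand_positions, width = 6, flag = "0"),
            collapse = ""), character(1L))
    out <- out[order(key)]
  }
  out
}

#' @export
print.ring_h2_match <- function(x, ...) {
  cat(sprintf("RING-H2 match [%d-%d] subtype %s\n", x$start, x$end, x$subtype))
  cat("  ligands:", paste(x$ligand_positions, collapse = ","),
      "| P at", x$proline_position,
      if (!is.na(x$w4_position)) paste("| W at", x$w4_position) else "", "\n")
  invisible(x)
}

#' Classify a RING-H2 match into the ATL/BTL subtype
#'
#' Deterministic map from proline spacing: proline two residues before the
#' third cysteine gives `ATL_PxC`, immediately adjacent gives `BTL_PC`.
#'
#' @param match A `ring_h2_match`.
#' @return `"ATL_PxC"` or `"BTL_PC"`.
#' @export
classify_subtype <- function(match) {
  stopifnot(inherits(match, "ring_h2_match"))
  c3 <- match$ligand_positions[3L]
  if (identical(match$proline_position, c3 - 1L)) return("BTL_PC")
  if (identical(match$proline_position, c3 - 2L)) return("ATL_PxC")
  stop("match proline position is neither C3-1 nor C3-2; invalid match")
}

#' Assign a family member to an N-terminal category
#'
#' Categories are mutually exclusive: `TM_PxC` (transmembrane or hydrophobic
#' N-terminus with a PxC motif), `BZF_PC` (N-terminal BZF domain, PC motif,
#' no hydrophobic/TM region), `Hyd_PC` (hydrophobic or TM N-terminus with a
#' PC motif), `BZF_Hyd_PC` (both), and `NoNterm` (no N-terminal feature
#' beyond the RING-H2 itself).
#'
#' @param subtype `"PxC"` or `"PC"` (also accepts `"ATL_PxC"`/`"BTL_PC"`).
#' @param tm_h_code 0 (none), 0.5 (one or more hydrophobic regions only), or
#'   an integer number of transmembrane segments.
#' @param has_bzf Logical; BZF (zf-RING_3) domain present.
#' @return One of `"TM_PxC"`, `"BZF_PC"`, `"Hyd_PC"`, `"BZF_Hyd_PC"`,
#'   `"NoNterm"`.
#' @export
classify_family_member <- function(subtype, tm_h_code, has_bzf) {
  subtype <- switch(as.character(subtype),
                    ATL_PxC = "PxC", BTL_PC = "PC",
                    PxC = "PxC", PC = "PC",
                    stop("unknown subtype: ", subtype))
  tm_h_code <- as.numeric(tm_h_code)
  if (is.na(tm_h_code) || tm_h_code < 0 ||
      !(tm_h_code == 0.5 || tm_h_code == floor(tm_h_code)))
    stop("tm_h_code must be 0, 0.5 or a non-negative integer")
  if (isTRUE(has_bzf)) {
    if (tm_h_code > 0) "BZF_Hyd_PC" else "BZF_PC"
  } else if (tm_h_code > 0) {
    if (subtype == "PxC") "TM_PxC" else "Hyd_PC"
  } else {
    "NoNterm"
  }
}

#' Per-column residue frequencies of aligned motif segments
#'
#' Numeric stand-in for a sequence LOGO: relative frequency of each residue
#' at each column of a set of equal-length aligned segments.
#'
#' @param segments Character vector of aligned segments (equal length).
#' @return Numeric matrix, residues x columns; each column sums to 1.
#' @export
position_frequency_summary <- function(segments) {
  segments <- as.character(segments)
  if (!length(segments)) stop("at least one segment required")
  L <- unique(nchar(segments))
  if (length(L) != 1L) stop("segments must have equal aligned length")
  m <- do.call(rbind, strsplit(segments, ""))
  residues <- sort(unique(as.vector(m)))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = residues))
    as.numeric(tab) / length(segments)
  }, numeric(length(residues)))
  freq <- matrix(freq, nrow = length(residues),
                 dimnames = list(residues, paste0("col", seq_len(L))))
  freq
}

#' Write a motif match table as TSV
#'
#' @param matches List of `ring_h2_match` objects (possibly from several
#'   proteins).
#' @param path Output file.
#' @return The table, invisibly.
#' @export
write_match_table <- function(matches, path) {
  df <- match_table(matches)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Tabulate motif matches
#'
#' @param matches List of `ring_h2_match` objects.
#' @return data.frame with protein_id, start, end, comma-joined ligand
#'   positions and subtype.
#' @export
match_table <- function(matches) {
  if (!length(matches))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), ligand_positions = character(),
                      subtype = character()))
  data.frame(
    protein_id = vapply(matches, `[[`, character(1L), "protein_id"),
    start = vapply(matches, `[[`, integer(1L), "start"),
    end = vapply(matches, `[[`, integer(1L), "end"),
    ligand_positions = vapply(matches, function(m)
      paste(m$ligand_positions, collapse = ","), character(1L)),
    subtype = vapply(matches, `[[`, character(1L), "subtype"))
}

#' Read or write a grammar as a plain-text config
#'
#' Flat `key = value` format with keys `ligand_pattern`, `spacer_ranges`
#' (semicolon-separated `min-max` gaps), `proline_rule`, `require_w4`,
#' `require_trailing_w`.
#'
#' @param path File path.
#' @return `read_grammar_config` returns a `motif_grammar`.
#' @export
read_grammar_config <- function(path) {
  kv <- read_key_value(path)
  rng <- do.call(rbind, lapply(strsplit(kv[["spacer_ranges"]], ";")[[1L]],
                               function(g) {
    p <- as.integer(strsplit(g, "-", fixed = TRUE)[[1L]])
    if (length(p) == 1L) c(p, p) else p
  }))
  motif_grammar(
    ligand_pattern = strsplit(kv[["ligand_pattern"]], ",")[[1L]],
    spacer_ranges = rng,
    proline_rule = kv[["proline_rule"]],
    require_w4 = as.logical(kv[["require_w4"]]),
    require_trailing_w = as.logical(kv[["require_trailing_w"]]))
}

#' @rdname read_grammar_config
#' @param grammar A `motif_grammar` to serialise.
#' @export
write_grammar_config <- function(grammar, path) {
  stopifnot(inherits(grammar, "motif_grammar"))
  gaps <- apply(grammar$spacer_ranges, 1L, function(r)
    if (r[1L] == r[2L]) as.character(r[1L]) else paste0(r[1L], "-", r[2L]))
  lines <- c(
    paste0("ligand_pattern = ", paste(grammar$ligand_pattern, collapse = ",")),
    paste0("spacer_ranges = ", paste(gaps, collapse = ";")),
    paste0("proline_rule = ", grammar$proline_rule),
    paste0("require_w4 = ", grammar$require_w4),
    paste0("require_trailing_w = ", grammar$require_trailing_w))
  writeLines(lines, path)
  invisible(path)
}

read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}
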