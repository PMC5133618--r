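# Physical and sequence feature annotation: Kyte-Doolittle hydropathy with
# TM/hydrophobic region calling, GLD-motif grading, isoelectric point,
# molecular weight, and ingestion of external domain tables.

# Kyte & Doolittle (1982) hydropathy scale; X (unknown) contributes 0.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0)

# Average (isotope-weighted) residue masses in Da; X uses a 110 Da
# placeholder for unknown residues.
AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326,
  X = 110.0)
WATER_MASS <- 18.01524

# pKa sets: EMBOSS defaults and the Bjellqvist-style constants used by
# ProtParam-type calculators.
PKA_SETS <- list(
  emboss = list(nterm = 8.6, cterm = 3.6,
                pos = c(K = 10.8, R = 12.5, H = 6.5),
                neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)),
  protparam = list(nterm = 7.5, cterm = 3.55,
                   pos = c(K = 10.0, R = 12.0, H = 5.98),
                   neg = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)))

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of per-residue hydropathy. Values are defined only
#' at window centres where the full window fits inside the sequence.
#'
#' @param protein A `protein_record` or sequence string.
#' @param window Odd window width in residues (default 19, the classic
#'   transmembrane setting).
#' @return A `hydropathy_profile`: list with `window`, `centers` (1-based
#'   residue indices) and `values`. Sequences shorter than the window give
#'   an empty profile with a warning.
#' @export
kyte_doolittle_profile <- function(protein, window = 19L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  protein <- as_protein_record(protein)
  chars <- strsplit(protein$sequence, "")[[1L]]
  n <- length(chars)
  if (n < window) {
    warning("sequence '", protein$id, "' shorter than window; empty profile")
    return(structure(list(window = window, centers = integer(),
                          values = numeric(), protein_id = protein$id),
                     class = "hydropathy_profile"))
  }
  h <- unname(KD_SCALE[chars])
  half <- (window - 1L) %/% 2L
  sums <- cumsum(c(0, h))
  centers <- (half + 1L):(n - half)
  values <- (sums[centers + half + 1L] - sums[centers - half]) / window
  structure(list(window = window, centers = centers, values = values,
                 protein_id = protein$id),
            class = "hydropathy_profile")
}

#' Call transmembrane and hydrophobic regions from a hydropathy profile
#'
#' Maximal runs of window centres at or above `hyd_threshold` and of length
#' at least `min_len` become one region each; a region whose peak reaches
#' `tm_threshold` is typed `TM`, otherwise `hydrophobic`.
#'
#' @param profile A `hydropathy_profile`.
#' @param tm_threshold Peak score for a transmembrane call (default 1.6).
#' @param hyd_threshold Run membership score (default 0.8).
#' @param min_len Minimum run length in centres (default 15).
#' @return List with `regions` (data.frame start, end, kind, peak in residue
#'   coordinates of the window centres) and `tm_h_code` (integer TM count,
#'   else 0.5 if any hydrophobic region, else 0).
#' @export
call_regions <- function(profile, tm_threshold = 1.6, hyd_threshold = 0.8,
                         min_len = 15L) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  if (hyd_threshold >= tm_threshold)
    stop("hyd_threshold must be below tm_threshold")
  v <- profile$values
  regions <- data.frame(start = integer(), end = integer(),
                        kind = character(), peak = numeric())
  if (length(v)) {
    above <- v >= hyd_threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_len)
    for (i in keep) {
      idx <- starts[i]:ends[i]
      peak <- max(v[idx])
      regions <- rbind(regions, data.frame(
        start = profile$centers[starts[i]],
        end = profile$centers[ends[i]],
        kind = if (peak >= tm_threshold) "TM" else "hydrophobic",
        peak = peak))
    }
  }
  n_tm <- sum(regions$kind == "TM")
  code <- if (n_tm >= 1L) as.numeric(n_tm)
          else if (nrow(regions)) 0.5 else 0
  list(regions = regions, tm_h_code = code)
}

#' Grade the GLD motif within a search region
#'
#' Looks for the conserved Gly-Leu-Asp tripartite motif upstream of the
#' RING-H2 domain and grades the best occurrence: `complete` (literal GLD),
#' `GLx` or `GxD` (two conserved residues), `Gxx` (glycine only) or `none`.
#' Preference is complete > GLx = GxD > Gxx, leftmost on ties.
#'
#' @param protein A `protein_record` or sequence string.
#' @param region Integer vector `c(start, end)` of the 1-based search
#'   region; `NULL` scans the whole sequence. An empty region grades `none`.
#' @return List with `grade` and `position` (1-based index of the glycine,
#'   `NA` if none).
#' @export
grade_gld <- function(protein, region = NULL) {
  protein <- as_protein_record(protein)
  chars <- strsplit(protein$sequence, "")[[1L]]
  n <- length(chars)
  if (is.null(region)) region <- c(1L, n)
  lo <- max(1L, as.integer(region[1L]))
  hi <- min(n, as.integer(region[2L]))
  if (lo > hi) return(list(grade = "none", position = NA_integer_))
  best <- list(grade = "none", position = NA_integer_)
  rank <- c(none = 0L, Gxx = 1L, GxD = 2L, GLx = 2L, complete = 3L)
  for (i in lo:min(hi, n - 2L)) {
    if (chars[i] != "G") next
    l <- chars[i + 1L] == "L"
    d <- chars[i + 2L] == "D"
    g <- if (l && d) "complete" else if (l) "GLx" else if (d) "GxD" else "Gxx"
    if (rank[[g]] > rank[[best$grade]]) best <- list(grade = g, position = i)
  }
  if (best$grade == "none" && hi >= lo) {
    # trailing G too close to the region end can still grade Gxx
    tail_g <- which(chars[lo:hi] == "G")
    if (length(tail_g)) best <- list(grade = "Gxx", position = lo + tail_g[1L] - 1L)
  }
  best
}

net_charge <- function(counts, nterm, cterm, pka, pH) {
  pos <- nterm / (1 + 10^(pH - pka$nterm)) +
    sum(counts[names(pka$pos)] / (1 + 10^(pH - pka$pos)), na.rm = TRUE)
  neg <- cterm / (1 + 10^(pka$cterm - pH)) +
    sum(counts[names(pka$neg)] / (1 + 10^(pka$neg - pH)), na.rm = TRUE)
  pos - neg
}

#' Isoelectric point by Henderson-Hasselbalch bisection
#'
#' Net charge is the Henderson-Hasselbalch sum over the free termini and the
#' ionizable side chains (D, E, C, Y, H, K, R); the pI is the pH where it
#' crosses zero, located by bisection to 0.01 pH units. `X` residues carry
#' no charge.
#'
#' @param protein A `protein_record` or sequence string.
#' @param pka_set `"emboss"` (default) or `"protparam"`.
#' @param free_termini Include the terminal charges (default `TRUE`).
#' @return pI in pH units; `NA` if the peptide has no ionizable group.
#' @export
isoelectric_point <- function(protein, pka_set = c("emboss", "protparam"),
                              free_termini = TRUE) {
  pka_set <- match.arg(pka_set)
  pka <- PKA_SETS[[pka_set]]
  protein <- as_protein_record(protein)
  chars <- strsplit(protein$sequence, "")[[1L]]
  counts <- table(factor(chars, levels = c(AA_ALPHABET, "X")))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  nt <- if (free_termini) 1 else 0
  if (nt == 0 && sum(counts[c(names(pka$pos), names(pka$neg))]) == 0)
    return(NA_real_)
  lo <- 0; hi <- 14
  f_lo <- net_charge(counts, nt, nt, pka, lo)
  f_hi <- net_charge(counts, nt, nt, pka, hi)
  if (f_lo <= 0 || f_hi >= 0) return(NA_real_)
  # converge well below the 0.01 pH reporting precision so the net charge
  # at the returned pI is negligible even for highly charged peptides
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, nt, nt, pka, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight from average residue masses
#'
#' Sum of average residue masses plus one water; unknown residues (`X`)
#' count 110 Da.
#'
#' @inheritParams isoelectric_point
#' @return Mass in Da.
#' @export
molecular_weight <- function(protein) {
  protein <- as_protein_record(protein)
  chars <- strsplit(protein$sequence, "")[[1L]]
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

# domain names recognised in the family and their normalised flags
DOMAIN_FLAGS <- c(
  "zf-RING_3" = "has_bzf", "BZF" = "has_bzf",
  "DUF1117" = "has_duf1117", "PA" = "has_pa",
  "GUB_WAK_bind" = "has_gub_wak_bind", "Rhodanese" = "has_rhodanese",
  "Asp" = "has_asp", "WAK_assoc" = "has_wak_assoc")

#' Ingest an external domain-annotation table
#'
#' Reads a TSV with columns `protein_id`, `domain_name`, `start`, `end`,
#' `score` (HMMER domtblout-like) and normalises the family's recurrent
#' domains into logical flags; unrecognised names are preserved verbatim in
#' `other_domains`. Malformed rows are skipped and counted.
#'
#' @param x Path to a TSV, or an equivalent data.frame.
#' @return data.frame keyed by `protein_id` with logical flag columns and an
#'   `other_domains` column; attribute `n_skipped` reports dropped rows.
#' @export
ingest_domain_table <- function(x) {
  if (is.character(x)) {
    x <- tryCatch(
      utils::read.delim(x, header = TRUE, stringsAsFactors = FALSE),
      error = function(e) data.frame())
  }
  flags <- unique(unname(DOMAIN_FLAGS))
  empty <- data.frame(protein_id = character(),
                      other_domains = character())
  for (f in flags) empty[[f]] <- logical()
  if (!nrow(x)) return(structure(empty, n_skipped = 0L))
  needed <- c("protein_id", "domain_name", "start", "end", "score")
  if (!all(needed %in% names(x)))
    stop("domain table must have columns: ", paste(needed, collapse = ", "))
  ok <- !is.na(x$protein_id) & nzchar(x$protein_id) &
    !is.na(x$domain_name) & nzchar(x$domain_name) &
    !is.na(suppressWarnings(as.numeric(x$start))) &
    !is.na(suppressWarnings(as.numeric(x$end)))
  n_skipped <- sum(!ok)
  if (n_skipped) message(n_skipped, " malformed domain row(s) skipped")
  x <- x[ok, , drop = FALSE]
  ids <- unique(x$protein_id)
  out <- data.frame(protein_id = ids, other_domains = "",
                    stringsAsFactors = FALSE)
  for (f in flags) out[[f]] <- FALSE
  for (i in seq_along(ids)) {
    doms <- unique(x$domain_name[x$protein_id == ids[i]])
    known <- doms %in% names(DOMAIN_FLAGS)
    for (d in doms[known]) out[[DOMAIN_FLAGS[[d]]]][i] <- TRUE
    out$other_domains[i] <- paste(doms[!known], collapse = ";")
  }
  structure(out, n_skipped = n_skipped)
}

#' Per-protein feature table
#'
#' Convenience wrapper computing length, pI, MW, hydropathy-based TM/H code
#' and GLD grade for a set of proteins.
#'
#' @param proteins data.frame with columns `id`, `sequence` (e.g. from
#'   [read_proteome()]), or a list of `protein_record`s.
#' @param window,tm_threshold,hyd_threshold,min_len Region-calling
#'   parameters, see [call_regions()].
#' @param gld_region Optional fixed `c(start, end)` GLD search region; by
#'   default the segment between the last N-terminal called region and the
#'   first RING ligand (whole sequence when neither exists).
#' @param grammar Grammar used to locate the RING domain for the GLD window.
#' @return data.frame: id, length, pi, mw, tm_h_code, gld_grade,
#'   gld_position, ring_subtype (NA when no motif).
#' @export
feature_table <- function(proteins, window = 19L, tm_threshold = 1.6,
                          hyd_threshold = 0.8, min_len = 15L,
                          gld_region = NULL, grammar = motif_grammar()) {
  proteins <- as_proteome(proteins)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    rec <- protein_record(proteins$id[i], proteins$sequence[i])
    prof <- suppressWarnings(kyte_doolittle_profile(rec, window))
    rc <- call_regions(prof, tm_threshold, hyd_threshold, min_len)
    matches <- scan_ring_h2(rec, grammar)
    ring_start <- if (length(matches)) matches[[1L]]$start else NA_integer_
    subtype <- if (length(matches)) matches[[1L]]$subtype else NA_character_
    reg <- gld_region
    if (is.null(reg)) {
      lo <- if (nrow(rc$regions)) max(rc$regions$end) + 1L else 1L
      hi <- if (!is.na(ring_start)) ring_start - 1L else nchar(rec$sequence)
      reg <- c(lo, hi)
    }
    gld <- grade_gld(rec, reg)
    data.frame(id = rec$id, length = nchar(rec$sequence),
               pi = isoelectric_point(rec), mw = molecular_weight(rec),
               tm_h_code = rc$tm_h_code, gld_grade = gld$grade,
               gld_position = gld$position, ring_subtype = subtype,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
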