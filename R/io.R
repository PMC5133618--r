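# File-format plumbing: FASTA via Biostrings, 12-column BLAST-like tabular
# homology hits, and small TSV writers shared across the pipeline stages.

#' Read a protein FASTA file
#'
#' @param path Multi-record FASTA (wrapped or single-line).
#' @return data.frame with columns `id`, `sequence`, `description`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- names(aa)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (anyDuplicated(id))
    stop("duplicate sequence ids in ", path)
  data.frame(id = id, sequence = as.character(aa), description = desc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteins data.frame with `id`, `sequence` and optional
#'   `description`, or a list of `protein_record`s.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_proteome <- function(proteins, path, width = 60L) {
  proteins <- as_proteome(proteins)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  desc <- proteins$description
  names(aa) <- ifelse(!is.null(desc) & nzchar(desc),
                      paste(proteins$id, desc), proteins$id)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

as_proteome <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    if (is.null(x$description)) x$description <- ""
    return(x)
  }
  if (inherits(x, "protein_record")) x <- list(x)
  data.frame(id = vapply(x, `[[`, character(1L), "id"),
             sequence = vapply(x, `[[`, character(1L), "sequence"),
             description = vapply(x, `[[`, character(1L), "description"),
             stringsAsFactors = FALSE)
}

BLAST_TAB_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read 12-column tabular homology hits
#'
#' Standard BLAST outfmt-6 layout: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. A header line is
#' detected and skipped.
#'
#' @param path TSV path.
#' @return data.frame with the twelve standard columns.
#' @export
read_blast_tab <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("qseqid", first, fixed = TRUE)) 1L else 0L
  df <- utils::read.delim(path, header = FALSE, skip = skip,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 12L)
    stop("expected 12 tab-separated columns, got ", ncol(df))
  names(df) <- BLAST_TAB_COLS
  for (col in c("pident", "evalue", "bitscore")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write 12-column tabular homology hits
#'
#' @param hits data.frame with the columns of [read_blast_tab()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits[, BLAST_TAB_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA of equal-length aligned sequences.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  if (length(unique(nchar(out))) > 1L)
    stop("aligned sequences must have equal length")
  out
}

#' Write an aligned FASTA file
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(alignment)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
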