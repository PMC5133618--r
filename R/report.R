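# Family report: the packaged 96-member grapevine ATL reference table,
# summary statistics, and the end-to-end pipeline orchestrator.

# md5 of the verbatim-transcribed reference table; the fixture is immutable
TABLE1_MD5 <- "966b3ac594432924215cc81379c0109a"

#' Load the packaged grapevine ATL family reference table
#'
#' The 96-member grapevine (Vitis vinifera) ATL family with its published
#' per-gene annotation: gene/protein lengths, intron counts, RING-H2
#' subtype (PC/PxC), the TM/hydrophobic code (an integer counts
#' transmembrane segments, 0.5 flags one or more hydrophobic regions, 0
#' neither) and additional domains. The chromosome is derived from the
#' VIT_ locus identifier (`VIT_09s...` is chr9; `VIT_00s...` is the
#' unplaced chrUn). The file is checksum-guarded: any modification is an
#' error.
#'
#' @return data.frame of class `family_table`, one row per member, with
#'   columns name, synonym, gene_id, gene_length_bp, intron_count,
#'   uniprot_id, protein_length_aa, ring_subtype, tm_h_code (numeric; 0.5
#'   preserved), domains, chromosome, has_bzf, has_duf1117.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "vviatl_family_table.tsv",
                      package = "ringfam", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE1_MD5))
    stop("family table fixture checksum mismatch (", md5,
         "); the fixture is immutable")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$gene_length_bp <- as.integer(df$gene_length_bp)
  df$intron_count <- as.integer(df$intron_count)
  df$protein_length_aa <- as.integer(df$protein_length_aa)
  df$tm_h_code <- as.numeric(df$tm_h_code)
  df$domains[is.na(df$domains)] <- ""
  chr_num <- sub("^VIT_(\\d\\d)s.*$", "\\1", df$gene_id)
  df$chromosome <- ifelse(chr_num == "00", "chrUn",
                          paste0("chr", as.integer(chr_num)))
  df$has_bzf <- grepl("zf-RING_3", df$domains, fixed = TRUE)
  df$has_duf1117 <- grepl("DUF1117", df$domains, fixed = TRUE)
  class(df) <- c("family_table", class(df))
  df
}

#' Summarise a family member table
#'
#' Computes the family-level counts: size, BZF and DUF1117 domains,
#' members with transmembrane segments, members with hydrophobic regions
#' only, members with no N-terminal feature, the mutually exclusive
#' N-terminal category partition, intron-structure fractions and (when a
#' `mode` column is present) duplication-mode counts.
#'
#' @param members A `family_table` (see [load_table1_fixture()]) or any
#'   data.frame with columns ring_subtype, tm_h_code and either logical
#'   `has_bzf` or a `domains` string column.
#' @return List of class `family_summary`.
#' @export
summarize_family <- function(members) {
  stopifnot(nrow(members) >= 1L)
  if (is.null(members$has_bzf))
    members$has_bzf <- grepl("zf-RING_3", members$domains, fixed = TRUE)
  tm <- as.numeric(members$tm_h_code)
  categories <- vapply(seq_len(nrow(members)), function(i)
    classify_family_member(members$ring_subtype[i], tm[i],
                           members$has_bzf[i]), character(1L))
  cat_counts <- table(factor(categories, levels = c(
    "TM_PxC", "BZF_PC", "Hyd_PC", "BZF_Hyd_PC", "NoNterm")))
  out <- list(
    family_size = nrow(members),
    n_bzf = sum(members$has_bzf),
    n_duf1117 = if (!is.null(members$has_duf1117)) sum(members$has_duf1117)
      else sum(grepl("DUF1117", members$domains, fixed = TRUE)),
    n_tm = sum(tm >= 1),
    n_hydrophobic_only = sum(tm == 0.5),
    n_no_nterm = sum(tm == 0 & !members$has_bzf),
    category_counts = cat_counts,
    intronless_fraction = if (!is.null(members$intron_count))
      mean(members$intron_count == 0L) else NA_real_,
    intron0to3_fraction = if (!is.null(members$intron_count))
      mean(members$intron_count <= 3L) else NA_real_,
    duplication_counts = if (!is.null(members$mode))
      table(members$mode) else NULL)
  class(out) <- "family_summary"
  out
}

#' @export
print.family_summary <- function(x, ...) {
  cat("Family summary\n")
  cat(sprintf("  members: %d\n", x$family_size))
  cat(sprintf("  BZF (zf-RING_3): %d | DUF1117: %d\n", x$n_bzf, x$n_duf1117))
  cat(sprintf("  TM-bearing: %d | hydrophobic-only: %d | no N-terminal: %d\n",
              x$n_tm, x$n_hydrophobic_only, x$n_no_nterm))
  cat("  N-terminal categories (mutually exclusive):\n")
  print(x$category_counts)
  if (!is.na(x$intronless_fraction))
    cat(sprintf("  intronless: %.1f%% | 0-3 introns: %.1f%%\n",
                100 * x$intronless_fraction, 100 * x$intron0to3_fraction))
  if (!is.null(x$duplication_counts)) {
    cat("  duplication modes:\n")
    print(x$duplication_counts)
  }
  invisible(x)
}

#' Run the full annotation pipeline
#'
#' Executes the stages scan -> features -> genome -> naming -> expression
#' -> report on the inputs named in `config`, writing each stage's TSV and
#' a run log into `out_dir`. Stages whose inputs are absent are skipped.
#' A failing stage halts the run with the stage name.
#'
#' @param config Named list (or path to a flat `key = value` text file)
#'   with any of: `proteome_fasta`, `domain_tsv`, `gff3`, `hits_tsv`,
#'   `tree_newick`, `expr_tsv`, `de_tsv`, `out_dir` (required), `seed`
#'   (required when the Mantel/expression stage runs), plus optional
#'   stage parameters (`k`, `evalue_max`, `max_gap_rank`,
#'   `min_block_size`, `tandem_max_rank_gap`, `proximal_max_rank_gap`,
#'   `lfc_min`, `fdr_max`, `min_conditions`, `n_perm`, `cut_k`).
#' @return Invisible list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- lapply(read_key_value(config), utils::type.convert,
                     as.is = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  log_lines <- c(sprintf("ringfam %s | R %s",
                         as.character(utils::packageVersion("ringfam")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config: %s", paste(names(config), unlist(lapply(
                   config, paste, collapse = ",")), sep = "=",
                   collapse = " ")))
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$expr_tsv) || !is.null(config$de_tsv)) {
    if (is.null(config$seed))
      stop("config must name a seed when the expression stage ",
           "(Mantel permutations) is enabled")
  }

  proteins <- NULL
  if (!is.null(config$proteome_fasta)) {
    results$scan <- stage("scan", {
      proteins <- read_proteome(config$proteome_fasta)
      matches <- unlist(lapply(seq_len(nrow(proteins)), function(i)
        scan_ring_h2(protein_record(proteins$id[i], proteins$sequence[i]))),
        recursive = FALSE)
      tab <- match_table(matches)
      write_tsv(tab, file.path(out_dir, "scan.tsv"))
      tab
    })
    results$features <- stage("features", {
      ft <- feature_table(proteins)
      if (!is.null(config$domain_tsv)) {
        dom <- ingest_domain_table(config$domain_tsv)
        ft <- merge(ft, dom, by.x = "id", by.y = "protein_id",
                    all.x = TRUE)
        for (fcol in grep("^has_", names(ft), value = TRUE))
          ft[[fcol]][is.na(ft[[fcol]])] <- FALSE
      }
      write_tsv(ft, file.path(out_dir, "features.tsv"))
      ft
    })
  }

  models <- NULL
  if (!is.null(config$gff3)) {
    results$genome <- stage("genome", {
      models <- parse_gene_models(config$gff3)
      res <- list(models = models)
      if (!is.null(config$hits_tsv)) {
        hits <- top_k_hits(read_blast_tab(config$hits_tsv),
                           k = prm("k", 5L),
                           evalue_max = prm("evalue_max", 1e-5))
        blocks <- chain_collinear_blocks(
          hits, models, max_gap_rank = prm("max_gap_rank", 25L),
          min_block_size = prm("min_block_size", 5L))
        calls <- classify_duplications(
          hits, models, blocks,
          tandem_max_rank_gap = prm("tandem_max_rank_gap", 1L),
          proximal_max_rank_gap = prm("proximal_max_rank_gap", 10L))
        write_tsv(calls, file.path(out_dir, "duplications.tsv"))
        block_tab <- do.call(rbind, lapply(seq_along(blocks), function(i)
          cbind(block = i, blocks[[i]]$anchors)))
        if (!is.null(block_tab))
          write_tsv(block_tab, file.path(out_dir, "blocks.tsv"))
        res$duplications <- calls
        res$blocks <- blocks
      }
      gene_tab <- models
      gene_tab$exons <- NULL
      write_tsv(gene_tab, file.path(out_dir, "gene_models.tsv"))
      res
    })
    models <- results$genome$models
  }

  if (!is.null(config$tree_newick)) {
    results$naming <- stage("naming", {
      tree <- ape::read.tree(config$tree_newick)
      nm <- assign_names(tree)
      write_name_map(nm, file.path(out_dir, "names.tsv"))
      nm
    })
  }

  if (!is.null(config$expr_tsv)) {
    results$expression <- stage("expression", {
      m <- read_expression_matrix(config$expr_tsv)
      centred <- median_center(m)
      hc <- hcluster(centred, k = prm("cut_k", 5L))
      cl <- data.frame(gene = names(hc$clusters), cluster = hc$clusters,
                       order = match(seq_along(hc$clusters), hc$tree$order),
                       row.names = NULL)
      write_tsv(cl, file.path(out_dir, "expression_clusters.tsv"))
      res <- list(clusters = hc)
      if (!is.null(config$de_tsv)) {
        de <- read_de_table(config$de_tsv)
        fl <- flag_responsive(de, lfc_min = prm("lfc_min", 0.5),
                              fdr_max = prm("fdr_max", 0.05),
                              min_conditions = prm("min_conditions", 2L))
        write_tsv(fl, file.path(out_dir, "responsive.tsv"))
        res$responsive <- fl
      }
      co <- coexpression_matrix(centred)
      dist_expr <- 1 - co
      diag(dist_expr) <- 0
      res$coexpression <- co
      res
    })
  }

  log_lines <- c(log_lines, paste("stages run:",
                                  paste(names(results), collapse = ", ")),
                 sprintf("seed: %s", prm("seed", "none")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
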