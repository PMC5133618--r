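# Genomic context: gene models from GFF3, top-k homology filtering,
# collinear block chaining by dynamic programming, duplication-mode
# classification and retention-enrichment testing.

#' Parse gene models from a GFF3 file
#'
#' One model per gene, using its longest mRNA (by summed exon width; ties
#' broken by feature order). Genes are ranked along each chromosome by
#' start coordinate; intron count is exon count minus one.
#'
#' @param path GFF3 file with gene/mRNA/exon features (1-based inclusive
#'   coordinates).
#' @return data.frame of class `gene_models`: gene_id, chromosome, strand,
#'   start, end, n_exons, intron_count, rank, and a list-column `exons`
#'   of two-column (start, end) matrices.
#' @export
parse_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  first_parent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, nrow(df)))
    vapply(as.list(p), function(x)
      if (length(x)) as.character(x)[1L] else NA_character_, character(1L))
  }
  df$parent1 <- first_parent(df$Parent)

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  orphans <- sum(!is.na(mrnas$parent1) & !(mrnas$parent1 %in% genes$ID)) +
    sum(!is.na(exons$parent1) & !(exons$parent1 %in% mrnas$ID))
  if (orphans) message(orphans, " feature(s) with missing parent links skipped")

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    mr <- mrnas[!is.na(mrnas$parent1) & mrnas$parent1 == g$ID, , drop = FALSE]
    if (nrow(mr) == 0L) {
      warning("gene '", g$ID, "' has no mRNA; using gene span as one exon")
      ex <- cbind(start = g$start, end = g$end)
    } else {
      ex_by_mrna <- lapply(mr$ID, function(mid) {
        e <- exons[!is.na(exons$parent1) & exons$parent1 == mid, , drop = FALSE]
        if (nrow(e) == 0L) NULL else unname(cbind(e$start, e$end))
      })
      widths <- vapply(seq_along(ex_by_mrna), function(k) {
        e <- ex_by_mrna[[k]]
        if (is.null(e)) mr$end[k] - mr$start[k] + 1L
        else sum(e[, 2L] - e[, 1L] + 1L)
      }, numeric(1L))
      best <- which.max(widths)
      ex <- ex_by_mrna[[best]]
      if (is.null(ex)) {
        warning("mRNA '", mr$ID[best], "' has no exons; single-exon model")
        ex <- cbind(mr$start[best], mr$end[best])
      }
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
      colnames(ex) <- c("start", "end")
    }
    list(gene_id = g$ID, chromosome = g$seqnames, strand = g$strand,
         start = g$start, end = g$end, n_exons = nrow(ex),
         intron_count = nrow(ex) - 1L, exons = ex)
  })
  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1L), "gene_id"),
    chromosome = vapply(rows, `[[`, character(1L), "chromosome"),
    strand = vapply(rows, `[[`, character(1L), "strand"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1L)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1L)),
    n_exons = vapply(rows, function(r) as.integer(r$n_exons), integer(1L)),
    intron_count = vapply(rows, function(r) as.integer(r$intron_count), integer(1L)),
    stringsAsFactors = FALSE)
  out$exons <- I(lapply(rows, `[[`, "exons"))
  out <- out[order(out$chromosome, out$start, out$gene_id), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$chromosome,
                         FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("gene_models", class(out))
  out
}

normalize_hits <- function(hits) {
  if (all(c("qseqid", "sseqid") %in% names(hits))) {
    data.frame(query_id = hits$qseqid, subject_id = hits$sseqid,
               bitscore = hits$bitscore, evalue = hits$evalue,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("query_id", "subject_id") %in% names(hits)))
    hits
  }
}

#' Retain the best k non-self homology hits per query
#'
#' Self-hits are removed, hits above the E-value threshold discarded, and
#' per query the k highest bitscores retained (ties broken by
#' lexicographically smaller subject id). Multiple HSPs for the same pair
#' collapse to the best-scoring one first.
#'
#' @param raw_hits data.frame from [read_blast_tab()] (or with columns
#'   query_id, subject_id, bitscore, evalue).
#' @param k Hits kept per query (default 5).
#' @param evalue_max E-value threshold (default 1e-5).
#' @return data.frame query_id, subject_id, bitscore, evalue.
#' @export
top_k_hits <- function(raw_hits, k = 5L, evalue_max = 1e-5) {
  stopifnot(k >= 1L)
  h <- normalize_hits(raw_hits)
  h <- h[h$query_id != h$subject_id & h$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(h)) return(h[0L, ])
  # best HSP per (query, subject) pair
  h <- h[order(h$query_id, h$subject_id, -h$bitscore), , drop = FALSE]
  h <- h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
  h <- h[order(h$query_id, -h$bitscore, h$subject_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$query_id), function(ix)
    ix[seq_len(min(k, length(ix)))]), use.names = FALSE)
  out <- h[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest chain of anchors under a rank-gap constraint; returns indices of
# the lexicographically smallest maximum-length chain (anchors must be
# sorted by ra, then rb).
best_chain <- function(ra, rb, max_gap, reversed = FALSE) {
  n <- length(ra)
  if (!n) return(integer())
  can_follow <- function(i, j) { # anchor j after anchor i
    dga <- ra[j] - ra[i]
    if (dga < 1L || dga > max_gap) return(FALSE)
    dgb <- if (reversed) rb[i] - rb[j] else rb[j] - rb[i]
    dgb >= 1L && dgb <= max_gap
  }
  F <- rep(1L, n)
  for (i in n:1L) {
    for (j in seq_len(n)[-seq_len(i)]) {
      if (can_follow(i, j) && F[j] + 1L > F[i]) F[i] <- F[j] + 1L
    }
  }
  maxlen <- max(F)
  chain <- integer(maxlen)
  cur <- which(F == maxlen)[1L]
  chain[1L] <- cur
  if (maxlen > 1L) for (step in 2L:maxlen) {
    nxt <- Filter(function(j) can_follow(cur, j) && F[j] == maxlen - step + 1L,
                  seq_len(length(ra))[-seq_len(cur)])
    cur <- nxt[[1L]]
    chain[step] <- cur
  }
  chain
}

#' Chain collinear blocks from homology hits
#'
#' For every chromosome pair, anchors (homologous gene pairs, positioned by
#' gene rank along each chromosome) are chained by dynamic programming into
#' maximal-scoring runs whose rank gaps do not exceed `max_gap_rank` on
#' either axis, in both orientations. Blocks are extracted greedily from
#' the highest-scoring chain down, without anchor reuse, and reported when
#' they contain at least `min_block_size` anchors.
#'
#' @param hits Filtered homology hits (see [top_k_hits()]).
#' @param gene_models A `gene_models` table from [parse_gene_models()].
#' @param max_gap_rank Maximum rank gap between consecutive anchors
#'   (default 25).
#' @param min_block_size Minimum anchors per reported block (default 5).
#' @param unplaced Chromosome names treated as unplaced (no rank geometry).
#' @return List of blocks; each is a list with `chr_a`, `chr_b`,
#'   `orientation` (`"forward"`/`"reverse"`), `anchors` (data.frame gene_a,
#'   gene_b, rank_a, rank_b) and `score` (anchor count).
#' @export
chain_collinear_blocks <- function(hits, gene_models, max_gap_rank = 25L,
                                   min_block_size = 5L, unplaced = "chrUn") {
  h <- normalize_hits(hits)
  gm <- gene_models
  idx <- match(c(h$query_id, h$subject_id), gm$gene_id)
  if (anyNA(idx)) stop("hit gene(s) absent from gene models")
  chr <- stats::setNames(gm$chromosome, gm$gene_id)
  rnk <- stats::setNames(gm$rank, gm$gene_id)

  a <- h$query_id; b <- h$subject_id
  placed <- !(chr[a] %in% unplaced) & !(chr[b] %in% unplaced)
  a <- a[placed]; b <- b[placed]
  if (!length(a)) return(list())
  # orient each pair so (chr, rank) of side A <= side B; dedupe
  swap <- chr[a] > chr[b] | (chr[a] == chr[b] & rnk[a] > rnk[b])
  ga <- ifelse(swap, b, a); gb <- ifelse(swap, a, b)
  self_anchor <- ga == gb
  ga <- ga[!self_anchor]; gb <- gb[!self_anchor]
  key <- paste(ga, gb)
  ga <- ga[!duplicated(key)]; gb <- gb[!duplicated(key)]

  anchors <- data.frame(gene_a = ga, gene_b = gb,
                        chr_a = unname(chr[ga]), chr_b = unname(chr[gb]),
                        rank_a = unname(rnk[ga]), rank_b = unname(rnk[gb]),
                        stringsAsFactors = FALSE)
  blocks <- list()
  for (pair in split(anchors, paste(anchors$chr_a, anchors$chr_b))) {
    pair <- pair[order(pair$rank_a, pair$rank_b), , drop = FALSE]
    avail <- rep(TRUE, nrow(pair))
    repeat {
      ix <- which(avail)
      if (length(ix) < min_block_size) break
      fwd <- best_chain(pair$rank_a[ix], pair$rank_b[ix], max_gap_rank, FALSE)
      rev_ <- best_chain(pair$rank_a[ix], pair$rank_b[ix], max_gap_rank, TRUE)
      use_fwd <- length(fwd) >= length(rev_)
      chain <- ix[if (use_fwd) fwd else rev_]
      if (length(chain) < min_block_size) break
      blocks[[length(blocks) + 1L]] <- list(
        chr_a = pair$chr_a[1L], chr_b = pair$chr_b[1L],
        orientation = if (use_fwd) "forward" else "reverse",
        anchors = data.frame(gene_a = pair$gene_a[chain],
                             gene_b = pair$gene_b[chain],
                             rank_a = pair$rank_a[chain],
                             rank_b = pair$rank_b[chain],
                             stringsAsFactors = FALSE),
        score = length(chain))
      avail[chain] <- FALSE
    }
  }
  blocks
}

#' Classify the duplication mode of each gene
#'
#' Precedence: a gene participating in any collinear block anchor is
#' `segmental_wgd`; otherwise a paralog at rank distance at most
#' `tandem_max_rank_gap` on the same chromosome makes it `tandem`; at most
#' `proximal_max_rank_gap`, `proximal`; any remaining paralog, `dispersed`;
#' no paralog at all, `singleton`. Genes on unplaced scaffolds have no rank
#' geometry and can only be dispersed or singleton.
#'
#' @inheritParams chain_collinear_blocks
#' @param blocks Output of [chain_collinear_blocks()].
#' @param tandem_max_rank_gap Rank window for tandem calls (default 1).
#' @param proximal_max_rank_gap Rank window for proximal calls (default 10).
#' @return data.frame gene_id, mode for every gene in `gene_models`.
#' @export
classify_duplications <- function(hits, gene_models, blocks,
                                  tandem_max_rank_gap = 1L,
                                  proximal_max_rank_gap = 10L,
                                  unplaced = "chrUn") {
  h <- normalize_hits(hits)
  gm <- gene_models
  if (!all(c(h$query_id, h$subject_id) %in% gm$gene_id))
    stop("hit gene(s) absent from gene models")
  chr <- stats::setNames(gm$chromosome, gm$gene_id)
  rnk <- stats::setNames(gm$rank, gm$gene_id)

  partners <- list()
  add_edge <- function(x, y) {
    partners[[x]] <<- union(partners[[x]], y)
    partners[[y]] <<- union(partners[[y]], x)
  }
  for (i in seq_len(nrow(h))) add_edge(h$query_id[i], h$subject_id[i])

  in_block <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))

  mode <- vapply(gm$gene_id, function(g) {
    if (g %in% in_block) return("segmental_wgd")
    ps <- setdiff(partners[[g]], g)
    if (!length(ps)) return("singleton")
    if (!(chr[g] %in% unplaced)) {
      same <- ps[chr[ps] == chr[g] & !(chr[ps] %in% unplaced)]
      if (length(same)) {
        gap <- abs(rnk[same] - rnk[g])
        if (any(gap <= tandem_max_rank_gap)) return("tandem")
        if (any(gap <= proximal_max_rank_gap)) return("proximal")
      }
    }
    "dispersed"
  }, character(1L))
  data.frame(gene_id = gm$gene_id, mode = unname(mode),
             stringsAsFactors = FALSE)
}

#' Duplication-mode retention enrichment
#'
#' Per mode, a 2 x 2 table (family vs background) x (mode vs other modes)
#' is tested with a two-sided Fisher's exact test; p-values are
#' Bonferroni-adjusted by the number of modes tested. Zero-margin tables
#' report p = 1 and are flagged.
#'
#' @param family_modes Character vector of modes for the gene family.
#' @param background_modes Character vector of modes for the rest of the
#'   genome (the comparison set).
#' @return data.frame: mode, family_count, background_count, odds_ratio
#'   (sample odds ratio), p_value, p_adj, degenerate flag.
#' @export
retention_enrichment <- function(family_modes, background_modes) {
  modes <- sort(unique(c(family_modes, background_modes)))
  res <- lapply(modes, function(m) {
    a <- sum(family_modes == m); b <- sum(family_modes != m)
    c_ <- sum(background_modes == m); d <- sum(background_modes != m)
    tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    p <- if (degenerate) 1.0 else
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    if (a == 0 && c_ == 0) or <- NaN
    data.frame(mode = m, family_count = a, background_count = c_,
               odds_ratio = or, p_value = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_value * length(modes))
  out[, c("mode", "family_count", "background_count", "odds_ratio",
          "p_value", "p_adj", "degenerate")]
}
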