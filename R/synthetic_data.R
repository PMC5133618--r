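# Seeded synthetic-data generators with exact ground truth for every
# pipeline stage: proteomes with planted RING-H2 motifs and single-
# violation decoys, genomes with planted duplication architectures, and
# expression matrices with planted organ clusters and condition effects.

sample_aa <- function(n, exclude = character(0L)) {
  pool <- setdiff(AA_ALPHABET, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Assemble one RING-H2 motif string for a subtype and spacer draw.
# Returns the motif string plus ligand offsets (1-based within the motif).
build_motif <- function(subtype, n1, n2) {
  g2 <- if (subtype == "PxC") {
    paste0(sample_aa(n1), "P", sample_aa(1L, exclude = "P"))
  } else {
    paste0(sample_aa(n1 + 1L), "P")
  }
  parts <- c("C", sample_aa(2L), "C", g2, "C", sample_aa(1L), "H",
             sample_aa(2L), "H", sample_aa(2L), "C", sample_aa(3L), "W",
             sample_aa(n2), "C", sample_aa(2L), "C", "W")
  motif <- paste(parts, collapse = "")
  gaps <- c(2L, n1 + 2L, 1L, 2L, 2L, n2 + 4L, 2L)
  ligands <- cumsum(c(1L, gaps + 1L))
  list(motif = motif, ligands = ligands)
}

#' Generate a synthetic proteome with planted RING-H2 motifs
#'
#' ATL records embed PxC-grammar motifs, BTL records PC-grammar motifs
#' (annotated with a BZF placeholder), and decoys violate exactly one
#' grammar constraint each (a mutated ligand, an out-of-range spacer, or a
#' missing post-C6 tryptophan). Decoys are rejection-sampled until the
#' scanner finds no match anywhere in the record, so planted truth is
#' exact. Output is byte-reproducible from (parameters, seed).
#'
#' @param n_atl,n_btl,n_decoys Record counts (>= 0).
#' @param spacer_dist List with integer vectors `n1`, `n2`: candidate
#'   lengths for the two variable spacers (defaults 4--30, the grammar
#'   bounds). Values outside the grammar bounds are an error.
#' @param seed RNG seed.
#' @param grammar Grammar the planted motifs must satisfy (default
#'   [motif_grammar()]).
#' @param flank_range Range of random flank lengths on each side.
#' @param out_dir Optional directory; writes `proteome.fasta` and
#'   `truth.json`.
#' @return List: `proteome` (data.frame id, sequence, description) and
#'   `truth` (data.frame id, class, motif_start, ligand_positions, subtype,
#'   decoy_violation).
#' @export
gen_proteome <- function(n_atl, n_btl, n_decoys,
                         spacer_dist = list(n1 = 4:30, n2 = 4:30),
                         seed = 1L, grammar = motif_grammar(),
                         flank_range = c(20L, 80L), out_dir = NULL) {
  stopifnot(n_atl >= 0L, n_btl >= 0L, n_decoys >= 0L)
  n1_ok <- (grammar$spacer_ranges[2L, 1L] - 2L):(grammar$spacer_ranges[2L, 2L] - 2L)
  n2_ok <- (grammar$spacer_ranges[6L, 1L] - 4L):(grammar$spacer_ranges[6L, 2L] - 4L)
  if (!all(spacer_dist$n1 %in% n1_ok) || !all(spacer_dist$n2 %in% n2_ok))
    stop("spacer_dist outside grammar bounds")
  set.seed(seed)

  plant <- function(id, subtype, desc) {
    repeat {
      n1 <- sample(rep(spacer_dist$n1, 2L), 1L)
      n2 <- sample(rep(spacer_dist$n2, 2L), 1L)
      bm <- build_motif(subtype, n1, n2)
      nf <- sample(flank_range[1L]:flank_range[2L], 1L)
      cf <- sample(flank_range[1L]:flank_range[2L], 1L)
      seqn <- paste0(sample_aa(nf), bm$motif, sample_aa(cf))
      rec <- protein_record(id, seqn, desc)
      hits <- scan_ring_h2(rec, grammar)
      planted <- bm$ligands + nf
      found <- any(vapply(hits, function(h)
        identical(h$ligand_positions, planted) && h$subtype == subtype,
        logical(1L)))
      if (found)
        return(list(rec = rec, start = planted[1L], ligands = planted,
                    subtype = subtype))
    }
  }

  make_decoy <- function(id) {
    repeat {
      violation <- sample(c("ligand_substitution", "spacer_out_of_range",
                            "missing_w"), 1L)
      subtype <- sample(c("PxC", "PC"), 1L)
      n1 <- sample(rep(spacer_dist$n1, 2L), 1L)
      n2 <- sample(rep(spacer_dist$n2, 2L), 1L)
      if (violation == "spacer_out_of_range")
        n1 <- max(n1_ok) + 3L
      bm <- build_motif(subtype, n1, n2)
      chars <- strsplit(bm$motif, "")[[1L]]
      if (violation == "ligand_substitution")
        chars[sample(bm$ligands, 1L)] <- "A"
      if (violation == "missing_w")
        chars[bm$ligands[6L] + 4L] <- "A"
      nf <- sample(flank_range[1L]:flank_range[2L], 1L)
      cf <- sample(flank_range[1L]:flank_range[2L], 1L)
      seqn <- paste0(sample_aa(nf), paste(chars, collapse = ""), sample_aa(cf))
      rec <- protein_record(id, seqn, "decoy")
      if (length(scan_ring_h2(rec, grammar)) == 0L)
        return(list(rec = rec, violation = violation))
    }
  }

  recs <- list(); truth <- list()
  for (i in seq_len(n_atl)) {
    p <- plant(sprintf("ATL_SYN_%03d", i), "PxC", "synthetic ATL")
    recs[[length(recs) + 1L]] <- p$rec
    truth[[length(truth) + 1L]] <- data.frame(
      id = p$rec$id, class = "ATL", motif_start = p$start,
      ligand_positions = paste(p$ligands, collapse = ","),
      subtype = "PxC", decoy_violation = NA_character_)
  }
  for (i in seq_len(n_btl)) {
    p <- plant(sprintf("BTL_SYN_%03d", i), "PC",
               "synthetic BTL; N-terminal BZF placeholder")
    recs[[length(recs) + 1L]] <- p$rec
    truth[[length(truth) + 1L]] <- data.frame(
      id = p$rec$id, class = "BTL", motif_start = p$start,
      ligand_positions = paste(p$ligands, collapse = ","),
      subtype = "PC", decoy_violation = NA_character_)
  }
  for (i in seq_len(n_decoys)) {
    d <- make_decoy(sprintf("DECOY_SYN_%03d", i))
    recs[[length(recs) + 1L]] <- d$rec
    truth[[length(truth) + 1L]] <- data.frame(
      id = d$rec$id, class = "decoy", motif_start = NA_integer_,
      ligand_positions = NA_character_, subtype = NA_character_,
      decoy_violation = d$violation)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), class = character(),
               motif_start = integer(), ligand_positions = character(),
               subtype = character(), decoy_violation = character())
  out <- list(proteome = as_proteome(recs), truth = truth, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_proteome(out$proteome, file.path(out_dir, "proteome.fasta"))
    jsonlite::write_json(truth, file.path(out_dir, "proteome_truth.json"),
                         dataframe = "rows", na = "null")
  }
  out
}

#' Generate a synthetic genome with planted duplication architecture
#'
#' Lays `n_genes` across `n_chromosomes`, plants whole-genome-duplication
#' pairs as collinear runs of at least `min_block_size` consecutive anchors
#' (chr1 vs chr2), tandem pairs as rank-adjacent genes, proximal pairs
#' within the proximal rank window, and dispersed pairs across chromosome
#' pairs that cannot accumulate enough anchors to chain into a block. The
#' homology table carries the implied paralog hits plus uniform noise hits
#' whose E-values exceed the default retention threshold, so the planted
#' truth is exact after standard filtering.
#'
#' @param n_genes Total genes.
#' @param n_wgd_pairs,n_tandem,n_proximal,n_dispersed Planted pair counts.
#' @param intron_dist Function(n) returning n intron counts (default
#'   geometric with mean 1, capped at 10).
#' @param seed RNG seed.
#' @param n_chromosomes Number of chromosomes (default 4).
#' @param min_block_size,max_gap_rank,proximal_max_rank_gap Geometry
#'   parameters mirrored from the classifier defaults.
#' @param noise_frac Noise hits as a fraction of `n_genes` (default 0.25).
#' @param out_dir Optional directory; writes `genome.gff3`, `hits.tsv` and
#'   `genome_truth.json`.
#' @return List: `gff` (character lines), `hits` (12-column data.frame),
#'   `truth` (list with `modes` data.frame, `pairs`, `blocks`,
#'   `intron_counts`).
#' @export
gen_genome <- function(n_genes = 200L, n_wgd_pairs = 10L, n_tandem = 4L,
                       n_proximal = 1L, n_dispersed = 6L,
                       intron_dist = function(n) pmin(stats::rgeom(n, 0.5), 10L),
                       seed = 1L, n_chromosomes = 4L,
                       min_block_size = 5L, max_gap_rank = 25L,
                       proximal_max_rank_gap = 10L, noise_frac = 0.25,
                       out_dir = NULL) {
  n_pair_genes <- 2L * (n_wgd_pairs + n_tandem + n_proximal + n_dispersed)
  if (n_pair_genes > n_genes)
    stop("planted pairs require more genes than n_genes")
  if (n_chromosomes < 4L) stop("at least 4 chromosomes required")
  if (n_wgd_pairs > 0L && n_wgd_pairs < min_block_size)
    stop("n_wgd_pairs below min_block_size cannot form a collinear block")
  set.seed(seed)

  chr_names <- paste0("chr", seq_len(n_chromosomes))
  sizes <- rep(n_genes %/% n_chromosomes, n_chromosomes)
  extra <- n_genes %% n_chromosomes
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  free <- lapply(sizes, function(s) rep(TRUE, s))
  names(free) <- chr_names

  take <- function(chr, ranks) {
    if (any(ranks > length(free[[chr]])) || !all(free[[chr]][ranks]))
      stop("infeasible layout: not enough free ranks on ", chr)
    free[[chr]][ranks] <<- FALSE
    ranks
  }

  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      mode = character(), stringsAsFactors = FALSE)
  slot <- function(chr, rank) paste0(chr, ":", rank)
  pair_slots <- list()
  add_pair <- function(sa, sb, mode) {
    pair_slots[[length(pair_slots) + 1L]] <<- list(a = sa, b = sb, mode = mode)
  }

  # WGD blocks: runs of consecutive anchors chr1 vs chr2, spaced by more
  # than max_gap_rank so separate blocks never chain together.
  block_defs <- list()
  if (n_wgd_pairs > 0L) {
    n_blocks <- n_wgd_pairs %/% min_block_size
    bsizes <- rep(min_block_size, n_blocks)
    rem <- n_wgd_pairs - sum(bsizes)
    if (rem > 0L) bsizes[n_blocks] <- bsizes[n_blocks] + rem
    start_a <- 1L + sample(0:2, 1L)
    start_b <- 1L + sample(0:2, 1L)
    for (bs in bsizes) {
      ra <- take("chr1", start_a:(start_a + bs - 1L))
      rb <- take("chr2", start_b:(start_b + bs - 1L))
      block_defs[[length(block_defs) + 1L]] <-
        list(chr_a = "chr1", chr_b = "chr2", rank_a = ra, rank_b = rb)
      for (i in seq_len(bs))
        add_pair(slot("chr1", ra[i]), slot("chr2", rb[i]), "segmental_wgd")
      start_a <- start_a + bs + max_gap_rank + 1L + sample(0:2, 1L)
      start_b <- start_b + bs + max_gap_rank + 1L + sample(0:2, 1L)
    }
  }

  # tandem: adjacent free ranks, chromosomes round-robin
  rr <- rep(chr_names, length.out = max(n_tandem, 1L))
  for (i in seq_len(n_tandem)) {
    chr <- rr[i]
    cand <- which(free[[chr]][-length(free[[chr]])] &
                  free[[chr]][-1L])
    if (!length(cand)) stop("infeasible layout: no adjacent free ranks")
    r <- cand[sample(length(cand), 1L)]
    take(chr, c(r, r + 1L))
    add_pair(slot(chr, r), slot(chr, r + 1L), "tandem")
  }

  # proximal: same chromosome, rank gap in (1, proximal_max_rank_gap]
  for (i in seq_len(n_proximal)) {
    placed <- FALSE
    for (chr in sample(chr_names)) {
      gaps <- sample(2:proximal_max_rank_gap)
      for (g in gaps) {
        cand <- which(utils::head(free[[chr]], -g) &
                      utils::tail(free[[chr]], -g))
        if (length(cand)) {
          r <- cand[sample(length(cand), 1L)]
          take(chr, c(r, r + g))
          add_pair(slot(chr, r), slot(chr, r + g), "proximal")
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("infeasible layout: no proximal slot available")
  }

  # dispersed: cross-chromosome pairs, spread so no chromosome pair other
  # than the WGD one accumulates min_block_size anchors
  cross <- utils::combn(chr_names, 2L)
  cross <- cross[, !(cross[1L, ] == "chr1" & cross[2L, ] == "chr2"),
                 drop = FALSE]
  if (n_dispersed > 0L &&
      ceiling(n_dispersed / ncol(cross)) >= min_block_size)
    stop("infeasible layout: too many dispersed pairs per chromosome pair")
  for (i in seq_len(n_dispersed)) {
    cp <- cross[, ((i - 1L) %% ncol(cross)) + 1L]
    ra <- which(free[[cp[1L]]]); rb <- which(free[[cp[2L]]])
    if (!length(ra) || !length(rb))
      stop("infeasible layout: no free rank for dispersed pair")
    a <- ra[sample(length(ra), 1L)]; b <- rb[sample(length(rb), 1L)]
    take(cp[1L], a); take(cp[2L], b)
    add_pair(slot(cp[1L], a), slot(cp[2L], b), "dispersed")
  }

  # gene ids by chromosome and rank; genomic coordinates and exon models
  gene_of_slot <- list()
  gid <- 0L
  gff <- c("##gff-version 3")
  introns_all <- integer(0L)
  ids_all <- character(0L)
  for (ci in seq_along(chr_names)) {
    chr <- chr_names[ci]
    pos <- 1L
    for (r in seq_len(sizes[ci])) {
      gid <- gid + 1L
      id <- sprintf("g%04d", gid)
      gene_of_slot[[slot(chr, r)]] <- id
      n_intr <- as.integer(intron_dist(1L))
      n_ex <- n_intr + 1L
      ex_len <- sample(100:500, n_ex, replace = TRUE)
      in_len <- if (n_intr > 0L) sample(80:800, n_intr, replace = TRUE)
                else integer(0L)
      pos <- pos + sample(1000:5000, 1L)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len - 1L
      g_start <- starts[1L]; g_end <- ends[n_ex]
      strand <- sample(c("+", "-"), 1L)
      gff <- c(gff,
        sprintf("%s\tringfam_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                chr, g_start, g_end, strand, id),
        sprintf("%s\tringfam_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                chr, g_start, g_end, strand, id, id),
        sprintf("%s\tringfam_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                chr, starts, ends, strand, id, seq_len(n_ex), id))
      pos <- g_end
      introns_all <- c(introns_all, n_intr)
      ids_all <- c(ids_all, id)
    }
  }

  modes <- stats::setNames(rep("singleton", n_genes), ids_all)
  hit_rows <- list()
  mk_hit <- function(q, s, strong) {
    ev <- if (strong) 10^-stats::runif(1L, 20, 80) else 10^-stats::runif(1L, 0, 4)
    bs <- if (strong) stats::runif(1L, 300, 500) else stats::runif(1L, 30, 60)
    len <- sample(80:400, 1L)
    data.frame(qseqid = q, sseqid = s,
               pident = round(stats::runif(1L, 60, 95), 1),
               length = len, mismatch = sample(0:50, 1L),
               gapopen = sample(0:5, 1L), qstart = 1L, qend = len,
               sstart = 1L, send = len,
               evalue = signif(ev, 3L), bitscore = round(bs, 1L),
               stringsAsFactors = FALSE)
  }
  truth_pairs <- list()
  for (p in pair_slots) {
    ga <- gene_of_slot[[p$a]]; gb <- gene_of_slot[[p$b]]
    modes[ga] <- p$mode; modes[gb] <- p$mode
    hit_rows[[length(hit_rows) + 1L]] <- mk_hit(ga, gb, TRUE)
    hit_rows[[length(hit_rows) + 1L]] <- mk_hit(gb, ga, TRUE)
    truth_pairs[[length(truth_pairs) + 1L]] <-
      data.frame(gene_a = ga, gene_b = gb, mode = p$mode,
                 stringsAsFactors = FALSE)
  }
  n_noise <- round(noise_frac * n_genes)
  for (i in seq_len(n_noise)) {
    qs <- sample(ids_all, 2L)
    hit_rows[[length(hit_rows) + 1L]] <- mk_hit(qs[1L], qs[2L], FALSE)
  }
  hits <- do.call(rbind, hit_rows)

  blocks_truth <- lapply(block_defs, function(b) {
    data.frame(gene_a = vapply(b$rank_a, function(r)
                 gene_of_slot[[slot(b$chr_a, r)]], character(1L)),
               gene_b = vapply(b$rank_b, function(r)
                 gene_of_slot[[slot(b$chr_b, r)]], character(1L)),
               stringsAsFactors = FALSE)
  })
  truth <- list(
    modes = data.frame(gene_id = ids_all, mode = unname(modes[ids_all]),
                       stringsAsFactors = FALSE),
    pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else NULL,
    blocks = blocks_truth,
    intron_counts = stats::setNames(introns_all, ids_all))
  out <- list(gff = gff, hits = hits, truth = truth, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(gff, file.path(out_dir, "genome.gff3"))
    write_blast_tab(hits, file.path(out_dir, "hits.tsv"))
    jsonlite::write_json(truth$modes, file.path(out_dir, "genome_truth.json"),
                         dataframe = "rows", na = "null")
  }
  out
}

#' Generate a synthetic expression atlas with planted structure
#'
#' Genes fall into `n_clusters` organ clusters whose mean profiles are
#' separated by `effect_lfc` across sample groups; a planted fraction of
#' genes is stress-responsive, receiving |log2FC| = `effect_lfc` with tiny
#' p-values in exactly two contrasts, all other statistics being null
#' (log2FC near zero, p uniform). With `effect_lfc = 0` nothing is planted
#' and every statistic is null.
#'
#' @param n_genes,n_samples Matrix dimensions (defaults mirror a 96-gene
#'   family over a 54-organ atlas).
#' @param n_clusters Planted gene clusters (default 5).
#' @param n_contrasts Number of DE contrasts (default 10).
#' @param effect_lfc Planted log2 fold change (and cluster separation).
#' @param noise_sd Residual noise standard deviation (> 0).
#' @param frac_responsive Planted responsive fraction (default 0.65).
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes `expr.tsv`, `de.tsv`,
#'   `expr_truth.json`.
#' @return List: `matrix`, `sample_groups`, `de` (gene, contrast, log2fc,
#'   pvalue, fdr), `truth` (list `clusters`, `responsive`, `planted`).
#' @export
gen_expression <- function(n_genes = 96L, n_samples = 54L, n_clusters = 5L,
                           n_contrasts = 10L, effect_lfc = 2,
                           noise_sd = 0.3, frac_responsive = 0.65,
                           seed = 1L, out_dir = NULL) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_clusters > n_genes) stop("n_clusters must not exceed n_genes")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- sprintf("sample%02d", seq_len(n_samples))
  clusters <- stats::setNames(rep(seq_len(n_clusters), length.out = n_genes),
                              genes)
  groups <- stats::setNames(rep(seq_len(n_clusters), length.out = n_samples),
                            samples)
  mu <- outer(clusters, groups, function(g, s) ifelse(g == s, effect_lfc, 0))
  m <- mu + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))

  responsive <- character(0L)
  planted <- data.frame(gene = character(), contrast = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  contrasts <- sprintf("contrast%02d", seq_len(n_contrasts))
  de <- expand.grid(gene = genes, contrast = contrasts,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  de <- de[order(de$contrast, de$gene), , drop = FALSE]
  de$log2fc <- stats::rnorm(nrow(de), sd = 0.05)
  de$pvalue <- stats::runif(nrow(de))
  if (effect_lfc > 0) {
    n_resp <- round(frac_responsive * n_genes)
    responsive <- sort(sample(genes, n_resp))
    for (g in responsive) {
      cs <- sample(contrasts, 2L)
      sgn <- sample(c(-1L, 1L), 1L)
      ix <- which(de$gene == g & de$contrast %in% cs)
      de$log2fc[ix] <- sgn * (effect_lfc + stats::rnorm(2L, sd = 0.05))
      de$pvalue[ix] <- 10^-stats::runif(2L, 6, 12)
      planted <- rbind(planted, data.frame(gene = g, contrast = cs,
                                           sign = sgn,
                                           stringsAsFactors = FALSE))
    }
  }
  de$fdr <- stats::ave(de$pvalue, de$contrast, FUN = bh_adjust)
  rownames(de) <- NULL
  truth <- list(clusters = clusters, responsive = responsive,
                planted = planted)
  out <- list(matrix = m, sample_groups = groups, de = de, truth = truth,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    expr_df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write_tsv(expr_df, file.path(out_dir, "expr.tsv"))
    write_tsv(de, file.path(out_dir, "de.tsv"))
    jsonlite::write_json(
      list(clusters = as.list(clusters), responsive = responsive),
      file.path(out_dir, "expr_truth.json"), auto_unbox = TRUE)
  }
  out
}

#' Generate a complete synthetic input bundle
#'
#' Runs all three generators with sub-seeds derived from one master seed
#' and writes `proteome.fasta`, `genome.gff3`, `hits.tsv`, `expr.tsv`,
#' `de.tsv` and the truth JSON files into a directory.
#'
#' @param out_dir Output directory (created).
#' @param seed Master seed; generator sub-seeds are derived from it.
#' @param ... Passed through to the individual generators is not
#'   supported; call them directly for custom parameters.
#' @return Invisible list with the three generator results.
#' @export
gen_bundle <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prot <- gen_proteome(n_atl = 40L, n_btl = 10L, n_decoys = 50L,
                       seed = seed, out_dir = out_dir)
  geno <- gen_genome(seed = seed + 1L, out_dir = out_dir)
  expr <- gen_expression(seed = seed + 2L, out_dir = out_dir)
  invisible(list(proteome = prot, genome = geno, expression = expr))
}
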