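# GFF3 gene models, homology filtering, collinearity chaining,
# duplication-mode classification, retention enrichment

write_gff <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("gene models derive intron counts and per-chromosome ranks", {
  path <- write_gff(gff3_lines(
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "chr1\tsrc\texon\t401\t500\t.\t+\t.\tID=gA.e3;Parent=gA.t1",
    "chr1\tsrc\tgene\t1000\t1200\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t1000\t1200\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\texon\t1000\t1200\t.\t-\t.\tID=gB.e1;Parent=gB.t1",
    "chr2\tsrc\tgene\t10\t400\t.\t+\t.\tID=gC",
    "chr2\tsrc\tmRNA\t10\t400\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr2\tsrc\texon\t10\t400\t.\t+\t.\tID=gC.e1;Parent=gC.t1"))
  gm <- parse_gene_models(path)
  expect_identical(gm$intron_count[gm$gene_id == "gA"], 2L)
  expect_identical(gm$intron_count[gm$gene_id == "gB"], 0L)
  expect_identical(gm$rank[gm$gene_id == "gA"], 1L)
  expect_identical(gm$rank[gm$gene_id == "gB"], 2L)
  expect_identical(gm$rank[gm$gene_id == "gC"], 1L)
})

test_that("longest mRNA is used; exonless mRNA warns into single exon", {
  path <- write_gff(gff3_lines(
    "chr1\tsrc\tgene\t1\t900\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=gA.t1",
    "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\texon\t1\t300\t.\t+\t.\tID=e2;Parent=gA.t2",
    "chr1\tsrc\texon\t500\t900\t.\t+\t.\tID=e3;Parent=gA.t2"))
  gm <- parse_gene_models(path)
  expect_identical(gm$intron_count, 1L) # gA.t2 is longer by exon sum
  path2 <- write_gff(gff3_lines(
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=gA.t1;Parent=gA"))
  expect_warning(gm2 <- parse_gene_models(path2), "no exons|single-exon")
  expect_identical(gm2$n_exons, 1L)
})

test_that("top_k_hits filters self-hits, E-values and keeps best k", {
  h <- data.frame(
    query_id = "q", subject_id = c("q", letters[1:7]),
    bitscore = c(999, 70, 60, 50, 40, 30, 20, 10),
    evalue = 1e-20)
  out <- top_k_hits(h, k = 5)
  expect_identical(nrow(out), 5L)
  expect_setequal(out$subject_id, letters[1:5])
  # only self-hit present -> empty
  expect_identical(nrow(top_k_hits(h[1, ], k = 5)), 0L)
  # equal score at the k-th place: lexicographically smaller subject kept
  h2 <- data.frame(query_id = "q", subject_id = c("z", "m", "a"),
                   bitscore = c(50, 10, 10), evalue = 1e-20)
  out2 <- top_k_hits(h2, k = 2)
  expect_setequal(out2$subject_id, c("z", "a"))
  # E-value threshold applies
  h3 <- data.frame(query_id = "q", subject_id = "s",
                   bitscore = 100, evalue = 1e-3)
  expect_identical(nrow(top_k_hits(h3)), 0L)
})

test_that("planted collinear runs chain into blocks of the planted size", {
  # 6 consecutive paralog pairs chr1/chr2 plus backbone genes
  gm <- toy_models(rep(c("chr1", "chr2"), each = 10), rep(1:10, 2))
  ids <- gm$gene_id # t001..t010 = chr1 ranks 1..10; t011.. = chr2
  hits <- data.frame(query_id = ids[3:8], subject_id = ids[13:18],
                     bitscore = 400, evalue = 1e-30)
  bl <- chain_collinear_blocks(hits, gm)
  expect_length(bl, 1L)
  expect_identical(bl[[1]]$score, 6L)
  expect_identical(bl[[1]]$orientation, "forward")
  expect_identical(bl[[1]]$anchors$gene_a, ids[3:8])

  # strictly decreasing subject ranks: one reversed block
  hits_r <- data.frame(query_id = ids[3:8], subject_id = ids[18:13],
                       bitscore = 400, evalue = 1e-30)
  bl_r <- chain_collinear_blocks(hits_r, gm)
  expect_length(bl_r, 1L)
  expect_identical(bl_r[[1]]$orientation, "reverse")

  # two isolated anchors, min_block_size 5 -> nothing
  hits_i <- data.frame(query_id = ids[c(1, 9)], subject_id = ids[c(11, 20)],
                       bitscore = 400, evalue = 1e-30)
  expect_length(chain_collinear_blocks(hits_i, gm), 0L)
})

test_that("chaining equals exhaustive maximal-chain extraction (<= 12 anchors)", {
  set.seed(17)
  for (case in 1:150) {
    n_anchor <- sample(3:12, 1)
    max_gap <- sample(2:6, 1)
    min_block <- sample(2:4, 1)
    ra <- sample(1:15, n_anchor)
    rb <- sample(1:15, n_anchor)
    key <- paste(ra, rb)
    keep <- !duplicated(key)
    ra <- ra[keep]; rb <- rb[keep]
    gm <- toy_models(rep(c("chr1", "chr2"), each = 15), rep(1:15, 2))
    ids_a <- gm$gene_id[match(paste("chr1", ra), paste(gm$chromosome, gm$rank))]
    ids_b <- gm$gene_id[match(paste("chr2", rb), paste(gm$chromosome, gm$rank))]
    hits <- data.frame(query_id = ids_a, subject_id = ids_b,
                       bitscore = 100, evalue = 1e-30)
    got <- chain_collinear_blocks(hits, gm, max_gap_rank = max_gap,
                                  min_block_size = min_block)
    exp_ <- oracle_chains(ra, rb, max_gap, min_block)
    expect_identical(length(got), length(exp_))
    for (b in seq_along(got)) {
      expect_identical(got[[b]]$orientation, exp_[[b]]$orientation)
      expect_setequal(got[[b]]$anchors$gene_a, ids_a[exp_[[b]]$idx])
    }
  }
})

test_that("duplication modes follow the stated precedence and windows", {
  gm <- toy_models(rep("chr1", 20), 1:20)
  ids <- gm$gene_id
  # adjacent paralogs, no block -> tandem
  h_t <- data.frame(query_id = ids[4], subject_id = ids[5],
                    bitscore = 300, evalue = 1e-40)
  cd <- classify_duplications(h_t, gm, list())
  expect_identical(cd$mode[4:5], c("tandem", "tandem"))
  expect_identical(unique(cd$mode[-(4:5)]), "singleton")
  # five ranks apart -> proximal
  h_p <- data.frame(query_id = ids[2], subject_id = ids[7],
                    bitscore = 300, evalue = 1e-40)
  cd_p <- classify_duplications(h_p, gm, list())
  expect_identical(cd_p$mode[c(2, 7)], c("proximal", "proximal"))
  # beyond the proximal window -> dispersed
  h_d <- data.frame(query_id = ids[1], subject_id = ids[18],
                    bitscore = 300, evalue = 1e-40)
  cd_d <- classify_duplications(h_d, gm, list())
  expect_identical(cd_d$mode[c(1, 18)], c("dispersed", "dispersed"))
  # absent gene -> error
  h_bad <- data.frame(query_id = "nope", subject_id = ids[1],
                      bitscore = 1, evalue = 1e-40)
  expect_error(classify_duplications(h_bad, gm, list()), "absent")
})

test_that("unplaced genes never get rank-based modes", {
  gm <- toy_models(c("chr1", "chr1", "chrUn", "chrUn"), c(1, 2, 1, 2))
  ids <- gm$gene_id
  h <- data.frame(query_id = ids[3], subject_id = ids[4],
                  bitscore = 300, evalue = 1e-40)
  cd <- classify_duplications(h, gm, list())
  expect_identical(cd$mode[3:4], c("dispersed", "dispersed"))
})

test_that("classification is invariant to input order and gene renaming", {
  gen <- gen_genome(120, 5, 2, 1, 3, seed = 12)
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gen$gff, path)
  gm <- parse_gene_models(path)
  hits <- top_k_hits(gen$hits)
  base <- classify_duplications(hits, gm,
                                chain_collinear_blocks(hits, gm))
  # permute hit rows
  set.seed(4)
  hits_p <- hits[sample(nrow(hits)), ]
  perm <- classify_duplications(hits_p, gm,
                                chain_collinear_blocks(hits_p, gm))
  expect_identical(base[order(base$gene_id), ],
                   perm[order(perm$gene_id), ])
  # bijective renaming
  map <- stats::setNames(paste0("X", gm$gene_id), gm$gene_id)
  gm2 <- gm; gm2$gene_id <- unname(map[gm$gene_id])
  hits2 <- hits
  hits2$query_id <- unname(map[hits$query_id])
  hits2$subject_id <- unname(map[hits$subject_id])
  ren <- classify_duplications(hits2, gm2,
                               chain_collinear_blocks(hits2, gm2))
  expect_identical(unname(stats::setNames(ren$mode, ren$gene_id)[map[base$gene_id]]),
                   base$mode)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # the worked 2x2 example
  fam <- c(rep("wgd", 8), rep("other", 2))
  bg <- c(rep("wgd", 10), rep("other", 80))
  res <- retention_enrichment(fam, bg)
  p_wgd <- res$p_value[res$mode == "wgd"]
  expect_equal(p_wgd, fisher_oracle(8, 2, 10, 80), tolerance = 1e-12)
  # identical proportions -> OR 1, p 1
  fam2 <- c(rep("a", 2), rep("b", 8))
  bg2 <- c(rep("a", 20), rep("b", 80))
  res2 <- retention_enrichment(fam2, bg2)
  expect_equal(res2$odds_ratio, c(1, 1))
  expect_equal(res2$p_value, c(1, 1))
  # Bonferroni caps at 1
  expect_true(all(res2$p_adj == 1))
  # degenerate margins flagged with p 1
  res3 <- retention_enrichment(c("a", "a"), c("a", "a"))
  expect_true(all(res3$degenerate))
  expect_true(all(res3$p_value == 1))
})

test_that("Fisher p equals the enumeration oracle on random margins <= 200", {
  set.seed(23)
  for (i in 1:100) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    c_ <- sample(0:40, 1); d <- sample(0:40, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    fam <- c(rep("m", a), rep("o", b))
    bg <- c(rep("m", c_), rep("o", d))
    res <- retention_enrichment(fam, bg)
    expect_equal(res$p_value[res$mode == "m"], fisher_oracle(a, b, c_, d),
                 tolerance = 1e-12)
  }
})

test_that("mode counts always partition the family", {
  gen <- gen_genome(100, 5, 2, 1, 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gen$gff, path)
  gm <- parse_gene_models(path)
  hits <- top_k_hits(gen$hits)
  cd <- classify_duplications(hits, gm, chain_collinear_blocks(hits, gm))
  expect_identical(nrow(cd), 100L)
  expect_identical(sum(table(cd$mode)), 100L)
})
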