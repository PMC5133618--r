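# Alignment curation, NJ builder, support collapsing, nomenclature rules

test_that("block filtering keeps qualifying runs and preserves order", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  expect_identical(unname(filter_alignment_blocks(aln)[1]), aln[[1]])
  # all-gap column between two clean 10-column blocks
  aln2 <- c(a = paste0("ACDEFGHIKL", "-", "ACDEFGHIKL"),
            b = paste0("ACDEFGHIKL", "-", "ACDEFGHIKL"))
  out <- filter_alignment_blocks(aln2, max_gap_fraction = 0.5,
                                 min_block_length = 5)
  expect_identical(nchar(out[[1]]), 20L)
  expect_identical(attr(out, "kept_columns"), c(1:10, 12:21))
  # everything gapped -> error advising relaxed thresholds
  expect_error(filter_alignment_blocks(c(a = "---", b = "---")), "relax")
})

test_that("block filtering equals the brute-force column oracle", {
  set.seed(3)
  for (i in 1:40) {
    n <- sample(3:8, 1); L <- sample(20:60, 1)
    maxg <- runif(1, 0.2, 0.8); minb <- sample(2:6, 1)
    m <- matrix(sample(c("A", "C", "-"), n * L, TRUE, c(.4, .4, .2)), n, L)
    aln <- apply(m, 1, paste, collapse = "")
    names(aln) <- paste0("s", 1:n)
    good <- colMeans(m == "-") <= maxg
    r <- rle(good)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    kept <- unlist(lapply(which(r$values & r$lengths >= minb),
                          function(k) starts[k]:ends[k]))
    if (is.null(kept)) {
      expect_error(filter_alignment_blocks(aln, maxg, minb))
    } else {
      out <- filter_alignment_blocks(aln, maxg, minb)
      expect_identical(attr(out, "kept_columns"), kept)
      expect_identical(unname(out[1]),
                       paste(m[1, kept], collapse = ""))
    }
  }
})

test_that("NJ recovers additive topologies and three-taxon closed form", {
  # additive matrix for ((a,b),(c,d)) with internal edge 2
  d4 <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 5,
                 10, 11, 5, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d4)
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  # additive decomposition: a=1, b=2, c=2, d=3, internal=6
  expect_equal(sum(tr$edge.length), 14, tolerance = 1e-9)
  # 3 taxa: x = (dab + dac - dbc)/2 etc.
  d3 <- matrix(c(0, 5, 8, 5, 0, 9, 8, 9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  bl <- stats::setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl["a"]), (5 + 8 - 9) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["b"]), (5 + 9 - 8) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["c"]), (8 + 9 - 5) / 2, tolerance = 1e-9)
  # ultrametric pairs are siblings
  du <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  du[cbind(c(1, 2), c(2, 1))] <- 0.1
  du[cbind(c(3, 4), c(4, 3))] <- 0.1
  diag(du) <- 0
  tru <- nj_tree(du)
  expect_true(ape::is.monophyletic(ape::root(tru, "d"), c("a", "b")))
  # validation
  dbad <- d3; dbad[1, 2] <- 7
  expect_error(nj_tree(dbad), "symmetric")
  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
})

test_that("negative NJ branches are clamped to zero", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(runif(n * n), n)
    d <- (x + t(x)) / 2; diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("t", 1:n)
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("support collapsing contracts exactly the low edges", {
  t_hi <- ape::read.tree(text = "((a:1,b:1)100:1,(c:1,d:1)95:1,e:3);")
  out_hi <- support_collapse(t_hi, 70)
  expect_identical(out_hi$Nnode, t_hi$Nnode)
  expect_identical(sort(out_hi$tip.label), sort(t_hi$tip.label))

  t_lo <- ape::read.tree(text = "((a:1,b:1)50:1,(c:1,d:1)95:1,e:3);")
  out_lo <- support_collapse(t_lo, 70)
  expect_identical(out_lo$Nnode, t_lo$Nnode - 1L)
  expect_identical(sort(out_lo$tip.label), sort(t_lo$tip.label))
  # the (c,d) clade must survive
  expect_true(ape::is.monophyletic(ape::root(out_lo, "e"), c("c", "d")))

  # chain of two low edges: both contracted; the root becomes degree 5
  t_chain <- ape::read.tree(
    text = "(((a:1,b:1)40:1,(c:1,d:1)30:1)90:1,e:1,f:1);")
  # inner 40 and 30 edges are below threshold, outer 90 is kept
  out_c <- support_collapse(t_chain, 70)
  expect_identical(out_c$Nnode, t_chain$Nnode - 2L)
  # the 90-supported clade keeps a,b,c,d together, now as one polytomy of 4
  expect_true(ape::is.monophyletic(ape::root(out_c, "e"), c("a", "b", "c", "d")))
  mrca <- ape::getMRCA(out_c, c("a", "b", "c", "d"))
  expect_identical(sum(out_c$edge[, 1] == mrca), 4L)
})

test_that("the three toy nomenclature cases resolve as published", {
  # one-to-one orthology inherits the reference number
  t1 <- ape::read.tree(
    text = "((AtATL43:0.05,T1:0.05):0.3,(AtATL7:0.05,T2:0.05):0.3);")
  n1 <- assign_names(t1)
  expect_identical(n1$assigned_name[n1$target == "T1"], "ATL43")
  expect_identical(n1$assigned_name[n1$target == "T2"], "ATL7")
  expect_true(all(n1$rule_used == "same-number"))

  # equidistant pair shares the number with letters in tree order
  t2 <- ape::read.tree(text = "(AtATL23:0.3,(T1:0.1,T2:0.1):0.2,AtATL9:4);")
  n2 <- assign_names(t2)
  expect_setequal(n2$assigned_name[n2$target %in% c("T1", "T2")],
                  c("ATL23a", "ATL23b"))

  # sister to a reference clade: first new number above the maximum (81)
  t3 <- ape::read.tree(
    text = "((AtATL46:0.1,AtATL48:0.1):0.2,T1:0.3,AtATL81:3);")
  n3 <- assign_names(t3)
  expect_identical(n3$assigned_name[n3$target == "T1"], "ATL82")
  expect_identical(n3$rule_used[n3$target == "T1"],
                   "new-number-multi-reference")
})

test_that("assignments are deterministic, unique, with gapless letters", {
  txt <- paste0("((AtATL5:0.1,(T1:0.05,T2:0.05):0.05):0.2,",
                "((T3:0.4,T4:0.5):0.2,(AtATL9:0.1,T5:0.1):0.1):0.2,",
                "AtATL2:1);")
  tr <- ape::read.tree(text = txt)
  a1 <- assign_names(tr)
  a2 <- assign_names(tr)
  expect_identical(a1, a2)
  expect_false(anyDuplicated(a1$assigned_name) > 0)
  # letters appear iff >= 2 targets share a number, gapless from "a"
  lettered <- grep("[a-z]$", a1$assigned_name, value = TRUE)
  if (length(lettered)) {
    stems <- sub("[a-z]$", "", lettered)
    for (s in unique(stems)) {
      suff <- sort(sub(s, "", lettered[stems == s], fixed = TRUE))
      expect_identical(suff, letters[seq_along(suff)])
      expect_gte(length(suff), 2L)
    }
  }
  # new numbers increase along the reported (traversal) order
  new_nums <- suppressWarnings(as.integer(sub("^ATL", "", a1$assigned_name[
    grepl("^new-number", a1$rule_used)])))
  expect_true(!is.unsorted(new_nums))
  expect_true(all(new_nums > 9))
  # duplicate reference numbers rejected
  expect_error(
    assign_names(tr, reference_numbers = c(AtATL5 = 5, AtATL9 = 5, AtATL2 = 2)),
    "duplicate")
})

test_that("NJ on generator-like genealogies recovers sibling pairs", {
  # true genealogy: k cherry pairs at small within-pair distance; NJ on
  # noisy distances must recover >= 95% of sibling pairs
  set.seed(19)
  recovered <- 0L; total <- 0L
  for (rep_ in 1:10) {
    k <- 6L
    n <- 2L * k
    labs <- paste0("L", seq_len(n))
    d <- matrix(runif(n * n, 4, 6), n, n, dimnames = list(labs, labs))
    d <- (d + t(d)) / 2
    for (p in seq_len(k)) {
      i <- 2L * p - 1L; j <- 2L * p
      d[i, j] <- d[j, i] <- runif(1, 0.1, 0.3)
    }
    diag(d) <- 0
    tr <- nj_tree(d)
    for (p in seq_len(k)) {
      total <- total + 1L
      pair <- labs[c(2L * p - 1L, 2L * p)]
      anc <- ape::getMRCA(tr, pair)
      kids <- tr$edge[tr$edge[, 1] == anc, 2]
      if (all(match(pair, tr$tip.label) %in% kids)) recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / total, 0.95)
})

test_that("alignments and trees round-trip through FASTA/newick", {
  aln <- c(s1 = "ACD-EF", s2 = "ACDGEF")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  expect_identical(read_alignment(f), aln)
  expect_error(read_alignment({
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACGT", ">b", "AC"), f2); f2
  }), "equal length")
})
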