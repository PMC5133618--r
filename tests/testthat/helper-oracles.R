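# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, probs = NULL) {
  paste(sample(AA20, n, replace = TRUE, prob = probs), collapse = "")
}

# composition biased toward motif residues so motif placements actually
# occur in random material
motif_biased_probs <- local({
  p <- rep(0.52 / 16, 20)
  names(p) <- AA20
  p[c("C", "H", "P", "W")] <- c(0.20, 0.12, 0.08, 0.08)
  p
})

# ---- brute-force regex oracle for the RING-H2 scanner --------------------
# one exact lookahead regex per spacer tuple; enumerates every placement

oracle_patterns <- function(grammar) {
  r <- grammar$spacer_ranges
  pats <- list()
  for (g2 in r[2, 1]:r[2, 2]) for (g6 in r[6, 1]:r[6, 2]) {
    pseg <- switch(grammar$proline_rule,
      PxC = sprintf(".{%d}P.", g2 - 2L),
      PC = sprintf(".{%d}P", g2 - 1L),
      either = sprintf("(?:.{%d}P.|.{%d}P)", g2 - 2L, g2 - 1L))
    wseg <- if (grammar$require_w4) sprintf(".{3}W.{%d}", g6 - 4L)
            else sprintf(".{%d}", g6)
    pat <- paste0("C.{", r[1, 1], "}C", pseg, "C.{", r[3, 1], "}H.{",
                  r[4, 1], "}H.{", r[5, 1], "}C", wseg, "C.{", r[7, 1],
                  "}C", if (grammar$require_trailing_w) "W" else "")
    pats[[length(pats) + 1L]] <- list(pat = paste0("(?=", pat, ")"),
                                      g2 = g2, g6 = g6)
  }
  pats
}

oracle_scan <- function(seq, pats, grammar) {
  # X must never match a ligand/P/W position: the regex dot would accept it
  # in spacers, which is fine, but literal classes C/H/P/W already exclude X
  r <- grammar$spacer_ranges
  out <- list()
  for (p in pats) {
    m <- gregexpr(p$pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (st in as.integer(m)) {
      gaps <- c(r[1, 1], p$g2, r[3, 1], r[4, 1], r[5, 1], p$g6, r[7, 1])
      out[[length(out) + 1L]] <- cumsum(c(st, gaps + 1L))
    }
  }
  out <- unique(out)
  out[order(vapply(out, function(l)
    paste(formatC(l, width = 6, flag = "0"), collapse = ""), character(1L)))]
}

scan_positions <- function(seq, grammar) {
  lapply(scan_ring_h2(seq, grammar), function(m) as.integer(m$ligand_positions))
}

# ---- hypergeometric enumeration oracle for Fisher's exact test -----------

fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k1 <- a + c_
  ks <- max(0L, k1 - r2):min(r1, k1)
  probs <- stats::dhyper(ks, r1, r2, k1)
  p_obs <- stats::dhyper(a, r1, r2, k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- exhaustive chain-extraction oracle for collinearity -----------------
# enumerates every chain (both orientations) and greedily extracts the
# longest, preferring forward orientation and the lexicographically
# smallest anchor-index sequence, mirroring the implementation contract

oracle_chains <- function(ra, rb, max_gap, min_block) {
  n <- length(ra)
  stopifnot(n <= 14L)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  follows <- function(i, j, rev_) {
    dga <- ra[j] - ra[i]
    if (dga < 1L || dga > max_gap) return(FALSE)
    dgb <- if (rev_) rb[i] - rb[j] else rb[j] - rb[i]
    dgb >= 1L && dgb <= max_gap
  }
  all_chains <- function(avail, rev_) {
    chains <- list()
    dfs <- function(path) {
      chains[[length(chains) + 1L]] <<- path
      last <- path[length(path)]
      for (j in avail[avail > last]) {
        if (follows(last, j, rev_)) dfs(c(path, j))
      }
    }
    for (i in avail) dfs(i)
    chains
  }
  best_of <- function(chains) {
    if (!length(chains)) return(integer())
    len <- vapply(chains, length, integer(1L))
    cand <- chains[len == max(len)]
    keys <- vapply(cand, function(ch)
      paste(formatC(ch, width = 4, flag = "0"), collapse = ""), character(1L))
    cand[[order(keys)[1L]]]
  }
  blocks <- list()
  avail <- seq_len(n)
  repeat {
    if (length(avail) < min_block) break
    bf <- best_of(all_chains(avail, FALSE))
    br <- best_of(all_chains(avail, TRUE))
    use_fwd <- length(bf) >= length(br)
    chain <- if (use_fwd) bf else br
    if (length(chain) < min_block) break
    blocks[[length(blocks) + 1L]] <-
      list(idx = ord[chain], orientation = if (use_fwd) "forward" else "reverse")
    avail <- setdiff(avail, chain)
  }
  blocks
}

# ---- misc ---------------------------------------------------------------

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# toy gene-models table builder (bypasses GFF3 for geometry-only tests)
toy_models <- function(chr, rank) {
  n <- length(chr)
  df <- data.frame(
    gene_id = sprintf("t%03d", seq_len(n)),
    chromosome = chr, strand = "+",
    start = rank * 1000L, end = rank * 1000L + 500L,
    n_exons = 1L, intron_count = 0L, stringsAsFactors = FALSE)
  df$exons <- I(lapply(seq_len(n), function(i)
    cbind(start = df$start[i], end = df$end[i])))
  df$rank <- rank
  class(df) <- c("gene_models", class(df))
  df
}

gff3_lines <- function(...) c("##gff-version 3", ...)
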