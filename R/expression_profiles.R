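# Expression-atlas profiling: median centering, Pearson-distance
# hierarchical clustering with an explicit tie-break, responsiveness
# flagging from per-contrast DE tables, BH adjustment, weighted Pearson
# co-expression and the Mantel permutation test.

#' Median-centre an expression matrix
#'
#' Subtracts the per-gene (row) median so every row median is exactly zero;
#' idempotent.
#'
#' @param matrix Numeric genes x samples matrix.
#' @return Centred matrix.
#' @export
median_center <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("expression matrix must be numeric")
  if (!ncol(m)) stop("at least one sample required")
  m - apply(m, 1L, stats::median)
}

#' Pearson distance matrix between gene rows
#'
#' d = 1 - r. Zero-variance rows get distance 1 to everything (0 on the
#' diagonal) with a warning.
#'
#' @param matrix Numeric genes x samples matrix.
#' @return Symmetric distance matrix.
#' @export
pearson_distance <- function(matrix) {
  m <- as.matrix(matrix)
  v <- apply(m, 1L, stats::var)
  flat <- v == 0 | is.na(v)
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s); distance set to 1")
    m[flat, ] <- 0
  }
  r <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - r
  d[flat, ] <- 1; d[, flat] <- 1
  diag(d) <- 0
  d
}

#' Hierarchical clustering with Pearson distance and average linkage
#'
#' Deterministic agglomeration: at each step the smallest pairwise
#' distance is merged, ties broken by the smaller index pair; average
#' linkage updates d(new, o) as the size-weighted mean. The result is a
#' standard `hclust` object, so [stats::cutree()] applies.
#'
#' @param matrix Numeric genes x samples matrix (rows are clustered).
#' @param k Optional number of flat clusters to cut.
#' @param metric `"pearson"` (1 - r) or `"euclidean"`.
#' @return List with `tree` (an `hclust`) and, when `k` is given,
#'   `clusters` (named integer vector).
#' @export
hcluster <- function(matrix, k = NULL, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n < 2L) stop("at least 2 genes required")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- if (metric == "pearson") pearson_distance(m)
       else as.matrix(stats::dist(m))

  active <- seq_len(n)           # current cluster ids (neg = singleton row)
  id <- -seq_len(n)              # hclust merge coding
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  d <- D
  for (step in seq_len(n - 1L)) {
    na <- length(active)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      if (d[i, j] < best[1L] - 1e-15) best <- c(d[i, j], i, j)
    }
    i <- best[2L]; j <- best[3L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best[1L]
    # average-linkage update into slot i, drop slot j
    wi <- size[i]; wj <- size[j]
    newd <- (wi * d[i, ] + wj * d[j, ]) / (wi + wj)
    d[i, ] <- newd; d[, i] <- newd; d[i, i] <- 0
    keep <- setdiff(seq_len(na), j)
    d <- d[keep, keep, drop = FALSE]
    size[i] <- wi + wj; size <- size[keep]
    id[i] <- step; id <- id[keep]
    active <- active[keep]
  }
  order_ <- dendro_order(merge, n)
  tree <- structure(list(merge = merge, height = height, order = order_,
                         labels = labels, method = "average",
                         call = match.call(),
                         dist.method = metric),
                    class = "hclust")
  out <- list(tree = tree)
  if (!is.null(k)) out$clusters <- stats::cutree(tree, k = k)
  out
}

dendro_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0L) return(-node)
    c(leaves(merge[node, 1L]), leaves(merge[node, 2L]))
  }
  leaves(n - 1L)
}

#' Flag stress-responsive genes from per-contrast DE statistics
#'
#' A gene is responsive when |log2FC| exceeds `lfc_min` and FDR is below
#' `fdr_max` in at least `min_conditions` contrasts. The relaxed count
#' (significant in at least one contrast regardless of fold change) is
#' reported alongside. Missing statistics are treated as not significant
#' and counted.
#'
#' @param de data.frame with columns `gene`, `contrast`, `log2fc`, `fdr`.
#' @param lfc_min Fold-change threshold on |log2FC| (default 0.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_conditions Minimum qualifying contrasts (default 2).
#' @return data.frame per gene: `gene`, `n_significant`, `responsive`,
#'   `relaxed` (significant FDR in >= 1 contrast, any FC). Attributes:
#'   `n_missing` (NA statistics encountered) and `signs`, a gene x contrast
#'   matrix of modulation signs (-1, 0, +1) among qualifying calls.
#' @export
flag_responsive <- function(de, lfc_min = 0.5, fdr_max = 0.05,
                            min_conditions = 2L) {
  stopifnot(all(c("gene", "contrast", "log2fc", "fdr") %in% names(de)))
  n_contrasts <- length(unique(de$contrast))
  if (n_contrasts < min_conditions)
    warning("fewer contrasts available (", n_contrasts,
            ") than min_conditions (", min_conditions, ")")
  miss <- is.na(de$log2fc) | is.na(de$fdr)
  n_missing <- sum(miss)
  sig <- !miss & abs(de$log2fc) > lfc_min & de$fdr < fdr_max
  relaxed_sig <- !miss & de$fdr < fdr_max
  genes <- unique(de$gene)
  contrasts <- unique(de$contrast)
  signs <- matrix(0L, length(genes), length(contrasts),
                  dimnames = list(genes, contrasts))
  signs[cbind(match(de$gene[sig], genes),
              match(de$contrast[sig], contrasts))] <-
    as.integer(sign(de$log2fc[sig]))
  n_sig <- as.integer(rowSums(signs != 0L))
  relaxed <- tapply(relaxed_sig, factor(de$gene, levels = genes), any)
  out <- data.frame(gene = genes, n_significant = n_sig,
                    responsive = n_sig >= min_conditions,
                    relaxed = as.logical(relaxed),
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  attr(out, "signs") <- signs
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: q_(i) = min over j >= i of p_(j) * m / j, capped at
#' 1, in the original order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

#' Weighted Pearson co-expression matrix
#'
#' Gene-by-gene weighted Pearson correlation over samples; unit weights
#' reduce to the ordinary Pearson correlation.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param weights Non-negative per-sample weights, not all zero (default
#'   unit weights).
#' @return Symmetric correlation matrix; genes with zero variance under
#'   the weights get `NA` rows/columns (diagonal stays 1).
#' @export
coexpression_matrix <- function(matrix, weights = NULL) {
  m <- as.matrix(matrix)
  ns <- ncol(m)
  if (is.null(weights)) weights <- rep(1, ns)
  if (length(weights) != ns) stop("one weight per sample required")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  mu <- as.vector(m %*% w)
  cm <- m - mu
  cov <- (cm * rep(w, each = nrow(m))) %*% t(cm)
  sd_ <- sqrt(diag(cov))
  degenerate <- sd_ <= 0 | is.na(sd_)
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero variance under weights")
  r <- cov / tcrossprod(sd_)
  r[degenerate, ] <- NA_real_; r[, degenerate] <- NA_real_
  diag(r) <- 1
  r
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries;
#' significance is assessed by jointly permuting rows and columns of the
#' second matrix. One-sided (greater): p = (1 + #{permuted r >= observed})
#' / (n_perm + 1).
#'
#' @param a,b Square symmetric matrices over the same objects, identical
#'   ordering, zero diagonal.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Mandatory RNG seed for reproducibility.
#' @return List: `statistic` (observed r), `p_value`, `n_perm`, `seed`.
#' @export
mantel_test <- function(a, b, n_perm = 999L, seed) {
  if (missing(seed)) stop("a seed is required for the Mantel permutations")
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  if (n < 3L) stop("matrices of size >= 3 required")
  if (!all(dim(a) == n) || !all(dim(b) == n))
    stop("matrices must be square and of equal size")
  if (!isSymmetric(unname(a), tol = 1e-8) || !isSymmetric(unname(b), tol = 1e-8))
    stop("matrices must be symmetric")
  ut <- upper.tri(a)
  av <- a[ut]
  if (stats::sd(av) == 0 || stats::sd(b[ut]) == 0)
    stop("degenerate (constant off-diagonal) matrix")
  r_obs <- stats::cor(av, b[ut])
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    bp <- b[p, p]
    if (stats::cor(av, bp[ut]) >= r_obs) count <- count + 1L
  }
  list(statistic = r_obs,
       p_value = (1 + count) / (n_perm + 1),
       n_perm = as.integer(n_perm),
       seed = seed)
}

#' Read an expression matrix TSV (genes in rows)
#'
#' First column (or row names) holds gene ids; remaining columns are
#' samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  as.matrix(df)
}

#' Read a per-contrast differential-expression table
#'
#' TSV with columns gene, contrast, log2fc and fdr (or raw `pvalue`, in
#' which case FDR is computed per contrast with [bh_adjust()]).
#'
#' @param path TSV path.
#' @return data.frame gene, contrast, log2fc, fdr.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "contrast", "log2fc") %in% names(df)))
  if (!("fdr" %in% names(df))) {
    if (!("pvalue" %in% names(df)))
      stop("DE table needs an 'fdr' or 'pvalue' column")
    df$fdr <- stats::ave(df$pvalue, df$contrast, FUN = bh_adjust)
  }
  df
}

#' Two-group Welch t-test DE stand-in
#'
#' Plain per-gene Welch t-test between two sample groups with BH-adjusted
#' p-values, for synthetic end-to-end runs only; it is not equivalent to
#' the moderated models used on real array/RNA-seq data.
#'
#' @param matrix Numeric genes x samples matrix (log scale).
#' @param group Factor/vector of two levels over samples.
#' @param contrast Contrast label carried into the output.
#' @return data.frame gene, contrast, log2fc, pvalue, fdr.
#' @export
welch_de <- function(matrix, group, contrast = "groupB_vs_groupA") {
  m <- as.matrix(matrix)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  ia <- which(group == levels(group)[1L])
  ib <- which(group == levels(group)[2L])
  res <- t(apply(m, 1L, function(x) {
    tt <- stats::t.test(x[ib], x[ia])
    c(lfc = mean(x[ib]) - mean(x[ia]), p = tt$p.value)
  }))
  data.frame(gene = rownames(m), contrast = contrast,
             log2fc = res[, "lfc"], pvalue = res[, "p"],
             fdr = bh_adjust(res[, "p"]), row.names = NULL,
             stringsAsFactors = FALSE)
}
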