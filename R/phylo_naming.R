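# Phylogeny-guided nomenclature: alignment block curation, a neighbour-
# joining builder for synthetic end-to-end runs, support-based edge
# collapsing, and name assignment against a numbered reference gene set.

#' Filter alignment columns into conserved blocks
#'
#' Gblocks-like curation under relaxed settings: keeps maximal runs of
#' columns whose gap fraction is at most `max_gap_fraction`, provided the
#' run spans at least `min_block_length` columns. Column order is
#' preserved.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (gaps `-` or `.`).
#' @param max_gap_fraction Maximum per-column gap fraction (default 0.5).
#' @param min_block_length Minimum run length in columns (default 5).
#' @return Curated alignment (same representation); attribute
#'   `kept_columns` records the original column indices.
#' @export
filter_alignment_blocks <- function(alignment, max_gap_fraction = 0.5,
                                    min_block_length = 5L) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_block_length >= 1L)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(m == "-" | m == ".")
  good <- gap_frac <= max_gap_fraction
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_runs <- which(r$values & r$lengths >= min_block_length)
  kept <- unlist(lapply(keep_runs, function(i) starts[i]:ends[i]))
  if (!length(kept))
    stop("no alignment blocks survive curation; relax max_gap_fraction ",
         "or min_block_length")
  out <- apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(alignment)
  attr(out, "kept_columns") <- kept
  out
}

#' Neighbour-joining tree
#'
#' Thin wrapper around the standard NJ algorithm with negative branch
#' lengths clamped to zero, for synthetic end-to-end runs where no external
#' maximum-likelihood tree is available.
#'
#' @param distance_matrix Symmetric numeric matrix with zero diagonal and
#'   at least 3 taxa; row names are the leaf labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3L) stop("at least 3 taxa required")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Collapse low-support edges into polytomies
#'
#' Internal edges whose child-node support (stored as node labels, as
#' written by common tree builders) falls below `threshold` are contracted;
#' the leaf set is unchanged. Unlabelled internal nodes are kept.
#'
#' @param tree A `phylo` tree with support values as internal node labels.
#' @param threshold Support threshold (default 70, the usual bootstrap
#'   cutoff).
#' @return The collapsed `phylo` tree.
#' @export
support_collapse <- function(tree, threshold = 70) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  # nodes to contract: internal, non-root, labelled, below threshold
  contract <- which(!is.na(sup) & sup < threshold) + ntip
  contract <- setdiff(contract, root)
  if (!length(contract)) return(tree)

  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- if (is.null(tree$edge.length)) NULL else
    stats::setNames(tree$edge.length, tree$edge[, 2L])
  lab_of <- function(node) {
    if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
  }
  write_node <- function(node) {
    if (node <= ntip) return(quote_label(lab_of(node)))
    kids <- children[[as.character(node)]]
    parts <- unlist(lapply(kids, function(k) {
      if (k > ntip && k %in% contract) {
        # splice contracted child's subtrees in place, dropping the outer
        # parentheses and the contracted node's own label
        sub("^\\((.*)\\)[^()]*$", "\\1", write_node(k))
      } else {
        paste0(write_node(k),
               if (!is.null(elen)) paste0(":", format(elen[[as.character(k)]],
                                                      digits = 12)) else "")
      }
    }))
    lab <- lab_of(node)
    paste0("(", paste(parts, collapse = ","), ")",
           if (!is.na(lab) && nzchar(lab)) lab else "")
  }
  nwk <- paste0(write_node(root), ";")
  ape::read.tree(text = nwk)
}

quote_label <- function(x) {
  if (grepl("[(),:;\\s]", x)) paste0("'", x, "'") else x
}

parse_reference_numbers <- function(labels) {
  hit <- grepl("^At.*[0-9]+$", labels) & grepl("ATL", labels)
  nums <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1",
                                          labels[hit])))
  stats::setNames(nums, labels[hit])
}

#' Assign family names from a reference-anchored phylogeny
#'
#' Implements the orthologue-based nomenclature rules: (i) a target leaf
#' whose unique nearest reference (by patristic distance) reciprocally has
#' that target as its unique nearest target inherits the reference number;
#' (ii) two or more targets equidistant from a single reference share the
#' number with letter suffixes `a`, `b`, ... in tree traversal order;
#' (iii) a target tied between two or more references (e.g. sister to a
#' reference clade) takes the next unused number above the reference
#' maximum; (iv) remaining targets are numbered progressively along a fixed
#' post-order traversal rooted at the lexicographically smallest leaf.
#'
#' @param tree A `phylo` tree whose leaves are partitioned into reference
#'   leaves (e.g. `AtATL43`) and target leaves.
#' @param reference_numbers Named integer vector mapping reference leaf
#'   labels to their numbers. By default parsed from leaf labels matching
#'   `At...ATL<number>`.
#' @param prefix Name root for assigned names (default `"ATL"`).
#' @param tol Relative tolerance for patristic-distance ties (default
#'   1e-6).
#' @return data.frame: target, assigned_name, rule_used, supporting_refs.
#' @export
assign_names <- function(tree, reference_numbers = NULL, prefix = "ATL",
                         tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(reference_numbers))
    reference_numbers <- parse_reference_numbers(tree$tip.label)
  if (!length(reference_numbers)) stop("no reference leaves identified")
  if (anyDuplicated(reference_numbers))
    stop("duplicate reference numbers")
  refs <- names(reference_numbers)
  targets <- setdiff(tree$tip.label, refs)
  if (!length(targets)) stop("no target leaves to name")
  if (!all(refs %in% tree$tip.label))
    stop("reference leaves absent from tree")

  D <- stats::cophenetic(tree)
  pos <- traversal_positions(tree)

  near_refs <- lapply(targets, function(t) {
    d <- D[t, refs]
    dm <- min(d)
    refs[d <= dm * (1 + tol) + 1e-12]
  })
  names(near_refs) <- targets
  near_targets <- lapply(refs, function(r) {
    d <- D[r, targets]
    dm <- min(d)
    targets[d <= dm * (1 + tol) + 1e-12]
  })
  names(near_targets) <- refs

  assigned <- character(0L)
  rule <- character(0L)
  support <- character(0L)
  pending <- character(0L)   # targets needing a new progressive number
  pending_rule <- character(0L)

  multi <- targets[vapply(near_refs, length, integer(1L)) >= 2L]
  pending <- c(pending, multi)
  pending_rule <- c(pending_rule, rep("multi-reference", length(multi)))

  single <- setdiff(targets, multi)
  by_ref <- split(single, vapply(near_refs[single], `[[`, character(1L), 1L))
  for (r in names(by_ref)) {
    S <- by_ref[[r]]
    num <- reference_numbers[[r]]
    if (length(S) == 1L) {
      if (identical(near_targets[[r]], S)) {
        assigned[S] <- paste0(prefix, num)
        rule[S] <- "same-number"; support[S] <- r
      } else {
        pending <- c(pending, S)
        pending_rule <- c(pending_rule, "unpaired")
      }
    } else {
      d <- D[r, S]
      equidistant <- max(d) <= min(d) * (1 + tol) + 1e-12
      if (equidistant) {
        S <- S[order(pos[S])]
        assigned[S] <- paste0(prefix, num, letters[seq_along(S)])
        rule[S] <- "lettered"; support[S] <- r
      } else {
        best <- S[order(d, pos[S])][1L]
        if (best %in% near_targets[[r]]) {
          assigned[best] <- paste0(prefix, num)
          rule[best] <- "same-number"; support[best] <- r
        } else {
          pending <- c(pending, best)
          pending_rule <- c(pending_rule, "unpaired")
        }
        rest <- setdiff(S, best)
        pending <- c(pending, rest)
        pending_rule <- c(pending_rule, rep("unpaired", length(rest)))
      }
    }
  }

  if (length(pending)) {
    ord <- order(pos[pending])
    pending <- pending[ord]
    pending_rule <- pending_rule[ord]
    new_nums <- max(reference_numbers) + seq_along(pending)
    assigned[pending] <- paste0(prefix, new_nums)
    rule[pending] <- ifelse(pending_rule == "multi-reference",
                            "new-number-multi-reference",
                            "new-number-progressive")
    support[pending] <- vapply(pending, function(t)
      paste(near_refs[[t]], collapse = ";"), character(1L))
  }

  out <- data.frame(target = targets,
                    assigned_name = unname(assigned[targets]),
                    rule_used = unname(rule[targets]),
                    supporting_refs = unname(support[targets]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$assigned_name))
    stop("internal error: duplicate assigned names")
  out[order(pos[out$target]), , drop = FALSE]
}

# Leaf positions along a fixed post-order traversal, rooted at the
# lexicographically smallest leaf so the order is reproducible for any
# input rotation of the same unrooted tree.
traversal_positions <- function(tree) {
  anchor <- sort(tree$tip.label)[1L]
  rt <- tryCatch(ape::root(tree, outgroup = anchor, resolve.root = TRUE),
                 error = function(e) tree)
  rt <- ape::reorder.phylo(rt, "postorder")
  tips <- rt$edge[, 2L][rt$edge[, 2L] <= length(rt$tip.label)]
  stats::setNames(seq_along(tips), rt$tip.label[tips])
}

#' Write a nomenclature map as TSV
#'
#' @param assignments Output of [assign_names()].
#' @param path Output path.
#' @export
write_name_map <- function(assignments, path) {
  write_tsv(assignments, path)
}
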