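# Phylogeny: p-distance, neighbor-joining with bootstrap supports,
# paralog-pair (cherry) extraction, subgroup assignment.
#
# Trees are ape "phylo" objects (unrooted, stored with a trifurcating
# root-equivalent node); bootstrap supports live in node.label as
# percentages.

#' Validate an alignment
#'
#' @param x Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @return `x`, validated.
#' @export
as_alignment <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment rows must be named")
  if (anyDuplicated(names(x))) stop("duplicate alignment ids")
  if (length(x) < 2L) stop("alignment needs >= 2 rows")
  if (length(unique(nchar(x))) != 1L)
    stop("alignment rows must have equal length")
  toupper(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Pairwise p-distance with pairwise deletion
#'
#' For each pair of rows, the proportion of mismatching sites among
#' sites where neither row has a gap. A pair with zero comparable sites
#' is an error naming the pair.
#'
#' @param aln Alignment (see [as_alignment()]).
#' @return Symmetric matrix with zero diagonal, entries in \[0, 1\],
#'   dimnames the alignment ids, attribute `method = "p-distance"`.
#' @export
p_distance <- function(aln) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  ids <- names(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     ids[i], ids[j]), call. = FALSE)
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  attr(d, "method") <- "p-distance"
  d
}

#' Percent identity between two aligned rows
#'
#' @param aln Alignment.
#' @param pair Character vector of two ids.
#' @return Identical sites / comparable sites x 100 (pairwise deletion).
#' @export
percent_identity <- function(aln, pair) {
  aln <- as_alignment(aln)
  stopifnot(length(pair) == 2L, all(pair %in% names(aln)))
  a <- strsplit(aln[[pair[1]]], "")[[1]]
  b <- strsplit(aln[[pair[2]]], "")[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok))
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 pair[1], pair[2]), call. = FALSE)
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - r(i) - r(j) is joined; ties are broken by the
#' lowest (row, column) index pair, so the result is deterministic.
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling branch (final trifurcation branches are
#' clamped without transfer).
#'
#' @param d Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have dimnames")
  d <- (d + t(d)) / 2
  # each active node is a newick fragment
  frag <- ids
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D[active, active, drop = FALSE])
    best <- NULL; bestq <- Inf
    for (ii in seq_len(m - 1L)) {
      for (jj in (ii + 1L):m) {
        q <- (m - 2) * D[active[ii], active[jj]] - r[ii] - r[jj]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(ii, jj) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    dij <- D[i, j]
    li <- dij / 2 + (r[best[1]] - r[best[2]]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    # distances from the new node u to every other active node
    newrow <- numeric(nrow(D))
    others <- setdiff(active, c(i, j))
    for (k in others)
      newrow[k] <- (D[i, k] + D[j, k] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    D[nrow(D), seq_len(nrow(D) - 1L)] <- newrow
    D[seq_len(nrow(D) - 1L), ncol(D)] <- newrow
    frag <- c(frag, sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj))
    active <- c(others, length(frag))
  }
  # final trifurcation: three-point formulas
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[a], la, frag[b], lb, frag[c3], lc)
  ape::read.tree(text = nwk)
}

# descendant tip labels per node (rooted representation)
node_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  clade <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) clade[[i]] <- phy$tip.label[i]
  # process internal nodes in an order where children come first
  ord <- rev(unique(phy$edge[order(phy$edge[, 1]), 1]))
  remaining <- ord
  while (length(remaining)) {
    nxt <- remaining[vapply(remaining, function(v)
      all(!vapply(clade[kids[[as.character(v)]]], is.null, TRUE)),
      logical(1))]
    for (v in nxt)
      clade[[v]] <- sort(unlist(clade[kids[[as.character(v)]]]))
    remaining <- setdiff(remaining, nxt)
  }
  clade
}

# canonical bipartition keys for internal, non-root nodes
tree_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  clade <- node_clades(phy)
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  nodes <- setdiff(unique(phy$edge[, 1]), root)
  keys <- vapply(nodes, function(v) {
    side <- clade[[v]]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "|")
  }, character(1))
  names(keys) <- nodes
  # drop trivial splits (single tip or all-but-one)
  sz <- lengths(strsplit(keys, "|", fixed = TRUE))
  keys[sz >= 2 & sz <= length(tips) - 2]
}

#' Neighbor-joining tree with bootstrap supports
#'
#' The point-estimate tree is built from the full alignment's p-distance
#' matrix; each replicate resamples alignment columns with replacement,
#' and the support of each internal bipartition of the point tree is the
#' percentage of replicate trees containing it. Fixed seeds give
#' bit-identical supports.
#'
#' @param aln Alignment.
#' @param n_reps Number of bootstrap replicates (>= 1; the family
#'   analysis uses 1000).
#' @param seed Integer RNG seed.
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L) {
  aln <- as_alignment(aln)
  stopifnot(n_reps >= 1L)
  m <- aln_matrix(aln)
  rownames(m) <- names(aln)
  point <- neighbor_joining(p_distance(aln))
  keys <- tree_splits(point)
  hits <- setNames(numeric(length(keys)), names(keys))
  set.seed(as.integer(seed))
  ncol_ <- ncol(m)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_, ncol_, replace = TRUE)
    rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(aln))
    rep_tree <- tryCatch(neighbor_joining(p_distance(rep_aln)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    rep_keys <- tree_splits(rep_tree)
    hits <- hits + as.numeric(keys %in% rep_keys)
  }
  supports <- 100 * hits / n_reps
  ntip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  labs[as.integer(names(keys)) - ntip] <-
    format(supports, trim = TRUE, digits = 15)
  point$node.label <- labs
  point
}

node_support <- function(phy, node) {
  if (is.null(phy$node.label)) return(NA_real_)
  lab <- phy$node.label[node - length(phy$tip.label)]
  if (is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Extract paralog pairs as supported cherries
#'
#' A paralog pair is two leaves that are mutual sisters (a cherry) whose
#' joining vertex has bootstrap support at least `min_support`. A vertex
#' with no support annotation (the root-equivalent trifurcation) uses
#' the support of the split separating the cherry from the rest. Each
#' leaf appears in at most one pair.
#'
#' @param tree A `phylo` tree, typically from [bootstrap_support()].
#' @param min_support Minimum support percentage (default 50).
#' @return A data.frame with columns `gene_a`, `gene_b`, `support`.
#' @export
extract_paralog_pairs <- function(tree, min_support = 50) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  out <- list()
  for (v in unique(tree$edge[, 1])) {
    ch <- kids[[as.character(v)]]
    leaf_ch <- ch[ch <= ntip]
    if (length(leaf_ch) != 2L) next
    if (length(ch) > 2L && v != root) next
    if (v == root && length(ch) != 3L) next
    sup <- node_support(tree, v)
    if (is.na(sup) && v == root) {
      third <- setdiff(ch, leaf_ch)
      sup <- if (length(third) == 1L && third > ntip)
        node_support(tree, third) else NA_real_
    }
    if (is.na(sup) || sup >= min_support) {
      pr <- sort(tree$tip.label[leaf_ch])
      out[[length(out) + 1L]] <- data.frame(
        gene_a = pr[1], gene_b = pr[2],
        support = if (is.na(sup)) NA_real_ else sup,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      support = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Assign leaves to k subgroups by cutting deep edges
#'
#' Edges are ranked by depth (the longest branch-length path from the
#' edge's lower endpoint to any descendant leaf; terminal edges have
#' depth 0) and cut greedily, deepest first, keeping only cuts that
#' increase the number of leaf-containing components, until the leaves
#' fall into `k` groups. Ties are broken by edge index, so the cut is
#' deterministic.
#'
#' @param tree A `phylo` tree.
#' @param k Number of subgroups (1..number of leaves).
#' @return Named character vector mapping each leaf to a Roman-numeral
#'   subgroup label ("I", "II", ...), numbered in tree tip order.
#' @export
assign_subgroups <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1L || k > ntip) stop("k must be between 1 and the leaf count")
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))
  # depth of each node: longest path down to a leaf
  depth <- rep(NA_real_, nnode)
  depth[seq_len(ntip)] <- 0
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  while (anyNA(depth)) {
    progressed <- FALSE
    for (v in as.integer(names(kids))) {
      es <- kids[[as.character(v)]]
      if (is.na(depth[v]) && all(!is.na(depth[edge[es, 2]]))) {
        depth[v] <- max(depth[edge[es, 2]] + elen[es])
        progressed <- TRUE
      }
    }
    if (!progressed) stop("malformed tree: cycle in edge table")
  }
  edge_depth <- depth[edge[, 2]]
  ord <- order(-edge_depth, seq_len(nrow(edge)))
  cut <- rep(FALSE, nrow(edge))
  groups_of <- function(cut) {
    # union-find over nodes joined by uncut edges
    parent <- seq_len(nnode)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in which(!cut)) {
      a <- find(edge[e, 1]); b <- find(edge[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(ntip), find, integer(1))
  }
  gl <- groups_of(cut)
  if (length(unique(gl)) > k) stop("tree too disconnected for k groups")
  for (e in ord) {
    if (length(unique(gl)) >= k) break
    cut2 <- cut; cut2[e] <- TRUE
    gl2 <- groups_of(cut2)
    if (length(unique(gl2)) == length(unique(gl)) + 1L) {
      cut <- cut2; gl <- gl2
    }
  }
  labels <- setNames(rep(NA_character_, ntip), tree$tip.label)
  next_lab <- 1L
  seen <- integer()
  for (i in seq_len(ntip)) {
    g <- gl[i]
    if (!g %in% seen) { seen <- c(seen, g) }
  }
  roman <- as.character(utils::as.roman(seq_along(seen)))
  labels[] <- roman[match(gl, seen)]
  labels
}
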