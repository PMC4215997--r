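# Expression: RPKM normalization, expressed-gene filtering,
# correlation-distance hierarchical clustering and cluster cutting.
#
# Matrices are plain numeric matrices (genes x conditions) with a
# "state" attribute in {raw_counts, rpkm, log2}; clustering wraps
# stats::hclust behind the module surface.

#' Construct an expression matrix
#'
#' @param m Numeric matrix, genes in rows, conditions in columns; no
#'   negative entries; unique dimnames.
#' @param state One of `"raw_counts"`, `"rpkm"`, `"log2"`.
#' @return `m` with class `expression_matrix` and a `state` attribute.
#' @export
expression_matrix <- function(m, state = c("raw_counts", "rpkm", "log2")) {
  state <- match.arg(state)
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene and condition names")
  if (anyDuplicated(colnames(m))) stop("condition labels must be unique")
  if (anyDuplicated(rownames(m))) stop("gene ids must be unique")
  structure(m, state = state, class = c("expression_matrix", "matrix"))
}

#' Read an expression matrix from TSV (genes x conditions, header row)
#'
#' @param path TSV file; first column gene ids.
#' @param state Normalization state of the stored values.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, state = "raw_counts") {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  expression_matrix(m, state = state)
}

#' RPKM normalization
#'
#' value = count / (gene length in kb) / (library size in millions).
#'
#' @param counts An `expression_matrix` in state `raw_counts`.
#' @param gene_lengths_bp Named vector of transcript lengths (> 0) covering
#'   every gene in `counts`.
#' @param library_sizes Named vector of mapped-read totals (> 0) per
#'   condition; a single unnamed value is recycled.
#' @return An `expression_matrix` in state `rpkm`.
#' @export
rpkm_normalize <- function(counts, gene_lengths_bp, library_sizes) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (attr(counts, "state") != "raw_counts")
    stop("rpkm_normalize expects raw counts")
  genes <- rownames(counts)
  if (!all(genes %in% names(gene_lengths_bp)))
    stop("missing gene length for: ",
         paste(setdiff(genes, names(gene_lengths_bp)), collapse = ", "))
  len <- gene_lengths_bp[genes]
  if (any(len <= 0)) stop("gene lengths must be > 0")
  if (length(library_sizes) == 1L && is.null(names(library_sizes)))
    library_sizes <- setNames(rep(library_sizes, ncol(counts)),
                              colnames(counts))
  if (!all(colnames(counts) %in% names(library_sizes)))
    stop("missing library size for: ",
         paste(setdiff(colnames(counts), names(library_sizes)),
               collapse = ", "))
  lib <- library_sizes[colnames(counts)]
  if (any(lib <= 0)) stop("library sizes must be > 0")
  out <- sweep(unclass(counts), 1, len / 1000, "/")
  out <- sweep(out, 2, lib / 1e6, "/")
  expression_matrix(out, state = "rpkm")
}

#' Log2(x + 1) transform
#'
#' @param m An `expression_matrix` (any non-log state).
#' @return An `expression_matrix` in state `log2`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (attr(m, "state") == "log2") stop("matrix is already log2")
  expression_matrix(log2(unclass(m) + 1), state = "log2")
}

#' Genes expressed in at least one condition
#'
#' @param m An `expression_matrix`.
#' @param min_value Expression threshold; a gene is expressed when some
#'   condition exceeds it (strictly).
#' @return Character vector of expressed gene ids, input order.
#' @export
expressed_filter <- function(m, min_value = 0) {
  stopifnot(inherits(m, "expression_matrix"))
  rownames(m)[apply(unclass(m) > min_value, 1, any)]
}

#' Hierarchical clustering of genes across conditions
#'
#' Agglomerative clustering of the gene rows under the chosen distance
#' (`pearson` distance = 1 - Pearson correlation across conditions, the
#' Cluster-3.0-style default for expression heat maps) and linkage.
#'
#' @param m An `expression_matrix` (>= 2 genes).
#' @param distance `"pearson"` or `"euclidean"`. Pearson requires every
#'   row to be non-constant.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return A `gene_dendrogram`: the underlying `hclust` plus distance and
#'   linkage tags.
#' @export
hierarchical_cluster <- function(m, distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete",
                                             "single")) {
  stopifnot(inherits(m, "expression_matrix"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- unclass(m)
  if (nrow(x) < 2L) stop("clustering needs >= 2 genes")
  if (distance == "pearson") {
    constant <- apply(x, 1, function(r) sd(r) == 0)
    if (any(constant))
      stop("constant row(s) under pearson distance: ",
           paste(rownames(x)[constant], collapse = ", "), call. = FALSE)
    d <- as.dist(1 - cor(t(x)))
  } else {
    d <- dist(x)
  }
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, distance = distance, linkage = linkage,
                 ids = rownames(x)),
            class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("gene dendrogram: %d genes, %s distance, %s linkage\n",
              length(x$ids), x$distance, x$linkage))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param d A `gene_dendrogram`.
#' @param k Number of clusters (1..n genes).
#' @return Named integer vector gene -> cluster, with cluster labels
#'   renumbered in order of first member appearance (matrix row order).
#' @export
cut_clusters <- function(d, k) {
  stopifnot(inherits(d, "gene_dendrogram"))
  n <- length(d$ids)
  if (k < 1L || k > n) stop("k must be between 1 and the gene count")
  raw <- cutree(d$hclust, k = k)
  first <- unique(raw)
  setNames(match(raw, first), names(raw))
}

#' Dendrogram merge table
#'
#' @param d A `gene_dendrogram`.
#' @return Data.frame of the n-1 merges with their heights.
#' @export
merge_table <- function(d) {
  stopifnot(inherits(d, "gene_dendrogram"))
  hc <- d$hclust
  data.frame(step = seq_len(nrow(hc$merge)),
             a = hc$merge[, 1], b = hc$merge[, 2],
             height = hc$height)
}
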