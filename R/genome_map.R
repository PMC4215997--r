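# Genome organization: chromosomal distribution, tandem clusters,
# tandem/segmental duplication classification.

#' Per-chromosome distribution summary
#'
#' @param genes A `gene_records` data.frame.
#' @return A list with `counts` (named integer vector over all 20
#'   chromosome labels), `occupied_count`, `absent` (labels with zero
#'   genes) and `n_genes`.
#' @export
chromosome_summary <- function(genes) {
  chroms <- soybean_chromosomes()
  counts <- table(factor(genes$chromosome, levels = chroms))
  counts <- setNames(as.integer(counts), chroms)
  list(counts = counts,
       occupied_count = sum(counts > 0L),
       absent = names(counts)[counts == 0L],
       n_genes = nrow(genes))
}

#' Detect tandem clusters of neighbouring genes
#'
#' Per chromosome, genes are ordered by strand-normalized start and
#' grouped into maximal runs where the gap between successive intervals
#' (`next start - previous end`) is at most `max_gap_bp` (boundary
#' inclusive; overlapping genes always group). Singleton genes are
#' returned as size-1 clusters, so clusters partition the input.
#'
#' @param genes A `gene_records` data.frame.
#' @param max_gap_bp Maximum inter-gene gap in bp (default 20000, wide
#'   enough to capture the family's largest observed same-cluster gap
#'   of ~19 kb without merging across unrelated neighbourhoods).
#' @return A data.frame with one row per cluster: `chromosome`,
#'   `members` (comma-joined, position order), `n_members`, `span_bp`
#'   (max(end) - min(start)).
#' @export
detect_tandem_clusters <- function(genes, max_gap_bp = 20000) {
  if (length(max_gap_bp) != 1L || is.na(max_gap_bp) || max_gap_bp < 0)
    stop("max_gap_bp must be a non-negative number")
  out <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    gap_prev <- c(Inf, g$start[-1] - g$end[-nrow(g)])
    cluster_id <- cumsum(gap_prev > max_gap_bp)
    for (k in unique(cluster_id)) {
      m <- g[cluster_id == k, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        members = paste(m$gene_id, collapse = ","),
        n_members = nrow(m),
        span_bp = max(m$end) - min(m$start),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), members = character(),
                      n_members = integer(), span_bp = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Tandem: both genes on one chromosome with an inter-gene gap of at most
#' `tandem_window_bp`. Otherwise segmental, with the fragment class taken
#' from the duplicated block covering the pair: `"large"` when the block
#' exceeds `large_threshold_bp` (default 1 Mb), else `"small"`. A
#' segmental pair covered by no block gets fragment class `NA` with a
#' warning. Symmetric in the two genes.
#'
#' @param gene_a,gene_b Single-row `gene_records` (or rows of one).
#' @param blocks A `duplicated_blocks` data.frame (may be `NULL`).
#' @param tandem_window_bp Maximum same-chromosome gap for a tandem call.
#' @param large_threshold_bp Block length above which a segmental
#'   duplication is a long fragment.
#' @return A list with `mode` ("tandem"/"segmental") and
#'   `fragment_class` ("large"/"small"/NA).
#' @export
classify_duplication <- function(gene_a, gene_b, blocks = NULL,
                                 tandem_window_bp = 20000,
                                 large_threshold_bp = 1e6) {
  stopifnot(nrow(gene_a) == 1L, nrow(gene_b) == 1L)
  if (gene_a$chromosome == gene_b$chromosome) {
    gap <- max(gene_a$start, gene_b$start) - min(gene_a$end, gene_b$end)
    if (gap <= tandem_window_bp)
      return(list(mode = "tandem", fragment_class = NA_character_))
  }
  blk <- covering_block(gene_a, gene_b, blocks)
  if (is.null(blk)) {
    warning("no duplicated block covers pair ", gene_a$gene_id, "/",
            gene_b$gene_id, "; fragment class unset", call. = FALSE)
    return(list(mode = "segmental", fragment_class = NA_character_))
  }
  list(mode = "segmental",
       fragment_class = if (blk$length_bp > large_threshold_bp)
         "large" else "small")
}

# A block covers the pair when one gene overlaps side A and the other
# side B (either orientation). Returns the longest covering block or NULL.
covering_block <- function(gene_a, gene_b, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(NULL)
  hits <- function(g, chrom, s, e)
    g$chromosome == chrom & g$start <= e & g$end >= s
  a_in_a <- hits(gene_a, blocks$chrom_a, blocks$start_a, blocks$end_a)
  a_in_b <- hits(gene_a, blocks$chrom_b, blocks$start_b, blocks$end_b)
  b_in_a <- hits(gene_b, blocks$chrom_a, blocks$start_a, blocks$end_a)
  b_in_b <- hits(gene_b, blocks$chrom_b, blocks$start_b, blocks$end_b)
  cov <- (a_in_a & b_in_b) | (a_in_b & b_in_a)
  if (!any(cov)) return(NULL)
  blocks[which(cov)[which.max(blocks$length_bp[cov])], , drop = FALSE]
}
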