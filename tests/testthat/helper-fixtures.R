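# Shared toy fixtures, built in code.

# 12-codon toy pair: one third-position synonymous change (AAC -> AAT)
# and one first-position nonsynonymous change (GAT -> CAT). No codon is
# one mutation away from a stop, so site counts do not depend on the
# stop-elimination convention.
toy_codon_pair <- function() {
  c(a = "ATGAACCCCGGGTTTCTGGATCACGCTACTCTTGTT",
    b = "ATGAATCCCGGGTTTCTGCATCACGCTACTCTTGTT")
}

# distance matrix of a random binary tree with positive branch lengths
random_additive_case <- function(n) {
  t0 <- ape::rtree(n)
  t0$edge.length <- runif(nrow(t0$edge), 0.1, 2)
  list(tree = t0, d = ape::cophenetic.phylo(t0))
}

# do two label vectors describe the same partition?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1)
}

# single-row subsets of a gene_records table, by symbol
gene_row <- function(genes, id) {
  genes[genes$gene_id == id, , drop = FALSE]
}
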