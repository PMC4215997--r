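# Domestication selection scan: reverse allele-distribution classifier,
# per-gene summaries, haplotype counting.

#' Classify a SNP site as selected (reverse allele distribution)
#'
#' Let s_w be the sign of (wild count of allele A minus allele B) and s_c
#' the same for cultivars. The site is selected when the majority allele
#' reverses between the panels: s_w * s_c < 0, or exactly one panel is
#' tied (s = 0) while the other has a strict majority. Both-tied sites
#' and same-direction majorities are not selected. The verdict is
#' invariant under allele relabeling and under swapping the two panels.
#'
#' @param sites A `snp_sites` data.frame (one or more rows).
#' @return Logical vector, one verdict per site. Sites where either
#'   population has zero observed calls are `NA` with a warning.
#' @export
classify_site <- function(sites) {
  sw <- sign(sites$wild_a - sites$wild_b)
  sc <- sign(sites$cult_a - sites$cult_b)
  verdict <- (sw * sc < 0) | xor(sw == 0, sc == 0)
  empty <- (sites$wild_a + sites$wild_b == 0L) |
    (sites$cult_a + sites$cult_b == 0L)
  if (any(empty)) {
    warning(sum(empty), " site(s) with zero observed calls in a panel ",
            "skipped", call. = FALSE)
    verdict[empty] <- NA
  }
  verdict
}

#' Per-gene and global selection summary
#'
#' Classifies every site, then aggregates: per gene the number of sites
#' tested, number selected, and whether all its sites are selected;
#' globally the number of genes with any selected site and with more
#' than one.
#'
#' @param sites A `snp_sites` data.frame.
#' @return A list with `per_gene` (data.frame) and global counts
#'   `genes_with_any`, `genes_with_multiple`, `n_sites`, `n_selected`.
#' @export
summarize_selection <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L)
    return(list(per_gene = data.frame(gene_id = character(),
                                      n_sites_tested = integer(),
                                      n_sites_selected = integer(),
                                      all_sites_selected = logical(),
                                      stringsAsFactors = FALSE),
                genes_with_any = 0L, genes_with_multiple = 0L,
                n_sites = 0L, n_selected = 0L))
  verdict <- classify_site(sites)
  keep <- !is.na(verdict)
  genes <- unique(sites$gene_id[keep])
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    v <- verdict[keep & sites$gene_id == g]
    data.frame(gene_id = g,
               n_sites_tested = length(v),
               n_sites_selected = sum(v),
               all_sites_selected = length(v) > 0 && all(v),
               stringsAsFactors = FALSE)
  }))
  list(per_gene = per_gene,
       genes_with_any = sum(per_gene$n_sites_selected >= 1L),
       genes_with_multiple = sum(per_gene$n_sites_selected > 1L),
       n_sites = sum(keep),
       n_selected = sum(verdict[keep]))
}

#' Count distinct haplotypes per population
#'
#' @param wild,cult Character vectors of haplotype strings (the ordered
#'   alleles across a gene's SNPs, one string per individual). All
#'   strings within a gene must have equal length.
#' @return A list with `n_wild`, `n_cult` (distinct haplotype counts),
#'   `private_wild`, `private_cult` (haplotypes seen in only one panel),
#'   and `shared`.
#' @export
count_haplotypes <- function(wild, cult) {
  lens <- unique(nchar(c(wild, cult)))
  if (length(lens) > 1L)
    stop("haplotype strings must have equal length", call. = FALSE)
  uw <- unique(wild); uc <- unique(cult)
  list(n_wild = length(uw), n_cult = length(uc),
       private_wild = sort(setdiff(uw, uc)),
       private_cult = sort(setdiff(uc, uw)),
       shared = sort(intersect(uw, uc)))
}

#' Read a wild/cultivar SNP panel from VCF
#'
#' Biallelic SNPs are mapped to per-population allele counts over the
#' declared sample lists; multiallelic or non-SNP records are skipped
#' with a warning. Counts are over observed calls only (missing
#' genotypes contribute nothing).
#'
#' @param path VCF file (plain text).
#' @param wild_samples,cult_samples Character vectors of sample names.
#' @param gene_id Gene symbol to assign to the sites (single value or one
#'   per kept record).
#' @return A `snp_sites` data.frame.
#' @export
read_vcf_panel <- function(path, wild_samples, cult_samples,
                           gene_id = "gene") {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header)) stop("VCF header line (#CHROM) not found")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  miss_w <- setdiff(wild_samples, samples)
  miss_c <- setdiff(cult_samples, samples)
  if (length(miss_w) || length(miss_c))
    stop("samples absent from VCF: ",
         paste(c(miss_w, miss_c), collapse = ", "))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  recs <- strsplit(body, "\t", fixed = TRUE)
  out <- list(); skipped <- 0L
  count_alleles <- function(gt) {
    al <- unlist(strsplit(gt, "[/|]"))
    al <- al[al %in% c("0", "1")]
    c(ref = sum(al == "0"), alt = sum(al == "1"))
  }
  for (r in recs) {
    ref <- r[4]; alt <- r[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt)) {
      skipped <- skipped + 1L; next
    }
    gts <- sub(":.*$", "", r[-(1:9)])
    names(gts) <- samples
    w <- rowSums(vapply(gts[wild_samples], count_alleles, numeric(2)))
    cu <- rowSums(vapply(gts[cult_samples], count_alleles, numeric(2)))
    out[[length(out) + 1L]] <- data.frame(
      position = as.numeric(r[2]), allele_a = ref, allele_b = alt,
      wild_a = w[["ref"]], wild_b = w[["alt"]],
      cult_a = cu[["ref"]], cult_b = cu[["alt"]],
      stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " multiallelic/non-SNP record(s) skipped",
            call. = FALSE)
  if (!length(out))
    return(snp_sites(character(), numeric(), character(), character(),
                     integer(), integer(), integer(), integer()))
  df <- do.call(rbind, out)
  snp_sites(rep_len(gene_id, nrow(df)), df$position, df$allele_a,
            df$allele_b, df$wild_a, df$wild_b, df$cult_a, df$cult_b)
}
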