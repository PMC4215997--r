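# End-to-end orchestration over whatever inputs are supplied, plus a
# self-check that recomputes the published family numbers from the
# packaged fixtures.

#' Run the family analysis pipeline
#'
#' Executes the stages for which inputs are available: genome map
#' (chromosome summary, tandem clusters, optional pair classification
#' against duplicated blocks), Ka/Ks dating summary, selection scan,
#' phylogeny (NJ + bootstrap + paralog pairs) and expression clustering.
#' Absent inputs mark their stage "skipped". Same inputs + seed give an
#' identical report.
#'
#' @param genes `gene_records` (default: the packaged family table).
#' @param pairs `duplicate_pairs` (default: the packaged pair table).
#' @param sites `snp_sites` (default: the packaged selected-site table).
#' @param blocks Optional `duplicated_blocks` for fragment-size classing.
#' @param aln Optional protein alignment for the phylogeny stage.
#' @param expr Optional `expression_matrix` for the clustering stage.
#' @param lam Synonymous rate for dating.
#' @param tandem_window_bp,large_threshold_bp,ratio_threshold,min_support,k_expr
#'   Stage parameters (see the stage functions).
#' @param n_bootstrap Bootstrap replicates for the phylogeny stage.
#' @param seed RNG seed (bootstrap).
#' @param out_dir Optional directory; when given, per-stage TSVs and a
#'   JSON report are written there.
#' @return The report, an object of class `cupin_report` (a list).
#' @export
run_pipeline <- function(genes = load_table1_fixture(warn_span = FALSE),
                         pairs = load_table2_fixture(),
                         sites = load_table3_fixture(),
                         blocks = NULL, aln = NULL, expr = NULL,
                         lam = SOYBEAN_LAMBDA,
                         tandem_window_bp = 20000,
                         large_threshold_bp = 1e6,
                         ratio_threshold = 0.3,
                         min_support = 50, k_expr = 5L,
                         n_bootstrap = 100L, seed = 1L,
                         out_dir = NULL) {
  cfg <- kaks_config(lam = lam)
  report <- list(parameters = list(
    lam = lam, tandem_window_bp = tandem_window_bp,
    large_threshold_bp = large_threshold_bp,
    ratio_threshold = ratio_threshold, min_support = min_support,
    k_expr = k_expr, n_bootstrap = n_bootstrap, seed = seed))

  report$map <- if (is.null(genes)) "skipped" else {
    cs <- chromosome_summary(genes)
    clusters <- detect_tandem_clusters(genes, tandem_window_bp)
    cls <- NULL
    if (!is.null(pairs) && nrow(pairs)) {
      gid <- normalize_gene_id(genes$gene_id)
      cls <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        ia <- match(normalize_gene_id(pairs$gene_a[i]), gid)
        ib <- match(normalize_gene_id(pairs$gene_b[i]), gid)
        if (is.na(ia) || is.na(ib))
          return(data.frame(gene_a = pairs$gene_a[i],
                            gene_b = pairs$gene_b[i],
                            mode = NA_character_,
                            fragment_class = NA_character_,
                            stringsAsFactors = FALSE))
        cl <- suppressWarnings(classify_duplication(
          genes[ia, , drop = FALSE], genes[ib, , drop = FALSE], blocks,
          tandem_window_bp, large_threshold_bp))
        data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
                   mode = cl$mode, fragment_class = cl$fragment_class,
                   stringsAsFactors = FALSE)
      }))
    }
    list(chromosome_counts = cs$counts,
         occupied_chromosomes = cs$occupied_count,
         absent_chromosomes = cs$absent,
         mean_aa_length = mean(genes$aa_length),
         clusters = clusters,
         pair_classification = cls)
  }

  report$kaks <- if (is.null(pairs)) "skipped" else {
    s <- summarize_pairs(pairs, ratio_threshold)
    tab <- pairs
    tab$date_recomputed_mya <- date_duplication(pairs$ks, cfg)
    list(table = tab, summary = s,
         mean_ks = round(s$ks_mean, 4),
         mean_date_mya = round(s$date_mean, 2),
         min_date_mya = s$date_min, max_date_mya = s$date_max,
         pct_family_in_pairs = if (!is.null(genes))
           round(100 * 2 * nrow(pairs) / nrow(genes), 1) else NA_real_)
  }

  report$selection <- if (is.null(sites)) "skipped" else {
    s <- summarize_selection(sites)
    c(s, list(genes_with_selected_sites = s$genes_with_any))
  }

  report$phylo <- if (is.null(aln)) "skipped" else {
    tree <- bootstrap_support(aln, n_reps = n_bootstrap, seed = seed)
    prs <- extract_paralog_pairs(tree, min_support = min_support)
    list(tree_newick = ape::write.tree(tree), paralog_pairs = prs)
  }

  report$expression <- if (is.null(expr)) "skipped" else {
    expressed <- expressed_filter(expr)
    sub <- expression_matrix(unclass(expr)[expressed, , drop = FALSE],
                             state = attr(expr, "state"))
    dend <- hierarchical_cluster(sub)
    list(n_expressed = length(expressed),
         clusters = cut_clusters(dend, min(k_expr, length(expressed))))
  }

  class(report) <- "cupin_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cupin_report <- function(x, ...) {
  cat("cupin family analysis report\n")
  if (!identical(x$map, "skipped"))
    cat(sprintf("  map: %d genes on %d chromosomes (absent: %s)\n",
                sum(x$map$chromosome_counts),
                x$map$occupied_chromosomes,
                paste(x$map$absent_chromosomes, collapse = ",")))
  if (!identical(x$kaks, "skipped"))
    cat(sprintf("  kaks: %d pairs, mean Ks %.4f, mean date %.2f Mya\n",
                x$kaks$summary$n_pairs, x$kaks$mean_ks,
                x$kaks$mean_date_mya))
  if (!identical(x$selection, "skipped"))
    cat(sprintf("  selection: %d/%d sites selected in %d genes\n",
                x$selection$n_selected, x$selection$n_sites,
                x$selection$genes_with_any))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!identical(report$map, "skipped")) {
    tsv(data.frame(chromosome = names(report$map$chromosome_counts),
                   n_genes = report$map$chromosome_counts), "chromosomes.tsv")
    tsv(report$map$clusters, "clusters.tsv")
    if (!is.null(report$map$pair_classification))
      tsv(report$map$pair_classification, "pair_classification.tsv")
  }
  if (!identical(report$kaks, "skipped"))
    tsv(report$kaks$table, "kaks_dates.tsv")
  if (!identical(report$selection, "skipped"))
    tsv(report$selection$per_gene, "selection_per_gene.tsv")
  json <- report
  json$map$clusters <- NULL; json$kaks$table <- NULL
  jsonlite::write_json(unclass(json), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Recompute the published family numbers from the packaged fixtures
#'
#' Each published quantity is recomputed from the packaged tables and
#' compared with its printed value; reruns are identical.
#'
#' @return A data.frame with `target`, `expected`, `computed`, `pass`;
#'   printed as a pass/fail table.
#' @export
verify_paper_targets <- function() {
  genes <- load_table1_fixture(warn_span = FALSE)
  pairs <- load_table2_fixture()
  sites <- load_table3_fixture()
  cs <- chromosome_summary(genes)
  clus <- detect_tandem_clusters(genes, 20000)
  ps <- summarize_pairs(pairs, 0.3)
  sel <- summarize_selection(sites)
  chr16_first <- clus[clus$chromosome == "Gm16" &
                        grepl("Gmcupin16.1,", clus$members, fixed = TRUE), ]
  rows <- list(
    c("family size", 69, nrow(genes)),
    c("occupied chromosomes", 17, cs$occupied_count),
    c("genes on Gm19", 15, unname(cs$counts["Gm19"])),
    c("empty chromosomes", 3, length(cs$absent)),
    c("mean peptide length (aa)", 224, round(mean(genes$aa_length))),
    c("chr16 three-gene cluster span (bp)", 8478,
      chr16_first$span_bp[1]),
    c("duplicate pairs", 18, ps$n_pairs),
    c("pct of family in pairs", 52.2,
      round(100 * 2 * ps$n_pairs / nrow(genes), 1)),
    c("date for Ks 0.1177 (Mya)", 9.65, date_duplication(0.1177)),
    c("date for Ks 0.0909 (Mya)", 7.45, date_duplication(0.0909)),
    c("mean Ks", 0.1682, round(ps$ks_mean, 4)),
    c("mean date (Mya)", 13.78, round(ps$date_mean, 2)),
    c("min date (Mya)", 7.45, ps$date_min),
    c("max date (Mya)", 28.66, ps$date_max),
    c("segmental pairs with Ka/Ks < 0.3", 8, ps$segmental_ratio_below),
    c("large-fragment pairs", 13, ps$n_fragment_large),
    c("small-fragment pairs", 4, ps$n_fragment_small),
    c("genes with selected site(s)", 16, sel$genes_with_any),
    c("genes with multiple selected sites", 8, sel$genes_with_multiple),
    c("selected sites", 38, sel$n_selected)
  )
  out <- data.frame(
    target = vapply(rows, `[[`, "", 1),
    expected = as.numeric(vapply(rows, `[[`, "", 2)),
    computed = as.numeric(vapply(rows, `[[`, "", 3)),
    stringsAsFactors = FALSE)
  out$pass <- abs(out$expected - out$computed) < 1e-9
  out
}
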