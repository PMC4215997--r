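# Seed-deterministic simulators emulating the study's inputs: codon
# sequences diverged to a target Ks under a syn/nonsyn rate ratio,
# wild/cultivar allele-count panels with planted majority reversals, and
# expression matrices with planted tissue-specific clusters.

#' Simulation configuration
#'
#' Defaults mirror the study's conditions: the soybean synonymous rate
#' lambda = 6.1e-9/site/year, the ~13-Mya Glycine-specific duplication,
#' panels of 17 wild and 14 cultivated accessions, a 69-gene family with
#' 35 expressed members, and strong purifying selection (Ka/Ks = 0.2).
#'
#' @param seed Integer RNG seed.
#' @param n_codons Codons per simulated CDS.
#' @param duplication_mya Duplication times (Mya), most ancient first.
#' @param lam Synonymous rate per site per year.
#' @param kaks Target Ka/Ks of the substitution process.
#' @param n_snp_sites Number of SNP sites in a simulated panel.
#' @param n_wild,n_cult Panel sizes (observed calls per site).
#' @param fraction_selected Fraction of SNP sites planted as
#'   majority-reversal (selected) sites.
#' @param contrast Frequency contrast of planted sites: wild frequency of
#'   allele A is (1+contrast)/2, cultivar frequency (1-contrast)/2;
#'   1 means fixed differences.
#' @param sites_per_gene SNP sites are grouped into genes of this size.
#' @param n_genes Family size for the expression simulator.
#' @param n_expressed Genes with nonzero expression (the rest all-zero).
#' @param n_tissues,n_clusters Expression design: conditions and planted
#'   tissue-specific groups.
#' @param signal Mean expression in a cluster's own tissue block.
#' @param noise Multiplicative log-normal noise sd (0 = noiseless).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_codons = 500L,
                       duplication_mya = 13, lam = SOYBEAN_LAMBDA,
                       kaks = 0.2, n_snp_sites = 100L, n_wild = 17L,
                       n_cult = 14L, fraction_selected = 0.1,
                       contrast = 0.8, sites_per_gene = 5L,
                       n_genes = 69L, n_expressed = 35L, n_tissues = 11L,
                       n_clusters = 5L, signal = 100, noise = 0.2) {
  stopifnot(n_codons > 0, lam > 0, kaks >= 0, n_snp_sites >= 0,
            n_wild > 0, n_cult > 0,
            fraction_selected >= 0, fraction_selected <= 1,
            contrast >= 0, contrast <= 1, n_genes > 0,
            n_expressed >= 0, n_expressed <= n_genes,
            n_tissues >= 2, n_clusters >= 1, signal > 0, noise >= 0)
  structure(list(seed = as.integer(seed), n_codons = as.integer(n_codons),
                 duplication_mya = duplication_mya, lam = lam, kaks = kaks,
                 n_snp_sites = as.integer(n_snp_sites),
                 n_wild = as.integer(n_wild), n_cult = as.integer(n_cult),
                 fraction_selected = fraction_selected, contrast = contrast,
                 sites_per_gene = as.integer(sites_per_gene),
                 n_genes = as.integer(n_genes),
                 n_expressed = as.integer(n_expressed),
                 n_tissues = as.integer(n_tissues),
                 n_clusters = as.integer(n_clusters),
                 signal = signal, noise = noise),
            class = "sim_config")
}

sense_codons <- function(genetic_code = Biostrings::GENETIC_CODE) {
  names(genetic_code)[genetic_code != "*"]
}

# single-nucleotide change options of a codon, split syn/nonsyn
# (changes to stops excluded from both lists)
codon_options <- function(codon, genetic_code) {
  aa <- genetic_code[[codon]]
  syn <- list(); nonsyn <- list()
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      maa <- genetic_code[[mut]]
      if (maa == "*") next
      if (maa == aa) syn[[length(syn) + 1L]] <- mut
      else nonsyn[[length(nonsyn) + 1L]] <- mut
    }
  }
  list(syn = unlist(syn), nonsyn = unlist(nonsyn))
}

# Evolve a codon vector for `years` under synonymous rate lam per
# synonymous site and nonsynonymous rate lam*omega per nonsynonymous
# site; stop codons are rejected by construction. NG86 site counts
# define the per-codon rates, so the realized pairwise Ks of two
# lineages diverged T years matches 2*lam*T in expectation.
evolve_codons <- function(codons, years, lam, omega, genetic_code) {
  syn_sites <- vapply(codons, ng86_syn_sites, 0, genetic_code = genetic_code)
  S <- sum(syn_sites)
  N <- 3 * length(codons) - S
  n_syn <- rpois(1, lam * years * S)
  n_nonsyn <- rpois(1, lam * omega * years * N)
  events <- sample(rep(c("s", "n"), c(n_syn, n_nonsyn)))
  for (ev in events) {
    w <- if (ev == "s") syn_sites else 3 - syn_sites
    if (sum(w) <= 0) next
    i <- sample.int(length(codons), 1L, prob = w)
    opts <- codon_options(codons[i], genetic_code)
    pool <- if (ev == "s") opts$syn else opts$nonsyn
    if (is.null(pool) || !length(pool)) next
    codons[i] <- pool[sample.int(length(pool), 1L)]
    syn_sites[i] <- ng86_syn_sites(codons[i], genetic_code)
  }
  codons
}

#' Simulate a duplicated gene family with known divergence times
#'
#' An ancestral random CDS is duplicated at the scheduled times (one
#' lineage duplicates per event); every lineage then accumulates codon
#' substitutions at synonymous rate lambda per synonymous site and
#' nonsynonymous rate lambda x Ka/Ks. Gene coordinates are laid out so
#' the first pair is tandem (adjacent on one chromosome) and later pairs
#' are cross-chromosome.
#'
#' @param cfg A [sim_config()].
#' @return A list: `cds`, `protein` (named character vectors), `genes`
#'   (`gene_records`), and `truth` (data.frame of pairs with split time
#'   and expected Ks = 2 lambda T).
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  gc_tab <- Biostrings::GENETIC_CODE
  set.seed(derive_seed(cfg$seed, 1L))
  exp_ks_max <- 2 * cfg$lam * max(c(0, cfg$duplication_mya)) * 1e6
  if (3 / 4 * (1 - exp(-4 / 3 * exp_ks_max)) >= 0.7)
    warning("schedule implies near-saturated Ks (Jukes-Cantor regime)",
            call. = FALSE)
  pool <- setdiff(sense_codons(gc_tab), c("ATG", "TGG")) # keep variety
  anc <- c("ATG", sample(pool, cfg$n_codons - 1L, replace = TRUE))
  times <- sort(cfg$duplication_mya, decreasing = TRUE)
  seqs <- list(anc)
  split_mya <- matrix(0, 1, 1)
  now <- if (length(times)) times[1] else 0
  for (t_ev in times) {
    # evolve all lineages from `now` down to the event time
    dt <- (now - t_ev) * 1e6
    if (dt > 0)
      seqs <- lapply(seqs, evolve_codons, years = dt, lam = cfg$lam,
                     omega = cfg$kaks, genetic_code = gc_tab)
    src <- sample.int(length(seqs), 1L)
    seqs[[length(seqs) + 1L]] <- seqs[[src]]
    k <- length(seqs)
    split_mya <- rbind(cbind(split_mya, 0), 0)
    split_mya[k, ] <- split_mya[src, ]
    split_mya[, k] <- split_mya[, src]
    split_mya[k, src] <- split_mya[src, k] <- t_ev
    split_mya[k, k] <- 0
    now <- t_ev
  }
  if (now > 0)
    seqs <- lapply(seqs, evolve_codons, years = now * 1e6, lam = cfg$lam,
                   omega = cfg$kaks, genetic_code = gc_tab)
  ids <- sprintf("simgene%02d", seq_along(seqs))
  cds <- setNames(vapply(seqs, paste, "", collapse = ""), ids)
  protein <- vapply(cds, function(s)
    paste(unname(gc_tab[split_codons(s)]), collapse = ""), "")
  n <- length(seqs)
  # coordinates: genes 1-2 adjacent on Gm01 (tandem layout), the rest
  # spread across chromosomes
  chrom <- c("Gm01", "Gm01",
             sprintf("Gm%02d", 1 + (seq_len(max(0, n - 2)) %% 19)))[1:n]
  start <- 10000 + (seq_len(n) - 1L) * 5000
  len <- cfg$n_codons * 3L
  genes <- gene_records(ids, ids, chrom, start, start + len - 1L,
                        aa_length = rep(cfg$n_codons, n),
                        n_exons = rep(1L, n), warn_span = FALSE)
  truth <- NULL
  if (n >= 2L) {
    idx <- which(upper.tri(split_mya), arr.ind = TRUE)
    truth <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                        split_mya = split_mya[idx],
                        expected_ks = 2 * cfg$lam * split_mya[idx] * 1e6,
                        stringsAsFactors = FALSE)
  }
  list(cds = cds, protein = protein, genes = genes, truth = truth)
}

#' Simulate a wild/cultivar SNP allele-count panel
#'
#' Planted selected sites put the wild major allele at frequency
#' (1+contrast)/2 and the cultivar major allele on the opposite allele;
#' neutral sites share a single per-site frequency (uniform on
#' 0.2..0.8) in both panels. Counts are binomial draws of the panel
#' sizes, so count totals never exceed them.
#'
#' @param cfg A [sim_config()].
#' @return A list: `sites` (`snp_sites`) and `truth` (data.frame with
#'   the planted flag and the generating frequencies).
#' @export
simulate_snp_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  n <- cfg$n_snp_sites
  n_sel <- round(cfg$fraction_selected * n)
  selected <- rep(c(TRUE, FALSE), c(n_sel, n - n_sel))
  p_wild <- numeric(n); p_cult <- numeric(n)
  p_wild[selected] <- (1 + cfg$contrast) / 2
  p_cult[selected] <- (1 - cfg$contrast) / 2
  shared <- runif(n - n_sel, 0.2, 0.8)
  p_wild[!selected] <- shared
  p_cult[!selected] <- shared
  wild_a <- rbinom(n, cfg$n_wild, p_wild)
  cult_a <- rbinom(n, cfg$n_cult, p_cult)
  gene_id <- sprintf("simgene%03d", ceiling(seq_len(n) / cfg$sites_per_gene))
  alleles <- cbind(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   NA_character_)
  alleles[, 2] <- vapply(alleles[, 1], function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1L), "")
  sites <- snp_sites(gene_id, seq_len(n) * 1000, alleles[, 1], alleles[, 2],
                     wild_a, cfg$n_wild - wild_a,
                     cult_a, cfg$n_cult - cult_a)
  truth <- data.frame(gene_id = gene_id, position = seq_len(n) * 1000,
                      selected = selected, p_wild = p_wild,
                      p_cult = p_cult, stringsAsFactors = FALSE)
  list(sites = sites, truth = truth)
}

#' Exact null reversal probability of the selection classifier
#'
#' For a neutral site with shared allele frequency p in both panels,
#' the probability that binomial counts of sizes n_wild and n_cult
#' produce a majority reversal (or a single-panel tie against a strict
#' majority) under the classifier's rule.
#'
#' @param p Shared allele frequency (vectorized).
#' @param n_wild,n_cult Panel sizes.
#' @return Probability per frequency.
#' @export
null_reversal_prob <- function(p, n_wild = 17L, n_cult = 14L) {
  vapply(p, function(pp) {
    pw <- stats::dbinom(0:n_wild, n_wild, pp)
    pc <- stats::dbinom(0:n_cult, n_cult, pp)
    sw <- sign(2 * (0:n_wild) - n_wild)
    sc <- sign(2 * (0:n_cult) - n_cult)
    grid <- outer(sw, sc)
    tie_one <- outer(sw == 0, sc == 0, xor)
    sum(outer(pw, pc)[grid < 0 | tie_one])
  }, numeric(1))
}

#' Simulate an expression matrix with planted tissue-specific clusters
#'
#' Expressed genes are split evenly into `n_clusters` groups, each with
#' mean `signal` in its own block of tissues and a low background (1)
#' elsewhere; multiplicative log-normal noise of sd `noise` is applied
#' (0 gives a noiseless matrix). The remaining genes are all-zero
#' (unexpressed).
#'
#' @param cfg A [sim_config()].
#' @return A list: `matrix` (an `expression_matrix`, state `rpkm`) and
#'   `truth` (data.frame with `expressed` flag and planted `cluster`).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 3L))
  genes <- sprintf("simgene%02d", seq_len(cfg$n_genes))
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  m <- matrix(0, cfg$n_genes, cfg$n_tissues,
              dimnames = list(genes, tissues))
  expressed <- seq_len(cfg$n_expressed)
  cluster <- rep(NA_integer_, cfg$n_genes)
  if (cfg$n_expressed > 0) {
    cluster[expressed] <- rep_len(seq_len(cfg$n_clusters), cfg$n_expressed)
    blocks <- split(seq_len(cfg$n_tissues),
                    rep_len(seq_len(cfg$n_clusters), cfg$n_tissues))
    for (g in expressed) {
      mu <- rep(1, cfg$n_tissues)
      mu[blocks[[cluster[g]]]] <- cfg$signal
      noise_fac <- if (cfg$noise > 0)
        exp(stats::rnorm(cfg$n_tissues, 0, cfg$noise)) else 1
      m[g, ] <- mu * noise_fac
    }
  }
  list(matrix = expression_matrix(m, state = "rpkm"),
       truth = data.frame(gene_id = genes,
                          expressed = seq_len(cfg$n_genes) %in% expressed,
                          cluster = cluster, stringsAsFactors = FALSE))
}
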