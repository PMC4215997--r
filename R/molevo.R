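# Molecular evolution: codon alignments, Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor correction, and Ks-based duplication dating.

GENETIC_CODE_STD <- NULL # resolved lazily from Biostrings

genetic_code_of <- function(config = NULL) {
  if (!is.null(config)) return(config$genetic_code)
  Biostrings::GENETIC_CODE
}

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Validate a codon alignment
#'
#' Rows must be equal-length, length divisible by 3, gaps in whole-codon
#' units (`---`), and free of internal stop codons (a trailing stop is
#' allowed and retained).
#'
#' @param x Named character vector of aligned CDS rows.
#' @param genetic_code Translation table (codon -> amino acid).
#' @return `x` with class `codon_alignment`.
#' @export
codon_alignment <- function(x, genetic_code = Biostrings::GENETIC_CODE) {
  x <- as_alignment(x)
  if (nchar(x[[1]]) %% 3 != 0)
    stop("codon alignment length must be divisible by 3")
  stops <- names(genetic_code)[genetic_code == "*"]
  for (id in names(x)) {
    cods <- split_codons(x[[id]])
    partial <- grepl("-", cods) & cods != "---"
    if (any(partial))
      stop(sprintf("'%s': gap not in whole-codon units at codon %d",
                   id, which(partial)[1]), call. = FALSE)
    is_stop <- cods %in% stops
    if (any(is_stop & seq_along(cods) < length(cods)))
      stop(sprintf("'%s': internal stop codon at codon %d",
                   id, which(is_stop)[1]), call. = FALSE)
  }
  structure(x, class = "codon_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue is replaced by its source codon and each protein gap by
#' `---`. The translated CDS (gaps removed, optional trailing stop
#' dropped) must match the protein row exactly.
#'
#' @param protein_aln Aligned protein sequences (named character vector).
#' @param cds Named character vector of unaligned CDS, ids matching
#'   `protein_aln`.
#' @param genetic_code Translation table.
#' @return A `codon_alignment`.
#' @export
backtranslate_alignment <- function(protein_aln, cds,
                                    genetic_code = Biostrings::GENETIC_CODE) {
  protein_aln <- as_alignment(protein_aln)
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing))
    stop("no CDS for: ", paste(missing, collapse = ", "), call. = FALSE)
  stops <- names(genetic_code)[genetic_code == "*"]
  out <- vapply(names(protein_aln), function(id) {
    prot <- strsplit(protein_aln[[id]], "")[[1]]
    nt <- toupper(gsub("-", "", cds[[id]]))
    if (nchar(nt) %% 3 != 0)
      stop(sprintf("'%s': CDS length %d not divisible by 3", id, nchar(nt)),
           call. = FALSE)
    cods <- split_codons(nt)
    if (length(cods) > 1L && cods[length(cods)] %in% stops)
      cods <- cods[-length(cods)]
    internal_stop <- cods %in% stops
    if (any(internal_stop))
      stop(sprintf("'%s': internal stop codon at codon %d", id,
                   which(internal_stop)[1]), call. = FALSE)
    res <- prot[prot != "-"]
    if (length(res) != length(cods))
      stop(sprintf("'%s': protein has %d residues but CDS has %d codons",
                   id, length(res), length(cods)), call. = FALSE)
    aa <- unname(genetic_code[cods])
    mismatch <- which(aa != res)
    if (length(mismatch))
      stop(sprintf(
        "'%s': translation mismatch at residue %d (codon %s -> %s, protein %s)",
        id, mismatch[1], cods[mismatch[1]], aa[mismatch[1]],
        res[mismatch[1]]), call. = FALSE)
    filled <- character(length(prot))
    filled[prot == "-"] <- "---"
    filled[prot != "-"] <- cods
    paste(filled, collapse = "")
  }, character(1))
  codon_alignment(setNames(out, names(protein_aln)),
                  genetic_code = genetic_code)
}

# --- NG86 internals -------------------------------------------------------

# Per-codon synonymous-site count: each of the 3 positions contributes
# s_i / (s_i + n_i) synonymous sites, where s_i and n_i count the
# synonymous and nonsynonymous single-nucleotide changes at that position
# (changes to stop codons are eliminated from the counting). Stop codons
# contribute zero sites.
ng86_syn_sites <- function(codon, genetic_code) {
  aa <- genetic_code[[codon]]
  if (is.na(aa) || aa == "*") return(0)
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    cur <- substr(codon, p, p)
    syn <- 0; nonsyn <- 0
    for (alt in setdiff(nts, cur)) {
      mut <- codon
      substr(mut, p, p) <- alt
      maa <- genetic_code[[mut]]
      if (maa == "*") next
      if (maa == aa) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    if (syn + nonsyn > 0) s <- s + syn / (syn + nonsyn)
  }
  s
}

# Average synonymous / nonsynonymous differences between two codons over
# all minimal mutational pathways; pathways through stop codons are
# excluded (if every pathway hits a stop, all are used as a fallback).
ng86_diffs <- function(ca, cb, genetic_code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else
    lapply(asplit(perms(pos), 1), as.integer)
  tallies <- list()
  for (ord in paths) {
    cur <- ca
    sd <- 0; nsd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (genetic_code[[nxt]] == "*") { valid <- FALSE; break }
      if (genetic_code[[nxt]] == genetic_code[[cur]]) sd <- sd + 1
      else nsd <- nsd + 1
      cur <- nxt
    }
    if (valid) tallies[[length(tallies) + 1L]] <- c(sd, nsd)
  }
  if (!length(tallies)) { # all pathways pass through stops: keep them all
    for (ord in paths) {
      cur <- ca; sd <- 0; nsd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (genetic_code[[nxt]] == genetic_code[[cur]]) sd <- sd + 1
        else nsd <- nsd + 1
        cur <- nxt
      }
      tallies[[length(tallies) + 1L]] <- c(sd, nsd)
    }
  }
  tm <- do.call(rbind, tallies)
  c(sd = mean(tm[, 1]), nd = mean(tm[, 2]))
}

# all permutations of a small vector (n <= 3 here)
perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of aligned coding sequences
#'
#' Synonymous-site fractions are averaged over the two sequences;
#' multi-position codon differences are averaged over all minimal
#' mutational pathways (pathways through stops excluded); the raw
#' proportions ps = Sd/S and pn = Nd/N get the Jukes-Cantor correction
#' d = -(3/4) ln(1 - 4p/3), flagged invalid when p >= 3/4. Codons with a
#' gap or ambiguity in either row are excluded, so S + N equals 3 times
#' the number of compared codons.
#'
#' @param caln A `codon_alignment`.
#' @param pair Character vector of two ids (defaults to the first two rows).
#' @param config A [kaks_config()].
#' @return A `kaks_result` list: `ka`, `ks`, `ratio` (`NA` when Ks = 0 or
#'   a correction is invalid), `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons`, `jc_valid` (named flags for ka and ks).
#' @export
ng86_kaks <- function(caln, pair = names(caln)[1:2], config = kaks_config()) {
  stopifnot(inherits(caln, "codon_alignment"),
            length(pair) == 2L, all(pair %in% names(caln)))
  gc_tab <- genetic_code_of(config)
  ca <- split_codons(caln[[pair[1]]])
  cb <- split_codons(caln[[pair[2]]])
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  # drop a shared trailing stop from the comparison
  stops <- names(gc_tab)[gc_tab == "*"]
  ok <- ok & !(ca %in% stops) & !(cb %in% stops)
  if (!any(ok))
    stop(sprintf("no comparable codons between '%s' and '%s'",
                 pair[1], pair[2]), call. = FALSE)
  ca <- ca[ok]; cb <- cb[ok]
  s_a <- sum(vapply(ca, ng86_syn_sites, 0, genetic_code = gc_tab))
  s_b <- sum(vapply(cb, ng86_syn_sites, 0, genetic_code = gc_tab))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) ng86_diffs(x, y, gc_tab), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  jc_valid <- c(ka = !is.na(ka), ks = !is.na(ks))
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = Sd, nonsyn_diffs = Nd,
                 n_codons = length(ca), jc_valid = jc_valid),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "NG86: Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (S = %.1f, N = %.1f, %d codons)\n",
    x$ka, x$ks, if (is.na(x$ratio)) "undef" else sprintf("%.4f", x$ratio),
    x$syn_sites, x$nonsyn_sites, x$n_codons))
  invisible(x)
}

#' Date a duplication event from Ks
#'
#' T = Ks / (2 lambda), in million years. The family analysis uses the
#' soybean synonymous rate lambda = 6.1e-9 per site per year.
#'
#' @param ks Synonymous substitutions per synonymous site (vectorized).
#' @param config A [kaks_config()] carrying lambda.
#' @param digits Decimal places for reporting (default 2, the table's
#'   print precision); `NULL` for the unrounded value.
#' @return Date(s) in Mya.
#' @export
date_duplication <- function(ks, config = kaks_config(), digits = 2) {
  if (any(is.na(ks)) || any(ks < 0)) stop("ks must be non-negative")
  t_mya <- ks / (2 * config$lam) / 1e6
  if (is.null(digits)) t_mya else round(t_mya, digits)
}

#' Summarize a duplicate-pair table
#'
#' Min/max/mean of Ks and date over all rows, counts of segmental pairs
#' with Ka/Ks below/at-or-above a threshold, tandem pairs counted
#' separately, and fragment-size class counts.
#'
#' @param pairs A `duplicate_pairs` data.frame.
#' @param ratio_threshold Ka/Ks ratio class boundary (default 0.3).
#' @return A list of summary statistics.
#' @export
summarize_pairs <- function(pairs, ratio_threshold = 0.3) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(n_pairs = 0L, n_segmental = 0L, n_tandem = 0L,
                ks_min = NA_real_, ks_max = NA_real_, ks_mean = NA_real_,
                date_min = NA_real_, date_max = NA_real_,
                date_mean = NA_real_,
                segmental_ratio_below = 0L, segmental_ratio_at_or_above = 0L,
                tandem_ratio_below = 0L, tandem_ratio_at_or_above = 0L,
                n_fragment_large = 0L, n_fragment_small = 0L))
  seg <- pairs$mode == "segmental"
  tan <- pairs$mode == "tandem"
  list(
    n_pairs = nrow(pairs),
    n_segmental = sum(seg),
    n_tandem = sum(tan),
    ks_min = min(pairs$ks), ks_max = max(pairs$ks),
    ks_mean = mean(pairs$ks),
    date_min = min(pairs$date_mya), date_max = max(pairs$date_mya),
    date_mean = mean(pairs$date_mya),
    segmental_ratio_below = sum(seg & !is.na(pairs$ratio) &
                                  pairs$ratio < ratio_threshold),
    segmental_ratio_at_or_above = sum(seg & !is.na(pairs$ratio) &
                                        pairs$ratio >= ratio_threshold),
    tandem_ratio_below = sum(tan & !is.na(pairs$ratio) &
                               pairs$ratio < ratio_threshold),
    tandem_ratio_at_or_above = sum(tan & !is.na(pairs$ratio) &
                                     pairs$ratio >= ratio_threshold),
    n_fragment_large = sum(pairs$fragment_class %in% "large"),
    n_fragment_small = sum(pairs$fragment_class %in% "small")
  )
}
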