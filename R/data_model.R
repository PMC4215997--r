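# Domain types and fixture loaders.
#
# Gene records, duplicate pairs and SNP sites are kept as classed
# data.frames with one row per record; coordinates are 1-based inclusive
# as printed, with strand inferred from reversed raw coordinates (the
# published family table carries no strand column).

#' Construct a table of gene records
#'
#' @param gene_id Gene symbols (e.g. "Gmcupin16.1").
#' @param locus Genome locus accessions.
#' @param chromosome Chromosome labels, "Gm01".."Gm20".
#' @param start_raw,end_raw 1-based inclusive positions as printed; a
#'   reversed pair (`start_raw > end_raw`) indicates the minus strand.
#' @param aa_length Peptide length in residues.
#' @param n_exons Exon count.
#' @param transcript Optional primary-transcript accessions.
#' @param warn_span If `TRUE` (default), warn when a printed span is
#'   shorter than the minimum implied by `aa_length` (3 bp per residue);
#'   such rows are retained verbatim, not corrected.
#' @return A `gene_records` data.frame with strand-normalized `start`,
#'   `end` (start <= end) and a `strand` column.
#' @export
gene_records <- function(gene_id, locus, chromosome, start_raw, end_raw,
                         aa_length, n_exons, transcript = NA_character_,
                         warn_span = TRUE) {
  n <- length(gene_id)
  start_raw <- as.numeric(start_raw); end_raw <- as.numeric(end_raw)
  if (length(aa_length) == 1L) aa_length <- rep_len(aa_length, n)
  if (length(n_exons) == 1L) n_exons <- rep_len(n_exons, n)
  aa_length <- as.integer(aa_length); n_exons <- as.integer(n_exons)
  stopifnot(length(locus) == n, length(chromosome) == n,
            length(start_raw) == n, length(end_raw) == n,
            length(aa_length) == n, length(n_exons) == n)
  bad_chr <- setdiff(unique(chromosome), soybean_chromosomes())
  if (length(bad_chr))
    stop("unknown chromosome label(s): ", paste(bad_chr, collapse = ", "))
  if (any(aa_length < 1L)) stop("aa_length must be >= 1")
  strand <- ifelse(start_raw > end_raw, "-", "+")
  df <- data.frame(
    gene_id = as.character(gene_id),
    locus = as.character(locus),
    transcript = rep_len(as.character(transcript), n),
    chromosome = as.character(chromosome),
    start_raw = start_raw, end_raw = end_raw,
    start = pmin(start_raw, end_raw),
    end = pmax(start_raw, end_raw),
    strand = strand,
    aa_length = aa_length, n_exons = n_exons,
    stringsAsFactors = FALSE
  )
  short <- df$end - df$start + 1 < 3 * df$aa_length
  if (warn_span && any(short))
    warning("printed span shorter than 3 x aa_length (kept verbatim): ",
            paste(df$gene_id[short], collapse = ", "), call. = FALSE)
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Construct a table of duplicate pairs
#'
#' @param gene_a,gene_b Gene symbols of each pair.
#' @param mode `"tandem"` or `"segmental"`.
#' @param fragment_class `"large"`, `"small"`, or `NA` (tandem pairs carry
#'   no fragment class).
#' @param ka,ks Non-synonymous / synonymous substitutions per site.
#' @param ratio Ka/Ks; `NA` when Ks = 0 (undefined, never infinite).
#' @param date_mya Duplication date in million years.
#' @return A `duplicate_pairs` data.frame.
#' @export
duplicate_pairs <- function(gene_a, gene_b, mode, fragment_class,
                            ka, ks, ratio = ka / ks, date_mya) {
  stopifnot(all(mode %in% c("tandem", "segmental")),
            all(fragment_class %in% c("large", "small") |
                  is.na(fragment_class)),
            all(ka >= 0), all(ks >= 0), all(date_mya >= 0))
  if (any(mode == "tandem" & !is.na(fragment_class)))
    stop("tandem pairs must have fragment_class NA")
  ratio[ks == 0] <- NA_real_
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   mode = mode, fragment_class = fragment_class,
                   ka = ka, ks = ks, ratio = ratio, date_mya = date_mya,
                   stringsAsFactors = FALSE)
  class(df) <- c("duplicate_pairs", "data.frame")
  df
}

#' Construct a table of biallelic SNP sites with per-population counts
#'
#' Each site carries the same two alleles in both populations, with
#' observed-call counts (totals may vary per site due to missing data).
#'
#' @param gene_id Gene symbol per site.
#' @param position Genomic coordinate.
#' @param allele_a,allele_b The two allele labels.
#' @param wild_a,wild_b Counts of each allele in the wild panel.
#' @param cult_a,cult_b Counts of each allele in the cultivated panel.
#' @return A `snp_sites` data.frame.
#' @export
snp_sites <- function(gene_id, position, allele_a, allele_b,
                      wild_a, wild_b, cult_a, cult_b) {
  stopifnot(all(wild_a >= 0), all(wild_b >= 0),
            all(cult_a >= 0), all(cult_b >= 0),
            all(allele_a != allele_b))
  df <- data.frame(gene_id = as.character(gene_id),
                   position = as.numeric(position),
                   allele_a = as.character(allele_a),
                   allele_b = as.character(allele_b),
                   wild_a = as.integer(wild_a), wild_b = as.integer(wild_b),
                   cult_a = as.integer(cult_a), cult_b = as.integer(cult_b),
                   stringsAsFactors = FALSE)
  class(df) <- c("snp_sites", "data.frame")
  df
}

#' Load the packaged family table (69 gene records)
#'
#' Rows are preserved exactly as printed, including a handful whose span
#' is inconsistent with the peptide length; these are flagged with a
#' warning, never corrected.
#'
#' @param path Fixture path; defaults to the packaged copy.
#' @param warn_span Warn on spans shorter than 3 x aa_length.
#' @return A `gene_records` data.frame.
#' @export
load_table1_fixture <- function(path = path_fixture("table1.tsv"),
                                warn_span = TRUE) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "locus", "transcript", "chromosome",
            "start_raw", "end_raw", "aa_length", "n_exons")
  if (!all(need %in% names(raw)))
    parse_error(path, "header", paste("missing column(s):",
                paste(setdiff(need, names(raw)), collapse = ", ")))
  if (nrow(raw) == 0L) {
    out <- gene_records(character(), character(), character(), numeric(),
                        numeric(), integer(), integer())
    return(out)
  }
  for (col in c("start_raw", "end_raw", "aa_length", "n_exons")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      parse_error(path, which(is.na(v))[1], paste("non-numeric", col))
    raw[[col]] <- v
  }
  gene_records(raw$gene_id, raw$locus, raw$chromosome,
               raw$start_raw, raw$end_raw, raw$aa_length, raw$n_exons,
               transcript = raw$transcript, warn_span = warn_span)
}

#' Load the packaged duplicate-pair table (18 rows)
#'
#' The printed rows are preserved verbatim, including the repeated
#' Gmcupin3.1/Gmcupin19.13 listing. Duplication modes are mapped from the
#' printed labels ("Fragment" -> segmental, "Tandem Repeat" -> tandem).
#'
#' @param path Fixture path; defaults to the packaged copy.
#' @return A `duplicate_pairs` data.frame.
#' @export
load_table2_fixture <- function(path = path_fixture("table2.tsv")) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  mode_map <- c("Fragment" = "segmental", "Tandem Repeat" = "tandem")
  bad <- !(raw$duplication %in% names(mode_map))
  if (any(bad)) parse_error(path, which(bad)[1], "unknown duplication mode")
  frag <- tolower(trimws(as.character(raw$fragment_size)))
  frag[!(frag %in% c("large", "small"))] <- NA_character_
  duplicate_pairs(raw$gene_a, raw$gene_b,
                  mode = unname(mode_map[raw$duplication]),
                  fragment_class = frag,
                  ka = raw$ka, ks = raw$ks, ratio = raw$ratio,
                  date_mya = raw$date_mya)
}

#' Parse an allele-count token such as "11C/5T"
#'
#' @param x Character vector of tokens, each "<count><allele>/<count><allele>".
#' @return A data.frame with columns `allele_a`, `allele_b`, `count_a`,
#'   `count_b`.
#' @export
#' @examples
#' parse_allele_counts("8A/8G")
parse_allele_counts <- function(x) {
  m <- regmatches(x, regexec("^(\\d+)([ACGT])/(\\d+)([ACGT])$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("malformed allele-count token: ", x[which(bad)[1]], call. = FALSE)
  data.frame(
    allele_a = vapply(m, `[[`, "", 3L),
    allele_b = vapply(m, `[[`, "", 5L),
    count_a = as.integer(vapply(m, `[[`, "", 2L)),
    count_b = as.integer(vapply(m, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Load the packaged selected-site table (38 SNP sites)
#'
#' Counts are parsed from the "11C/5T" dialect into per-allele columns;
#' a site whose two populations list different allele pairs is a parse
#' error.
#'
#' @param path Fixture path; defaults to the packaged copy.
#' @return A `snp_sites` data.frame.
#' @export
load_table3_fixture <- function(path = path_fixture("table3.tsv")) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  w <- parse_allele_counts(raw$wild)
  cu <- parse_allele_counts(raw$cultivar)
  # align cultivar counts onto the wild allele order
  swap <- cu$allele_a == w$allele_b & cu$allele_b == w$allele_a
  same <- cu$allele_a == w$allele_a & cu$allele_b == w$allele_b
  if (any(!(swap | same)))
    parse_error(path, which(!(swap | same))[1],
                "allele sets differ between populations")
  ca <- ifelse(swap, cu$count_b, cu$count_a)
  cb <- ifelse(swap, cu$count_a, cu$count_b)
  snp_sites(raw$gene_id, raw$position, w$allele_a, w$allele_b,
            w$count_a, w$count_b, ca, cb)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"cds"`; sequences are validated against the
#'   amino-acid or `ACGTN` alphabet respectively (gap `-` allowed).
#' @return Named character vector of sequences (ids must be unique).
#' @export
read_fasta <- function(path, kind = c("protein", "cds")) {
  kind <- match.arg(kind)
  set <- if (kind == "cds") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  seqs <- toupper(as.character(set))
  alphabet <- if (kind == "cds") "ACGTN-" else
    paste0(paste(Biostrings::AA_STANDARD, collapse = ""), "XBZJUO*-")
  pat <- sprintf("[^%s]", alphabet)
  bad <- grepl(pat, seqs)
  if (any(bad))
    stop(sprintf("illegal %s character in sequence '%s'", kind,
                 ids[bad][1]), call. = FALSE)
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene coordinates from GFF3 or a 5-column TSV
#'
#' GFF3 `gene` features (other types are skipped with a message) or a TSV
#' with columns `gene_id`, `chromosome`, `start`, `end`, `strand` are
#' mapped onto `gene_records`. GFF3 coordinates are 1-based inclusive.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return A `gene_records` data.frame (aa_length/exons set to 1 when the
#'   source does not carry them).
#' @export
read_gene_coords <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path, format = "gff3")
      keep <- as.character(gr$type) == "gene"
      if (any(!keep))
        message("skipped ", sum(!keep), " non-gene feature(s)")
      gr <- gr[keep]
      ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
        as.character(seq_along(gr))
      chr <- as.character(GenomicRanges::seqnames(gr))
      st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
      strand <- as.character(GenomicRanges::strand(gr))
    } else {
      lines <- readLines(path)
      lines <- lines[!grepl("^#", lines) & nzchar(lines)]
      f <- strsplit(lines, "\t", fixed = TRUE)
      ok <- vapply(f, length, integer(1)) >= 9L
      if (any(!ok)) stop("malformed GFF3 line ", which(!ok)[1], call. = FALSE)
      type <- vapply(f, `[[`, "", 3L)
      keep <- type == "gene"
      if (any(!keep))
        message("skipped ", sum(!keep), " non-gene feature(s)")
      f <- f[keep]
      attr9 <- vapply(f, `[[`, "", 9L)
      ids <- sub(".*ID=([^;]+).*", "\\1", attr9)
      chr <- vapply(f, `[[`, "", 1L)
      st <- as.numeric(vapply(f, `[[`, "", 4L))
      en <- as.numeric(vapply(f, `[[`, "", 5L))
      strand <- vapply(f, `[[`, "", 7L)
    }
    if (length(ids) == 0L)
      return(gene_records(character(), character(), character(), numeric(),
                          numeric(), integer(), integer()))
    # encode strand through raw coordinate order (minus = reversed)
    sr <- ifelse(strand == "-", en, st)
    er <- ifelse(strand == "-", st, en)
    gene_records(ids, ids, chr, sr, er, aa_length = 1L, n_exons = 1L,
                 warn_span = FALSE)
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start", "end", "strand")
    if (!all(need %in% names(raw)))
      parse_error(path, "header", paste("missing column(s):",
                  paste(setdiff(need, names(raw)), collapse = ", ")))
    sr <- ifelse(raw$strand == "-", raw$end, raw$start)
    er <- ifelse(raw$strand == "-", raw$start, raw$end)
    gene_records(raw$gene_id, raw$gene_id, raw$chromosome, sr, er,
                 aa_length = 1L, n_exons = 1L, warn_span = FALSE)
  }
}

#' Read a duplicated-block annotation TSV
#'
#' Columns: `block_id`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#' `start_b`, `end_b`, and optionally `length_bp` (defaults to the larger
#' span length).
#'
#' @param path TSV file.
#' @return A `duplicated_blocks` data.frame.
#' @export
read_blocks <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("block_id", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b")
  if (!all(need %in% names(raw)))
    parse_error(path, "header", paste("missing column(s):",
                paste(setdiff(need, names(raw)), collapse = ", ")))
  if (is.null(raw$length_bp))
    raw$length_bp <- pmax(raw$end_a - raw$start_a, raw$end_b - raw$start_b) + 1
  if (any(raw$length_bp <= 0)) stop("block length_bp must be > 0")
  if (any(raw$end_a < raw$start_a | raw$end_b < raw$start_b))
    stop("malformed block span")
  class(raw) <- c("duplicated_blocks", "data.frame")
  raw
}

#' Write a duplicate-pair table as TSV (inverse of [load_table2_fixture()])
#'
#' @param pairs A `duplicate_pairs` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  mode_map <- c(segmental = "Fragment", tandem = "Tandem Repeat")
  frag <- ifelse(is.na(pairs$fragment_class), "",
                 paste0(toupper(substr(pairs$fragment_class, 1, 1)),
                        substring(pairs$fragment_class, 2)))
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    duplication = unname(mode_map[pairs$mode]),
                    fragment_size = frag,
                    ka = sprintf("%.4f", pairs$ka),
                    ks = sprintf("%.4f", pairs$ks),
                    ratio = sprintf("%.4f", pairs$ratio),
                    date_mya = sprintf("%.2f", pairs$date_mya),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
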