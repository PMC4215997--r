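# Internal helpers shared across modules.

# The 20 soybean chromosome labels Gm01..Gm20.
soybean_chromosomes <- function() sprintf("Gm%02d", 1:20)

#' Normalize a Gmcupin gene symbol
#'
#' The published tables are inconsistent about zero padding
#' ("Gmcupin5.1" vs "Gmcupin05.1"). Normalization pads the chromosome
#' part to two digits so symbols join across tables.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector with two-digit chromosome numbers.
#' @export
#' @examples
#' normalize_gene_id(c("Gmcupin5.1", "Gmcupin19.13"))
normalize_gene_id <- function(x) {
  m <- regmatches(x, regexec("^(Gmcupin\\s?)(\\d+)\\.(\\d+)$", x))
  vapply(seq_along(x), function(i) {
    p <- m[[i]]
    if (length(p) == 0L) return(x[[i]])
    sprintf("Gmcupin%02d.%s", as.integer(p[[3]]), p[[4]])
  }, character(1))
}

# stop() with a consistent prefix for parse errors naming the offending row
parse_error <- function(file, row, msg) {
  stop(sprintf("%s: row %s: %s", basename(file), row, msg), call. = FALSE)
}

path_fixture <- function(name) {
  p <- system.file("extdata", name, package = "cupinfam")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

# Derive a stream-specific 32-bit sub-seed from a user seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + stream * 7919L
}
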