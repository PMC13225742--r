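#' Reverse complement of a DNA string
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Complement of a character vector of single bases (N maps to N).
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Convert an IUPAC pattern to an anchored regular expression.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ""))
  paste0("^", paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = ""), "$")
}

# Does each concrete sequence match an IUPAC pattern of the same length?
iupac_match <- function(pattern, seqs) {
  ok <- nchar(seqs) == nchar(pattern)
  ok[ok] <- grepl(iupac_regex(pattern), seqs[ok])
  ok
}

# Truncated-normal draw on (lo, hi) by resampling; mosaic allele fractions.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

# Coerce a genome argument (path, DNAStringSet, DNAString or named character
# vector) to a named character vector of contig sequences.
as_genome_seqs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(stats::setNames(list(genome), "chr1"))
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("chr", seq_along(genome))
    return(toupper(genome))
  }
  stop("cannot interpret 'genome' as sequences")
}
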