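#' Read / write pileup TSVs
#'
#' Pileup TSVs have header columns
#' `chrom, pos (1-based), ref, depth, nA, nC, nG, nT`.
#'
#' @param path File path.
#' @export
read_pileup_tsv <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_pileup(p, path)
}

#' @rdname read_pileup_tsv
#' @param pileup A pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read SNV calls from TSV or minimal VCF
#'
#' TSV input needs columns `chrom, pos, ref, alt` (extra columns kept). A
#' `.vcf` path is parsed with the VariantAnnotation package; only SNVs
#' (single-base ref and alt) are returned.
#'
#' @param path Path to a `.tsv` or `.vcf` file.
#' @return An `snv_call_set` data.frame.
#' @export
read_snv_calls <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    alt <- as.character(unlist(rr$ALT))
    ref <- as.character(rr$REF)
    keep <- nchar(ref) == 1L & nchar(alt) == 1L
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr))[keep],
      pos = BiocGenerics::start(rr)[keep],
      ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(out)))
      stop("SNV TSV must have columns: ", paste(need, collapse = ", "))
  }
  class(out) <- c("snv_call_set", "data.frame")
  out
}

#' Write SNV calls as a VCF-like TSV
#' @param snvs An `snv_call_set`.
#' @param path Output path.
#' @export
write_snv_tsv <- function(snvs, path) {
  utils::write.table(as.data.frame(snvs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-site editing profile TSV
#'
#' One row per protospacer position: `position, ref_base, coverage, nA, nC,
#' nG, nT, a2g, c_edit`.
#'
#' @param profile An [quantify_site()] result.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = seq_along(profile$ref),
                   ref_base = profile$ref,
                   coverage = profile$coverage,
                   profile$counts,
                   a2g = profile$a2g, c_edit = profile$c_edit)
  names(df)[4:7] <- c("nA", "nC", "nG", "nT")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a window report TSV for one or more profiles
#' @param windows Named list of [editing_window()] results.
#' @param path Output path.
#' @export
write_window_tsv <- function(windows, path) {
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    cw <- contiguous_window(w)
    data.frame(name = nm, peak_position = w$peak_position,
               peak_value = w$peak_value,
               threshold_frac = w$threshold_frac,
               window_positions = paste(w$window_positions, collapse = ","),
               contiguous_run = if (length(cw))
                 sprintf("A%d-A%d", min(cw), max(cw)) else "",
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a FASTA file
#' @param seqs A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
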