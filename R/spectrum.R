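SUB_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' 12-class substitution spectrum of an SNV set
#'
#' Counts each call into its directed substitution class and reports the
#' combined A-to-G plus T-to-C fraction (the adenine-deamination signature on
#' either strand) and the C-to-T plus G-to-A fraction (the cytosine
#' counterpart). Calls with ambiguous ref/alt bases are excluded and counted.
#'
#' @param snvs An `snv_call_set` or data.frame with `ref` and `alt` single
#'   bases.
#' @return A `spectrum_summary` with `counts_12`, `frac_AG_TC`,
#'   `frac_CT_GA`, `n_total`, `n_excluded`.
#' @export
mutation_spectrum <- function(snvs) {
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  valid <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  cls <- paste0(ref[valid], ">", alt[valid])
  counts <- table(factor(cls, levels = SUB_CLASSES))
  n <- sum(counts)
  structure(list(
    counts_12 = stats::setNames(as.integer(counts), SUB_CLASSES),
    frac_AG_TC = if (n) unname((counts["A>G"] + counts["T>C"]) / n)
                 else NA_real_,
    frac_CT_GA = if (n) unname((counts["C>T"] + counts["G>A"]) / n)
                 else NA_real_,
    n_total = n, n_excluded = sum(!valid)),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("mutation spectrum over %d SNVs (%d excluded)\n",
              x$n_total, x$n_excluded))
  cat(sprintf("  A>G + T>C: %.1f%%   C>T + G>A: %.1f%%\n",
              100 * x$frac_AG_TC, 100 * x$frac_CT_GA))
  print(x$counts_12)
  invisible(x)
}

# Orient A>G / T>C calls onto the deaminated-A strand and extract the
# flanking sequence; other classes are dropped. Returns a character matrix
# (events x positions -flank..+flank) or NULL if no event survives.
oriented_contexts <- function(snvs, seqs, flank) {
  keep <- (snvs$ref == "A" & snvs$alt == "G") |
    (snvs$ref == "T" & snvs$alt == "C")
  s <- snvs[keep, , drop = FALSE]
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(s))) {
    chrom <- s$chrom[i]; pos <- s$pos[i]
    if (!chrom %in% names(seqs)) { n_skipped <- n_skipped + 1L; next }
    len <- nchar(seqs[[chrom]])
    if (pos - flank < 1L || pos + flank > len) {
      n_skipped <- n_skipped + 1L; next
    }
    ctx <- substring(seqs[[chrom]], pos - flank, pos + flank)
    if (s$ref[i] == "T") ctx <- revcomp(ctx)
    rows[[length(rows) + 1L]] <- strsplit(ctx, "")[[1]]
  }
  list(mat = if (length(rows)) do.call(rbind, rows) else NULL,
       n_skipped = n_skipped)
}

#' Strand-standardized flanking-context matrix and information content
#'
#' A-to-G calls are read on the forward strand and T-to-C calls are
#' reverse-complemented, so that position 0 is always the deaminated A; other
#' substitution classes are excluded. Per flanking position the base counts
#' and the information content `ic = 2 - H` (Shannon entropy in bits of the
#' base frequencies, with a pseudocount per base) are reported. Events whose
#' flank runs past a contig end are skipped and counted.
#'
#' @param snvs SNV set with `chrom, pos, ref, alt`.
#' @param reference Genome/transcriptome FASTA path, `DNAStringSet` or named
#'   character vector.
#' @param flank Number of flanking positions on each side (default 3).
#' @param mode `"dna"` or `"rna"` (RNA output reports U for T).
#' @param pseudocount Added to every base count before computing frequencies
#'   (default 0.5).
#' @return A `context_matrix` with `flank`, `n`, `n_skipped`, `base_counts`
#'   (positions x 4) and `ic` (bits per position).
#' @export
context_logo <- function(snvs, reference, flank = 3L,
                         mode = c("dna", "rna"), pseudocount = 0.5) {
  mode <- match.arg(mode)
  seqs <- as_genome_seqs(reference)
  oc <- oriented_contexts(snvs, seqs, flank)
  mat <- oc$mat
  positions <- seq(-flank, flank)
  bases <- c("A", "C", "G", "T")
  bc <- matrix(0L, length(positions), 4,
               dimnames = list(positions, bases))
  if (!is.null(mat))
    for (b in bases) bc[, b] <- colSums(mat == b)
  n <- if (is.null(mat)) 0L else nrow(mat)
  freq <- (bc + pseudocount) / (n + 4 * pseudocount)
  h <- -rowSums(ifelse(freq > 0, freq * log2(freq), 0))
  ic <- 2 - h
  if (mode == "rna") colnames(bc) <- c("A", "C", "G", "U")
  structure(list(flank = as.integer(flank), mode = mode, n = n,
                 n_skipped = oc$n_skipped,
                 pseudocount = pseudocount, base_counts = bc, ic = ic),
            class = "context_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.context_matrix <- function(x, ...) {
  cat(sprintf("context_matrix (%s): %d oriented events, flank +/-%d (%d skipped)\n",
              x$mode, x$n, x$flank, x$n_skipped))
  cat("  ic (bits):", paste(sprintf("%+d:%.2f", as.integer(rownames(x$base_counts)),
                                    x$ic), collapse = " "), "\n")
  invisible(x)
}

#' TA (or UA) context fraction of oriented deamination events
#'
#' Fraction of oriented A-to-G / T-to-C events whose standardized -1 base
#' (the 5' neighbour of the deaminated A, on the deaminated strand) is T.
#'
#' @inheritParams context_logo
#' @return A single fraction (`NA` if no event is orientable).
#' @export
ta_context_fraction <- function(snvs, reference) {
  seqs <- as_genome_seqs(reference)
  oc <- oriented_contexts(snvs, seqs, 1L)
  if (is.null(oc$mat)) return(NA_real_)
  mean(oc$mat[, 1] == "T")
}
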