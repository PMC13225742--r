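#' Align amplicon reads to a site's reference amplicon
#'
#' Performs a fitting alignment (pattern-global, subject-local: end gaps on
#' the amplicon are free) of each read against the amplicon with affine gap
#' penalties, and projects the observed base at every protospacer position
#' onto the protospacer strand. A gap of length L costs
#' `gap_open + L * gap_ext`. Ties are broken deterministically by the
#' alignment engine (leftmost gap placement).
#'
#' Reads containing characters outside ACGTN, or shorter than `min_len`, are
#' rejected and counted rather than raising an error.
#'
#' @param reads Character vector or `DNAStringSet` of read sequences
#'   (pre-merged, amplicon orientation).
#' @param site A [protospacer_site()].
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters
#'   (defaults +2 / -3 / 8 / 1).
#' @param min_len Minimum accepted read length (default 30).
#' @param indel_flank Indels are flagged when any gap overlaps the
#'   protospacer extended by this many bases on each side (default 10).
#'
#' @return An object of class `aligned_reads` with elements `read_id`,
#'   `score`, `has_indel`, `base_mat` (reads x protospacer positions, bases on
#'   the protospacer strand, `NA` where uncovered or deleted), `n_reads`,
#'   `n_rejected`.
#' @export
align_reads <- function(reads, site, match = 2, mismatch = -3,
                        gap_open = 8, gap_ext = 1, min_len = 30L,
                        indel_flank = 10L) {
  reads <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  reads <- toupper(reads)

  ok <- !grepl("[^ACGTN]", reads) & nchar(reads) >= min_len &
    nchar(site$amplicon_seq) >= nchar(reads) / 2
  n_rejected <- sum(!ok)
  reads <- reads[ok]
  ids <- ids[ok]
  if (!length(reads)) stop("no read passed the input filters")

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(site$amplicon_seq),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)

  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  sub_start <- BiocGenerics::start(Biostrings::subject(aln))

  amp_len <- nchar(site$amplicon_seq)
  span <- range(proto_coords(site))
  win_lo <- max(1L, span[1] - indel_flank)
  win_hi <- min(amp_len, span[2] + indel_flank)
  coords <- proto_coords(site)

  n <- length(reads)
  base_mat <- matrix(NA_character_, n, site$proto_len,
                     dimnames = list(ids, paste0("P", seq_len(site$proto_len))))
  has_indel <- logical(n)
  for (k in seq_len(n)) {
    pc <- strsplit(pat[k], "")[[1]]
    sc <- strsplit(sub[k], "")[[1]]
    is_base <- sc != "-"
    pos <- integer(length(sc))
    pos[is_base] <- sub_start[k] + cumsum(is_base)[is_base] - 1L
    # deletions: read gap at an amplicon base; insertions: amplicon gap,
    # anchored at the preceding amplicon position (or alignment start)
    del_pos <- pos[is_base & pc == "-"]
    ins_anchor <- integer(0)
    if (any(!is_base)) {
      prev <- cummax(ifelse(is_base, pos, 0L))
      ins_anchor <- pmax(prev[!is_base], sub_start[k])
    }
    gap_pos <- c(del_pos, ins_anchor)
    has_indel[k] <- any(gap_pos >= win_lo & gap_pos <= win_hi)
    obs <- rep(NA_character_, amp_len)
    keep <- is_base & pc != "-"
    obs[pos[keep]] <- pc[keep]
    b <- obs[coords]
    if (site$strand == "-") b <- comp_base(b)
    base_mat[k, ] <- b
  }

  structure(list(read_id = ids, score = BiocGenerics::score(aln),
                 has_indel = has_indel, base_mat = base_mat,
                 n_reads = n, n_rejected = n_rejected,
                 site_id = site$site_id),
            class = "aligned_reads")
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @export
align_read <- function(read, site, ...) align_reads(read, site, ...)

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("aligned_reads: %d reads on site '%s' (%d rejected, %d with indel)\n",
              x$n_reads, x$site_id, x$n_rejected, sum(x$has_indel)))
  invisible(x)
}
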