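#' Protospacer site definition
#'
#' Describes one amplicon together with the geometry of its protospacer and
#' PAM. Protospacer positions are numbered 1..proto_len from the PAM-distal
#' (5') end, with the PAM immediately 3'-adjacent, so position A5 is the fifth
#' base of the protospacer counting away from the PAM end. All per-position
#' bases downstream are reported on the protospacer strand: for a minus-strand
#' site the observed amplicon bases are complemented and the coordinates
#' mirrored.
#'
#' @param site_id Character scalar identifying the site.
#' @param amplicon_seq Amplicon sequence (ACGT, forward strand).
#' @param proto_start 0-based offset of the protospacer span on the amplicon
#'   forward strand.
#' @param proto_len Protospacer length (default 20).
#' @param strand `"+"` or `"-"`: orientation of the protospacer relative to
#'   the amplicon forward strand.
#' @param pam_seq IUPAC PAM pattern immediately 3' of the protospacer on the
#'   protospacer strand (default `"NGG"`).
#' @param intended_positions Integer vector of 1-based protospacer positions
#'   carrying the intended A-to-G edit; each must be an A on the protospacer
#'   strand.
#'
#' @return An object of class `protospacer_site`.
#' @export
protospacer_site <- function(site_id, amplicon_seq, proto_start,
                             proto_len = 20L, strand = c("+", "-"),
                             pam_seq = "NGG", intended_positions = integer()) {
  strand <- match.arg(strand)
  amplicon_seq <- toupper(as.character(amplicon_seq))
  stopifnot(is.character(site_id), length(site_id) == 1L,
            nchar(amplicon_seq) >= 1L)
  if (grepl("[^ACGT]", amplicon_seq))
    stop("amplicon_seq must contain only A, C, G, T")
  proto_start <- as.integer(proto_start)
  proto_len <- as.integer(proto_len)
  intended_positions <- as.integer(intended_positions)
  amp_len <- nchar(amplicon_seq)
  if (proto_start < 0L || proto_start + proto_len > amp_len)
    stop("protospacer does not fit on the amplicon")

  site <- structure(
    list(site_id = site_id, amplicon_seq = amplicon_seq,
         proto_start = proto_start, proto_len = proto_len,
         strand = strand, pam_seq = toupper(pam_seq),
         intended_positions = intended_positions),
    class = "protospacer_site")

  proto <- protospacer_seq(site)
  pam <- pam_observed(site)
  if (is.na(pam))
    stop("PAM extends past the amplicon end")
  if (!iupac_match(site$pam_seq, pam))
    stop(sprintf("observed PAM '%s' does not match pattern '%s'",
                 pam, site$pam_seq))
  if (length(intended_positions)) {
    if (any(intended_positions < 1L | intended_positions > proto_len))
      stop("intended_positions must lie in [1, proto_len]")
    bases <- substring(proto, intended_positions, intended_positions)
    if (any(bases != "A"))
      stop("every intended position must be an A on the protospacer strand")
  }
  site
}

#' @export
print.protospacer_site <- function(x, ...) {
  cat(sprintf("protospacer_site '%s': %d-bp amplicon, protospacer %d..%d (%s), PAM %s\n",
              x$site_id, nchar(x$amplicon_seq), x$proto_start + 1L,
              x$proto_start + x$proto_len, x$strand, x$pam_seq))
  cat(sprintf("  protospacer: %s\n", protospacer_seq(x)))
  if (length(x$intended_positions))
    cat(sprintf("  intended A positions: %s\n",
                paste0("A", x$intended_positions, collapse = ", ")))
  invisible(x)
}

#' Amplicon forward-strand coordinates of protospacer positions
#'
#' Maps protospacer positions 1..proto_len (PAM-distal numbering) to 1-based
#' coordinates on the amplicon forward strand.
#'
#' @param site A [protospacer_site()].
#' @return Integer vector of length `proto_len`.
#' @export
proto_coords <- function(site) {
  i <- seq_len(site$proto_len)
  if (site$strand == "+") site$proto_start + i
  else site$proto_start + site$proto_len + 1L - i
}

#' Protospacer sequence on the protospacer strand
#' @param site A [protospacer_site()].
#' @return Character scalar of length `proto_len`.
#' @export
protospacer_seq <- function(site) {
  span <- substr(site$amplicon_seq, site$proto_start + 1L,
                 site$proto_start + site$proto_len)
  if (site$strand == "+") span else revcomp(span)
}

# Observed PAM bases 3' of the protospacer on the protospacer strand,
# or NA if it runs off the amplicon.
pam_observed <- function(site) {
  np <- nchar(site$pam_seq)
  if (site$strand == "+") {
    from <- site$proto_start + site$proto_len + 1L
    if (from + np - 1L > nchar(site$amplicon_seq)) return(NA_character_)
    substr(site$amplicon_seq, from, from + np - 1L)
  } else {
    to <- site$proto_start
    if (to - np + 1L < 1L) return(NA_character_)
    revcomp(substr(site$amplicon_seq, to - np + 1L, to))
  }
}

#' Read a sites table and its amplicons
#'
#' The sites table is a TSV with header columns `site_id`, `amplicon_id`,
#' `proto_start` (0-based), `strand`, `pam` and `intended_positions`
#' (comma-separated 1-based protospacer positions, empty allowed).
#'
#' @param path Path to the sites TSV.
#' @param amplicon_fasta Path to a FASTA file of amplicon sequences whose
#'   names match `amplicon_id`.
#' @return A named list of [protospacer_site()] objects.
#' @export
read_sites_tsv <- function(path, amplicon_fasta) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "amplicon_id", "proto_start", "strand", "pam",
            "intended_positions")
  if (!all(need %in% names(tab)))
    stop("sites TSV must have columns: ", paste(need, collapse = ", "))
  amps <- Biostrings::readDNAStringSet(amplicon_fasta)
  names(amps) <- sub("\\s.*$", "", names(amps))
  sites <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (!row$amplicon_id %in% names(amps))
      stop("amplicon '", row$amplicon_id, "' not found in FASTA")
    ip_str <- as.character(row$intended_positions)
    ip <- if (is.na(ip_str) || ip_str == "") integer() else
      as.integer(strsplit(ip_str, ",")[[1]])
    protospacer_site(row$site_id, as.character(amps[[row$amplicon_id]]),
                     row$proto_start, strand = row$strand,
                     pam_seq = row$pam, intended_positions = ip)
  })
  stats::setNames(sites, tab$site_id)
}
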