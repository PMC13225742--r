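#' Caller threshold profile for paired de novo SNV calling
#'
#' The paired caller is parameterized by a threshold profile; three stock
#' profiles (strict / default / sensitive) emulate running three independent
#' somatic callers on the same edited-vs-control pair, with their
#' intersection taken as the consensus.
#'
#' @param name Profile name.
#' @param min_depth Minimum depth required in both samples (default 10).
#' @param min_alt_depth Minimum alt-supporting reads in the edited sample
#'   (default 3).
#' @param min_af Minimum allele fraction in the edited sample (default 0.10).
#' @param max_control_alt Maximum alt-supporting reads tolerated in the
#'   control sample (default 0).
#' @return A `caller_profile` object.
#' @export
caller_profile <- function(name, min_depth = 10L, min_alt_depth = 3L,
                           min_af = 0.10, max_control_alt = 0L) {
  stopifnot(min_depth >= 0, min_alt_depth >= 0, min_af >= 0,
            max_control_alt >= 0)
  structure(list(name = name, min_depth = as.integer(min_depth),
                 min_alt_depth = as.integer(min_alt_depth),
                 min_af = min_af,
                 max_control_alt = as.integer(max_control_alt)),
            class = "caller_profile")
}

#' @rdname caller_profile
#' @export
default_caller_profiles <- function() {
  list(strict = caller_profile("strict", min_alt_depth = 5L, min_af = 0.15),
       default = caller_profile("default"),
       sensitive = caller_profile("sensitive", min_alt_depth = 2L,
                                  min_af = 0.05, max_control_alt = 1L))
}

check_pileup <- function(p, label) {
  need <- c("chrom", "pos", "ref", "depth", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(p)))
    stop(label, " pileup must have columns: ", paste(need, collapse = ", "))
  bad <- with(p, nA + nC + nG + nT > depth)
  if (any(bad)) stop(label, " pileup: base counts exceed depth at ",
                     sum(bad), " position(s)")
  p
}

#' Call de novo SNVs from paired edited/control pileups
#'
#' A site is called when both samples reach `min_depth`, the edited sample
#' shows at least `min_alt_depth` alt reads at allele fraction `min_af` or
#' more, and the control sample shows at most `max_control_alt` alt reads
#' (germline exclusion). Positions present in only one pileup cannot satisfy
#' the paired depth requirement and are dropped; a reference-base
#' disagreement between the samples at a shared position is a hard error.
#'
#' @param edited,control Pileup data.frames with columns
#'   `chrom, pos (1-based), ref, depth, nA, nC, nG, nT`.
#' @param profile A [caller_profile()].
#' @return An `snv_call_set` data.frame with one row per (chrom, pos, alt):
#'   `chrom, pos, ref, alt, alt_depth, depth, af, control_alt_depth`.
#' @export
call_denovo_snvs <- function(edited, control, profile) {
  stopifnot(inherits(profile, "caller_profile"))
  edited <- check_pileup(edited, "edited")
  control <- check_pileup(control, "control")
  m <- merge(edited, control, by = c("chrom", "pos"),
             suffixes = c(".e", ".c"))
  if (nrow(m) && any(m$ref.e != m$ref.c))
    stop("reference base mismatch between samples at ",
         sum(m$ref.e != m$ref.c), " position(s)")
  out <- list()
  for (alt in c("A", "C", "G", "T")) {
    col <- paste0("n", alt)
    sel <- m$ref.e != alt &
      m$depth.e >= profile$min_depth & m$depth.c >= profile$min_depth &
      m[[paste0(col, ".e")]] >= profile$min_alt_depth &
      m[[paste0(col, ".e")]] / m$depth.e >= profile$min_af &
      m[[paste0(col, ".c")]] <= profile$max_control_alt
    if (any(sel)) {
      s <- m[sel, ]
      out[[alt]] <- data.frame(
        chrom = s$chrom, pos = s$pos, ref = s$ref.e, alt = alt,
        alt_depth = s[[paste0(col, ".e")]], depth = s$depth.e,
        af = s[[paste0(col, ".e")]] / s$depth.e,
        control_alt_depth = s[[paste0(col, ".c")]],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), alt_depth = integer(), depth = integer(),
               af = numeric(), control_alt_depth = integer(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$pos, res$alt), ]
  rownames(res) <- NULL
  class(res) <- c("snv_call_set", "data.frame")
  res
}

snv_key <- function(s) paste(s$chrom, s$pos, s$alt, sep = ":")

#' Consensus of three call sets
#'
#' Keeps calls present (same chrom, pos, alt) in all three sets
#' (intersection, the default) or in any of them (union). Allele fractions
#' and depths are taken from the first set where available.
#'
#' @param callsets A list of exactly 3 `snv_call_set` data.frames.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return An `snv_call_set`.
#' @export
consensus_intersection <- function(callsets, mode = c("intersection",
                                                      "union")) {
  mode <- match.arg(mode)
  if (length(callsets) != 3L)
    stop("consensus requires exactly 3 call sets, got ", length(callsets))
  keys <- lapply(callsets, snv_key)
  keep <- if (mode == "intersection")
    Reduce(intersect, keys) else Reduce(union, keys)
  pool <- do.call(rbind, lapply(callsets, as.data.frame))
  pool <- pool[!duplicated(snv_key(pool)), , drop = FALSE]
  res <- pool[snv_key(pool) %in% keep, , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$alt), ]
  rownames(res) <- NULL
  class(res) <- c("snv_call_set", "data.frame")
  res
}

#' Replicate overlap (Venn counts) of SNV sets
#'
#' Tabulates how many variants, keyed by (chrom, pos, alt), fall in every
#' membership pattern of up to 4 sets, plus a pairwise shared-count matrix.
#'
#' @param snv_sets Named list of 2-4 `snv_call_set` data.frames.
#' @return List with `venn` (data.frame of membership pattern and count),
#'   `pairwise` (matrix of shared counts), `all_shared` (count present in
#'   every set).
#' @export
replicate_overlap <- function(snv_sets) {
  k <- length(snv_sets)
  if (k < 2L || k > 4L) stop("replicate_overlap takes 2-4 sets")
  if (is.null(names(snv_sets))) names(snv_sets) <- paste0("set", seq_len(k))
  keys <- lapply(snv_sets, function(s) unique(snv_key(s)))
  all_keys <- unique(unlist(keys))
  memb <- vapply(keys, function(kk) all_keys %in% kk, logical(length(all_keys)))
  if (length(all_keys) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(keys)))
  pat <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE], 1,
                paste, collapse = "")
  pats <- setdiff(pats, paste(rep("0", k), collapse = ""))
  venn <- data.frame(pattern = pats,
                     count = as.integer(table(factor(pat, levels = pats))),
                     stringsAsFactors = FALSE)
  pairwise <- matrix(0L, k, k, dimnames = list(names(snv_sets),
                                               names(snv_sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  list(venn = venn, pairwise = pairwise,
       all_shared = if (length(all_keys)) sum(rowSums(memb) == k) else 0L)
}

#' Enumerate guide-similar (predicted off-target) sites in a genome
#'
#' Exhaustively finds, on both strands, every 20-mer within `max_mm`
#' mismatches of the spacer that is followed 3' by a PAM matching the IUPAC
#' pattern. Coordinates are 0-based half-open (BED convention) on the forward
#' strand and span the protospacer only.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param spacer 20-nt spacer sequence (protospacer strand).
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @param max_mm Maximum spacer mismatches.
#' @return Data.frame `chrom, start, end, strand, mismatches, matched_seq`,
#'   sorted by (mismatches, chrom, start).
#' @export
enumerate_predicted_sites <- function(genome, spacer, pam_pattern = "NGG",
                                      max_mm = 3L) {
  spacer <- toupper(as.character(spacer))
  if (nchar(spacer) != 20L) stop("spacer must be a 20-mer")
  seqs <- as_genome_seqs(genome)
  np <- nchar(pam_pattern)
  pam_re <- iupac_regex(pam_pattern)
  out <- list()
  for (chrom in names(seqs)) {
    seq <- seqs[[chrom]]
    dna <- Biostrings::DNAString(seq)
    len <- nchar(seq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else revcomp(spacer)
      hits <- Biostrings::matchPattern(pat, dna, max.mismatch = max_mm,
                                       with.indels = FALSE)
      st <- BiocGenerics::start(hits)
      if (!length(st)) next
      proto <- as.character(Biostrings::extractAt(
        dna, IRanges::IRanges(st, width = 20L)))
      if (strand == "+") {
        pam_ok <- st + 20L + np - 1L <= len
        pam_seq <- rep(NA_character_, length(st))
        pam_seq[pam_ok] <- substring(seq, st[pam_ok] + 20L,
                                     st[pam_ok] + 19L + np)
        proto_strand <- proto
      } else {
        pam_ok <- st - np >= 1L
        pam_seq <- rep(NA_character_, length(st))
        pam_seq[pam_ok] <- revcomp(substring(seq, st[pam_ok] - np,
                                             st[pam_ok] - 1L))
        proto_strand <- revcomp(proto)
      }
      keep <- pam_ok & grepl(pam_re, pam_seq)
      if (!any(keep)) next
      st <- st[keep]; proto_strand <- proto_strand[keep]
      mm <- vapply(proto_strand, function(s)
        sum(strsplit(s, "")[[1]] != strsplit(spacer, "")[[1]]),
        integer(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = st - 1L, end = st + 19L, strand = strand,
        mismatches = mm, matched_seq = proto_strand,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               matched_seq = character(), stringsAsFactors = FALSE)
  res <- res[order(res$mismatches, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Overlap of SNV calls with predicted sites
#'
#' An SNV overlaps a predicted site when its position falls within the site
#' extended by `flank_bp` on each side (site coordinates are 0-based
#' half-open).
#'
#' @param snvs An `snv_call_set` (or data.frame with `chrom`, `pos`).
#' @param sites Predicted-site data.frame from [enumerate_predicted_sites()]
#'   or a BED-like frame with `chrom`, `start`, `end`.
#' @param flank_bp Flank in bp (default 25).
#' @return List with `count`, `fraction` (of SNVs overlapping) and `pairs`
#'   (data.frame of matched snv/site row indices).
#' @export
overlap_with_predicted <- function(snvs, sites, flank_bp = 25L) {
  if (nrow(snvs) == 0L || nrow(sites) == 0L)
    return(list(count = 0L, fraction = if (nrow(snvs)) 0 else NA_real_,
                pairs = data.frame(snv = integer(), site = integer())))
  gr_snv <- GenomicRanges::GRanges(snvs$chrom,
                                   IRanges::IRanges(snvs$pos, width = 1L))
  gr_site <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(1L, sites$start + 1L - flank_bp),
                     sites$end + flank_bp))
  ov <- GenomicRanges::findOverlaps(gr_snv, gr_site)
  hit <- unique(S4Vectors::queryHits(ov))
  list(count = length(hit), fraction = length(hit) / nrow(snvs),
       pairs = data.frame(snv = S4Vectors::queryHits(ov),
                          site = S4Vectors::subjectHits(ov)))
}

#' Group summaries and Welch tests for per-embryo SNV counts
#'
#' Per-group mean and SEM, fold change of each group mean over the control
#' group mean, and a two-sided unpaired Welch t-test of each group against
#' the control (reported only when both groups have at least two values).
#'
#' @param counts_by_group Named list of numeric vectors (per-embryo counts).
#' @param control Name of the control group.
#' @return Data.frame with `group, n, mean, sem, fold_vs_control, p_value`.
#' @export
group_statistics <- function(counts_by_group, control) {
  stopifnot(control %in% names(counts_by_group))
  ctrl <- counts_by_group[[control]]
  ctrl_mean <- mean(ctrl)
  if (ctrl_mean == 0) warning("control mean is zero; folds are undefined")
  res <- lapply(names(counts_by_group), function(g) {
    x <- counts_by_group[[g]]
    p <- if (g != control && length(x) >= 2L && length(ctrl) >= 2L)
      stats::t.test(x, ctrl, var.equal = FALSE)$p.value else NA_real_
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = if (length(x) >= 2L) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               fold_vs_control = if (ctrl_mean > 0) mean(x) / ctrl_mean
                                 else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
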