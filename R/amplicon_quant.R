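#' Per-position editing profile of one amplicon site
#'
#' Tabulates observed bases at every protospacer position over
#' substitution-only reads (reads whose alignment shows no indel near the
#' protospacer) and derives the A-to-G editing frequency at reference-A
#' positions and the C-editing frequency (C to anything else) at reference-C
#' positions. Indel-containing reads are excluded from the substitution
#' denominators by default and reported through `indel_fraction`; set
#' `include_indel_reads = TRUE` to count their aligned bases as well.
#'
#' @param aligned An [align_reads()] result.
#' @param site The matching [protospacer_site()].
#' @param include_indel_reads Include indel reads in substitution counts
#'   (default `FALSE`).
#' @return An object of class `editing_profile` with per-position `counts`
#'   (positions x A,C,G,T), `coverage`, `ref`, `a2g`, `c_edit`, plus
#'   `n_reads`, `n_indel_reads` and `indel_fraction`. Positions with zero
#'   substitution-only coverage have `NA` frequencies and are listed in
#'   `attr(, "uncovered")`.
#' @export
quantify_site <- function(aligned, site, include_indel_reads = FALSE) {
  stopifnot(inherits(aligned, "aligned_reads"),
            inherits(site, "protospacer_site"))
  if (aligned$n_reads < 1L) stop("need at least one aligned read")
  keep <- if (include_indel_reads) rep(TRUE, aligned$n_reads) else
    !aligned$has_indel
  bm <- aligned$base_mat[keep, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  counts <- sapply(bases, function(b) colSums(bm == b, na.rm = TRUE))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, bases))
  rownames(counts) <- paste0("P", seq_len(site$proto_len))
  coverage <- rowSums(counts)   # N and uncovered excluded
  ref <- strsplit(protospacer_seq(site), "")[[1]]
  a2g <- ifelse(ref == "A" & coverage > 0, counts[, "G"] / coverage, NA_real_)
  c_edit <- ifelse(ref == "C" & coverage > 0,
                   (coverage - counts[, "C"]) / coverage, NA_real_)
  uncovered <- which(coverage == 0)
  prof <- structure(
    list(site_id = site$site_id, n_reads = aligned$n_reads,
         n_indel_reads = sum(aligned$has_indel),
         indel_fraction = sum(aligned$has_indel) / aligned$n_reads,
         ref = ref, counts = counts, coverage = coverage,
         a2g = a2g, c_edit = c_edit),
    class = "editing_profile")
  attr(prof, "uncovered") <- uncovered
  prof
}

#' @export
print.editing_profile <- function(x, ...) {
  cat(sprintf("editing_profile '%s': %d reads (%.1f%% indel)\n", x$site_id,
              x$n_reads, 100 * x$indel_fraction))
  a <- which(x$ref == "A")
  if (length(a))
    cat("  a2g:", paste(sprintf("A%d=%.3f", a, x$a2g[a]), collapse = " "), "\n")
  invisible(x)
}

#' Summarize undesired C editing for a profile
#'
#' Two conventions are offered: the maximum per-position C-editing frequency
#' within the protospacer (`"max_position"`, the default used in site-level
#' summaries) or, given the original alignments, the fraction of
#' substitution-only reads carrying at least one C edit (`"per_read"`).
#'
#' @param profile An [quantify_site()] result.
#' @param mode `"max_position"` or `"per_read"`.
#' @param aligned Required for `mode = "per_read"`.
#' @return A single fraction (0 when the protospacer has no C).
#' @export
c_edit_summary <- function(profile, mode = c("max_position", "per_read"),
                           aligned = NULL) {
  mode <- match.arg(mode)
  cpos <- which(profile$ref == "C")
  if (!length(cpos)) return(0)
  if (mode == "max_position") {
    v <- profile$c_edit[cpos]
    if (all(is.na(v))) return(NA_real_)
    return(max(v, na.rm = TRUE))
  }
  if (is.null(aligned)) stop("per_read mode needs the aligned reads")
  bm <- aligned$base_mat[!aligned$has_indel, , drop = FALSE]
  sub <- bm[, cpos, drop = FALSE]
  edited <- rowSums(sub != "C" & sub != "N", na.rm = TRUE) > 0
  mean(edited)
}

#' Mean editing profile across sites
#'
#' Unweighted mean of per-site A-to-G frequencies at each protospacer
#' position, over the sites that have a reference A (with coverage) there.
#'
#' @param profiles A list of [quantify_site()] results.
#' @return A data.frame with `position`, `mean_a2g` (`NA` where no site
#'   contributes) and `n_sites`.
#' @export
aggregate_mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  plen <- max(vapply(profiles, function(p) length(p$a2g), integer(1)))
  mean_a2g <- rep(NA_real_, plen)
  n_sites <- integer(plen)
  for (i in seq_len(plen)) {
    vals <- unlist(lapply(profiles, function(p)
      if (i <= length(p$a2g) && !is.na(p$a2g[i])) p$a2g[i] else NULL))
    n_sites[i] <- length(vals)
    if (length(vals)) mean_a2g[i] <- mean(vals)
  }
  data.frame(position = seq_len(plen), mean_a2g = mean_a2g,
             n_sites = n_sites)
}

#' Editing window of a mean profile
#'
#' The editing window is the set of protospacer positions whose mean A-to-G
#' efficiency is at least `threshold_frac` of the peak efficiency (default
#' 30%). The window is reported as the full threshold-passing set; use
#' [contiguous_window()] for the largest contiguous run containing the peak,
#' which matches how windows are conventionally printed (e.g. "A2-A10").
#'
#' @param mean_profile Numeric vector of per-position mean efficiencies
#'   (`NA` allowed at non-A positions), or the data.frame returned by
#'   [aggregate_mean_profile()].
#' @param threshold_frac Fraction of the peak defining the window
#'   (default 0.30).
#' @return An object of class `window_result` with `threshold_frac`,
#'   `peak_position`, `peak_value`, `window_positions`.
#' @export
editing_window <- function(mean_profile, threshold_frac = 0.30) {
  if (is.data.frame(mean_profile)) mean_profile <- mean_profile$mean_a2g
  x <- as.numeric(mean_profile)
  if (all(is.na(x))) stop("profile has no non-missing position")
  peak_value <- max(x, na.rm = TRUE)
  if (peak_value <= 0) {
    res <- list(threshold_frac = threshold_frac, peak_position = NA_integer_,
                peak_value = 0, window_positions = integer())
    return(structure(res, class = "window_result"))
  }
  peak_position <- which(x == peak_value)[1]   # ties: smallest index
  window_positions <- which(!is.na(x) & x >= threshold_frac * peak_value)
  structure(list(threshold_frac = threshold_frac,
                 peak_position = peak_position, peak_value = peak_value,
                 window_positions = window_positions),
            class = "window_result")
}

#' Largest contiguous window run containing the peak
#' @param wr A [editing_window()] result.
#' @return Integer vector of consecutive positions (empty if the window is).
#' @export
contiguous_window <- function(wr) {
  stopifnot(inherits(wr, "window_result"))
  w <- wr$window_positions
  if (!length(w)) return(integer())
  runs <- split(w, cumsum(c(1L, diff(w) != 1L)))
  for (r in runs) if (wr$peak_position %in% r) return(r)
  integer()
}

#' @export
print.window_result <- function(x, ...) {
  cw <- contiguous_window(x)
  cat(sprintf("editing window (>= %.0f%% of peak %.3f at A%s): {%s}\n",
              100 * x$threshold_frac, x$peak_value,
              ifelse(is.na(x$peak_position), "-", x$peak_position),
              paste0("A", x$window_positions, collapse = ",")))
  if (length(cw))
    cat(sprintf("  contiguous run through peak: A%d-A%d\n", min(cw), max(cw)))
  invisible(x)
}

#' Bystander and C-editing purity ratios for one profile
#'
#' Ratios of undesired editing at A2 and A8, and of C editing at C5, to the
#' desired peak A5 editing. A ratio is `NA` when the reference base at the
#' positions involved is not the required A (or C); all ratios are `NaN` with
#' a warning when A5 efficiency is zero.
#'
#' @param profile An [quantify_site()] result, or a list with numeric
#'   elements `a2g` and `c_edit` (e.g. library-level mean vectors).
#' @param aligned Optional [align_reads()] object; adds a per-read
#'   `c_edit_fraction`.
#' @return An object of class `site_editing_summary` with `a2_over_a5`,
#'   `a8_over_a5`, `c5_over_a5`, `bystander_sum`, `indel_fraction`,
#'   `c_edit_fraction`.
#' @export
purity_metrics <- function(profile, aligned = NULL) {
  a2g <- unname(profile$a2g)
  c_ed <- unname(profile$c_edit)
  a5 <- if (length(a2g) >= 5) a2g[5] else NA_real_
  ratio <- function(num) {
    if (is.na(num) || is.na(a5)) return(NA_real_)
    if (a5 == 0) return(NaN)
    num / a5
  }
  if (!is.na(a5) && a5 == 0)
    warning("A5 efficiency is zero; ratios are NaN")
  out <- list(
    a2_over_a5 = ratio(if (length(a2g) >= 2) a2g[2] else NA_real_),
    a8_over_a5 = ratio(if (length(a2g) >= 8) a2g[8] else NA_real_),
    c5_over_a5 = ratio(if (length(c_ed) >= 5) c_ed[5] else NA_real_))
  out$bystander_sum <- out$a2_over_a5 + out$a8_over_a5
  out$indel_fraction <- if (!is.null(profile$indel_fraction))
    profile$indel_fraction else NA_real_
  out$c_edit_fraction <- if (inherits(profile, "editing_profile"))
    c_edit_summary(profile) else NA_real_
  structure(out, class = "site_editing_summary")
}

#' Library-level purity ratios from many site profiles
#'
#' Averages A-to-G efficiency and C-editing frequency per position across
#' sites (each over the sites carrying the required reference base) before
#' forming the A2/A5, A8/A5 and C5/A5 ratios, mirroring how bystander purity
#' is summarized over an sgRNA library.
#'
#' @param profiles List of [quantify_site()] results.
#' @return A `site_editing_summary` over the library means.
#' @export
aggregate_purity <- function(profiles) {
  plen <- max(vapply(profiles, function(p) length(p$a2g), integer(1)))
  mean_at <- function(field, i) {
    vals <- unlist(lapply(profiles, function(p)
      if (i <= length(p[[field]]) && !is.na(p[[field]][i])) p[[field]][i]
      else NULL))
    if (length(vals)) mean(vals) else NA_real_
  }
  a2g <- vapply(seq_len(plen), function(i) mean_at("a2g", i), numeric(1))
  c_ed <- vapply(seq_len(plen), function(i) mean_at("c_edit", i), numeric(1))
  purity_metrics(list(a2g = a2g, c_edit = c_ed))
}

#' Perfect-edit and dual-edit read fractions
#'
#' A perfect read carries no indel, a G at every intended position and the
#' reference base at every other protospacer position. When the site defines
#' exactly two intended positions, the dual fraction is the fraction of reads
#' carrying G at both, regardless of other positions (indel reads cannot
#' display the protospacer faithfully and count as non-dual). Both fractions
#' are over all aligned reads.
#'
#' @param aligned An [align_reads()] result.
#' @param site The matching [protospacer_site()]; `intended_positions` must
#'   be nonempty.
#' @return List with `perfect_fraction` and `dual_fraction` (`NA` unless two
#'   intended positions are defined).
#' @export
perfect_and_dual_fractions <- function(aligned, site) {
  ip <- site$intended_positions
  if (!length(ip)) stop("site has no intended_positions")
  ref <- strsplit(protospacer_seq(site), "")[[1]]
  if (any(ref[ip] != "A")) stop("intended positions must be reference A")
  bm <- aligned$base_mat
  n <- aligned$n_reads
  other <- setdiff(seq_len(site$proto_len), ip)
  at_int <- bm[, ip, drop = FALSE]
  edited_all <- rowSums(at_int == "G", na.rm = TRUE) == length(ip) &
    rowSums(is.na(at_int)) == 0
  ref_ok <- rowSums(bm[, other, drop = FALSE] ==
                      matrix(ref[other], n, length(other), byrow = TRUE),
                    na.rm = TRUE) == length(other)
  perfect <- !aligned$has_indel & edited_all & ref_ok
  dual <- if (length(ip) == 2L) !aligned$has_indel & edited_all else NA
  list(perfect_fraction = sum(perfect) / n,
       dual_fraction = if (length(ip) == 2L) sum(dual) / n else NA_real_)
}
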