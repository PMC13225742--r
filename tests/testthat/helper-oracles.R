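# Independent oracles used across the suite. These are deliberately naive
# (full DP, exhaustive scans, quadratic loops) and share no code with the
# package implementations they check.

# Fitting alignment score by full dynamic programming: pattern global,
# subject end-gaps free, affine gaps costing open + L * ext.
dp_fit_score <- function(read, ref, match = 2, mismatch = -3,
                         open = 8, ext = 1) {
  r <- strsplit(read, "")[[1]]
  g <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(g)
  NEG <- -1e9
  # three-state affine DP, one row (over subject positions j = 0..m) at a
  # time; M ends in (mis)match, X in a read-consuming gap, Y in a
  # ref-consuming gap. Leading/trailing subject gaps are free.
  M_prev <- rep(0, m + 1)
  X_prev <- rep(NEG, m + 1)
  Y_prev <- rep(NEG, m + 1)
  for (i in 1:n) {
    sc <- ifelse(g == r[i], match, mismatch)
    best_prev <- pmax(M_prev, X_prev, Y_prev)
    M_cur <- c(NEG, sc + best_prev[1:m])
    X_cur <- pmax(pmax(M_prev, Y_prev) - open - ext, X_prev - ext)
    # Y(i, j) = max_{k<j} [max(M, X)(i, k) + k*ext] - open - j*ext
    base <- pmax(M_cur, X_cur) + (0:m) * ext
    Y_cur <- c(NEG, cummax(base)[1:m] - open - (1:m) * ext)
    M_prev <- M_cur; X_prev <- X_cur; Y_prev <- Y_cur
  }
  max(pmax(M_prev, X_prev))
}

# Exhaustive mismatch scan for guide-similar sites: every offset, both
# strands, 3'-adjacent PAM. Returns 0-based half-open protospacer spans.
hamming_scan_sites <- function(seq, spacer, pam, max_mm, chrom = "chr1") {
  g <- strsplit(seq, "")[[1]]
  len <- length(g)
  sp <- strsplit(spacer, "")[[1]]
  np <- nchar(pam)
  pam_sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), N = c("A", "C", "G", "T"))
  pam_ok <- function(bases_5to3) {
    all(mapply(function(b, p) b %in% pam_sets[[p]], bases_5to3,
               strsplit(pam, "")[[1]]))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (s in 1:(len - 19L)) {
    win <- g[s:(s + 19L)]
    # forward strand: protospacer read as-is, PAM 3' to the right
    mm <- sum(win != sp)
    if (mm <= max_mm && s + 19L + np <= len &&
        pam_ok(g[(s + 20L):(s + 19L + np)]))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1L, end = s + 19L, strand = "+",
        mismatches = mm, stringsAsFactors = FALSE)
    # reverse strand: protospacer = revcomp(window), PAM to the left
    rc <- rev(unname(comp[win]))
    mm <- sum(rc != sp)
    if (mm <= max_mm && s - np >= 1L &&
        pam_ok(rev(unname(comp[g[(s - np):(s - 1L)]]))))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1L, end = s + 19L, strand = "-",
        mismatches = mm, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer()))
  do.call(rbind, out)
}

# Quadratic interval-overlap oracle: SNV pos within [start - flank,
# end + flank) of any 0-based half-open site.
quadratic_overlap_count <- function(snvs, sites, flank) {
  hit <- logical(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    p0 <- snvs$pos[i] - 1L   # 0-based position of the SNV base
    for (j in seq_len(nrow(sites))) {
      if (snvs$chrom[i] == sites$chrom[j] &&
          p0 >= sites$start[j] - flank && p0 < sites$end[j] + flank) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# Welch two-sample t-test p-value from the closed-form statistic.
welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

truth_keys <- function(truth, origins = c("deaminase", "background")) {
  ev <- truth$events[truth$events$origin %in% origins, ]
  paste(ev$chrom, ev$pos, ev$alt)
}

call_keys <- function(calls) paste(calls$chrom, calls$pos, calls$alt)
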