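#' Simulation configuration for genome-wide deaminase off-targets
#'
#' Defaults emulate a GOTI-style experiment at desk scale: a 2.5-Mb genome at
#' mouse-like GC, ~350 deaminase off-target events per embryo against a
#' spontaneous background of 13 events, mosaic allele fractions centred at
#' 0.5 (single-blastomere lineage after sorting), 50x coverage and a 0.1%
#' per-base sequencing error rate.
#'
#' @param seed Integer seed used by all draws.
#' @param genome_len Genome length in bp (>= 1e4).
#' @param gc GC fraction in (0, 1).
#' @param n_deaminase Number of deaminase A-to-G/T-to-C events.
#' @param ta_weight Sampling weight (>= 1) for adenines whose 5' neighbour on
#'   the deaminated strand is T.
#' @param n_background Number of spontaneous background SNVs (uniform over
#'   positions and the six substitution types, both strands).
#' @param n_germline Number of germline heterozygous variants (present in
#'   both samples at allele fraction 0.5).
#' @param af_mean,af_sd Truncated-normal mosaic allele-fraction parameters.
#' @param depth Mean sequencing depth (Poisson).
#' @param err_rate Per-base sequencing error rate.
#' @return An `offtarget_sim_config` list.
#' @export
offtarget_sim_config <- function(seed = 1L, genome_len = 2.5e6, gc = 0.42,
                                 n_deaminase = 350L, ta_weight = 1,
                                 n_background = 13L, n_germline = 50L,
                                 af_mean = 0.5, af_sd = 0.1,
                                 depth = 50L, err_rate = 0.001) {
  stopifnot(genome_len >= 1e4, af_mean > 0, af_mean < 1, ta_weight >= 1,
            n_deaminase >= 0, n_background >= 0, n_germline >= 0)
  structure(list(seed = as.integer(seed), genome_len = genome_len, gc = gc,
                 n_deaminase = as.integer(n_deaminase),
                 ta_weight = ta_weight,
                 n_background = as.integer(n_background),
                 n_germline = as.integer(n_germline),
                 af_mean = af_mean, af_sd = af_sd,
                 depth = depth, err_rate = err_rate),
            class = "offtarget_sim_config")
}

#' Generate a random genome
#'
#' I.i.d. bases at the stated GC content; byte-deterministic for a fixed
#' seed.
#'
#' @param length Genome length in bp (>= 1e4).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param chrom Contig name.
#' @return A `DNAStringSet` with one contig.
#' @export
make_genome <- function(length, gc = 0.42, seed = 1L, chrom = "chr1") {
  if (length < 1e4) stop("genome length must be >= 1e4")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
               collapse = "")
  Biostrings::DNAStringSet(stats::setNames(seq, chrom))
}

#' Count adenine contexts of a genome
#'
#' Counts, over both strands, the adenines whose 5' neighbour on the
#' deaminated strand is T (`n_ta`) versus all other adenines (`n_other`),
#' excluding contig-terminal adenines with no 5' neighbour.
#'
#' @param genome FASTA path, `DNAStringSet` or named character vector.
#' @return List with `n_ta`, `n_other`, `n_total`.
#' @export
count_ta_contexts <- function(genome) {
  seqs <- as_genome_seqs(genome)
  n_ta <- 0L; n_total <- 0L
  for (seq in seqs) {
    ch <- strsplit(seq, "")[[1]]
    len <- length(ch)
    fwd <- which(ch == "A"); fwd <- fwd[fwd > 1L]
    rev <- which(ch == "T"); rev <- rev[rev < len]
    n_ta <- n_ta + sum(ch[fwd - 1L] == "T") + sum(ch[rev + 1L] == "A")
    n_total <- n_total + length(fwd) + length(rev)
  }
  list(n_ta = n_ta, n_other = n_total - n_ta, n_total = n_total)
}

#' TA-context sampling weight for a target TA fraction
#'
#' Solves `w * n_ta / (w * n_ta + n_other) = target` by exhaustive context
#' enumeration of the genome, giving the `ta_weight` at which the expected
#' TA-context fraction of deaminase events equals `target`.
#'
#' @param genome Genome (see [count_ta_contexts()]).
#' @param target Desired expected TA-context fraction.
#' @return The required weight.
#' @export
ta_weight_for_fraction <- function(genome, target) {
  stopifnot(target > 0, target < 1)
  ctx <- count_ta_contexts(genome)
  target * ctx$n_other / ((1 - target) * ctx$n_ta)
}

#' Simulate deaminase off-target SNVs with TA-context bias
#'
#' Deaminase events are drawn without replacement over the adenines of both
#' strands, each weighted by `ta_weight` when its 5' neighbour on the
#' deaminated strand is T, and recorded as A-to-G (forward) or T-to-C
#' (reverse). Background events are uniform over remaining positions and the
#' six substitution types; germline events are uniform with allele fraction
#' fixed at 0.5 and are implanted in both samples downstream. No position is
#' used twice.
#'
#' @param genome Genome (see [count_ta_contexts()]).
#' @param config An [offtarget_sim_config()]; its `seed` drives all draws.
#' @return A `truth_set`: list with `events` (data.frame `chrom, pos, ref,
#'   alt, strand, origin, af`) and `config`.
#' @export
simulate_deaminase_snvs <- function(genome, config) {
  stopifnot(inherits(config, "offtarget_sim_config"))
  seqs <- as_genome_seqs(genome)
  set.seed(config$seed)
  cc <- list(chrom = list(), pos = list(), ref = list(), w = list())
  for (chrom in names(seqs)) {
    ch <- strsplit(seqs[[chrom]], "")[[1]]
    len <- length(ch)
    fwd <- which(ch == "A"); fwd <- fwd[fwd > 1L]
    rev <- which(ch == "T"); rev <- rev[rev < len]
    cc$chrom[[chrom]] <- rep(chrom, length(fwd) + length(rev))
    cc$pos[[chrom]] <- c(fwd, rev)
    cc$ref[[chrom]] <- rep(c("A", "T"), c(length(fwd), length(rev)))
    w <- rep(1, length(fwd) + length(rev))
    w[c(ch[fwd - 1L] == "T", ch[rev + 1L] == "A")] <- config$ta_weight
    cc$w[[chrom]] <- w
  }
  cand <- lapply(cc, function(x) do.call(c, unname(x)))
  n_cand <- length(cand$pos)
  if (n_cand < config$n_deaminase)
    stop("not enough eligible adenines for n_deaminase")

  events <- list()
  used <- character()
  if (config$n_deaminase > 0L) {
    # weighted sampling without replacement via exponential keys
    key <- stats::rexp(n_cand) / cand$w
    idx <- order(key)[seq_len(config$n_deaminase)]
    d <- data.frame(chrom = cand$chrom[idx], pos = cand$pos[idx],
                    ref = cand$ref[idx],
                    strand = ifelse(cand$ref[idx] == "A", "+", "-"),
                    stringsAsFactors = FALSE)
    events$deaminase <- data.frame(
      chrom = d$chrom, pos = d$pos, ref = d$ref,
      alt = ifelse(d$ref == "A", "G", "C"),
      strand = d$strand, origin = "deaminase",
      af = rtruncnorm01(nrow(d), config$af_mean, config$af_sd),
      stringsAsFactors = FALSE)
    used <- paste(d$chrom, d$pos)
  }
  draw_uniform <- function(n, origin, af) {
    if (n == 0L) return(NULL)
    total <- sum(nchar(seqs))
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      m <- n - if (is.null(out)) 0L else nrow(out)
      chrom <- sample(names(seqs), m, replace = TRUE, prob = nchar(seqs))
      pos <- vapply(chrom, function(cc) sample(nchar(seqs[[cc]]), 1L),
                    integer(1), USE.NAMES = FALSE)
      key <- paste(chrom, pos)
      ok <- !key %in% used & !duplicated(key)
      if (!any(ok)) next
      chrom <- chrom[ok]; pos <- pos[ok]
      ref <- substring(seqs[chrom], pos, pos)
      alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L),
        character(1), USE.NAMES = FALSE)
      add <- data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                        alt = alt,
                        strand = sample(c("+", "-"), length(pos), TRUE),
                        origin = origin,
                        af = if (is.null(af))
                          rtruncnorm01(length(pos), config$af_mean,
                                       config$af_sd) else af,
                        stringsAsFactors = FALSE)
      used <<- c(used, paste(chrom, pos))
      out <- rbind(out, add)
    }
    out[seq_len(n), ]
  }
  events$background <- draw_uniform(config$n_background, "background",
                                    af = NULL)
  events$germline <- draw_uniform(config$n_germline, "germline", af = 0.5)
  ev <- do.call(rbind, events)
  if (is.null(ev))
    ev <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), strand = character(),
                     origin = character(), af = numeric(),
                     stringsAsFactors = FALSE)
  ev <- ev[order(ev$chrom, ev$pos), ]
  rownames(ev) <- NULL
  structure(list(events = ev, config = config), class = "truth_set")
}

#' Write / read a truth set as TSV (lossless round trip)
#' @param truth A `truth_set`.
#' @param path Output TSV path.
#' @export
write_truth_set <- function(truth, path) {
  utils::write.table(truth$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_set
#' @export
read_truth_set <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer", af = "numeric"))
  structure(list(events = ev, config = NULL), class = "truth_set")
}

#' Simulate paired edited/control pileups from a truth set
#'
#' Per position the depth in each sample is Poisson(`depth`); sequencing
#' errors hit reads at `err_rate` per base and convert them to a uniformly
#' chosen other base. Truth events contribute Binomial(depth, af) alt reads
#' in the edited sample only, except germline events which appear in both.
#' The returned pileups are sparse: they carry the union of all positions
#' showing any non-reference observation in either sample plus all truth
#' positions (purely reference positions are omitted).
#'
#' @param genome Genome (see [count_ta_contexts()]).
#' @param truth A `truth_set` from [simulate_deaminase_snvs()].
#' @param config The [offtarget_sim_config()]; `seed + 1` drives the
#'   sequencing layer so that truth generation and sequencing are
#'   independently reproducible.
#' @return List with elements `edited` and `control`, each a pileup
#'   data.frame (`chrom, pos, ref, depth, nA, nC, nG, nT`).
#' @export
simulate_paired_pileups <- function(genome, truth, config) {
  stopifnot(inherits(truth, "truth_set"),
            inherits(config, "offtarget_sim_config"))
  seqs <- as_genome_seqs(genome)
  set.seed(config$seed + 1L)
  bases <- c("A", "C", "G", "T")
  out_e <- list(); out_c <- list()
  for (chrom in names(seqs)) {
    ch <- strsplit(seqs[[chrom]], "")[[1]]
    len <- length(ch)
    dep_e <- stats::rpois(len, config$depth)
    dep_c <- stats::rpois(len, config$depth)
    err_e <- stats::rbinom(len, dep_e, config$err_rate)
    err_c <- stats::rbinom(len, dep_c, config$err_rate)
    tr <- truth$events[truth$events$chrom == chrom, , drop = FALSE]
    pos <- sort(unique(c(which(err_e > 0L), which(err_c > 0L), tr$pos)))
    if (!length(pos)) next
    ref <- ch[pos]
    mk_counts <- function(dep, err) {
      np <- length(pos)
      cnt <- matrix(0L, np, 4, dimnames = list(NULL, bases))
      # reference reads = depth minus error reads at each retained position
      cnt[cbind(seq_len(np), match(ref, bases))] <- dep[pos] - err[pos]
      ei <- which(err[pos] > 0L)
      if (length(ei)) {
        reads <- rep(ei, err[pos][ei])
        alt_off <- sample.int(3L, length(reads), replace = TRUE)
        # error base: one of the 3 non-reference bases, uniformly
        ref_i <- match(ref, bases)[reads]
        alt_i <- ifelse(alt_off >= ref_i, alt_off + 1L, alt_off)
        cnt <- cnt + matrix(tabulate((reads - 1L) * 4L + alt_i,
                                     nbins = 4L * np),
                            ncol = 4L, byrow = TRUE)
      }
      cnt
    }
    cnt_e <- mk_counts(dep_e, err_e)
    cnt_c <- mk_counts(dep_c, err_c)
    if (nrow(tr)) {
      ti <- match(tr$pos, pos)
      alt_j <- match(tr$alt, bases)
      ref_j <- match(tr$ref, bases)
      n_alt_e <- stats::rbinom(nrow(tr), dep_e[tr$pos], tr$af)
      n_alt_e <- pmin(n_alt_e, cnt_e[cbind(ti, ref_j)])
      cnt_e[cbind(ti, alt_j)] <- cnt_e[cbind(ti, alt_j)] + n_alt_e
      cnt_e[cbind(ti, ref_j)] <- cnt_e[cbind(ti, ref_j)] - n_alt_e
      germ <- which(tr$origin == "germline")
      if (length(germ)) {
        n_alt_c <- stats::rbinom(length(germ), dep_c[tr$pos[germ]],
                                 tr$af[germ])
        n_alt_c <- pmin(n_alt_c, cnt_c[cbind(ti[germ], ref_j[germ])])
        cnt_c[cbind(ti[germ], alt_j[germ])] <-
          cnt_c[cbind(ti[germ], alt_j[germ])] + n_alt_c
        cnt_c[cbind(ti[germ], ref_j[germ])] <-
          cnt_c[cbind(ti[germ], ref_j[germ])] - n_alt_c
      }
    }
    mk_df <- function(dep, cnt) data.frame(
      chrom = chrom, pos = pos, ref = ref, depth = dep[pos],
      nA = cnt[, "A"], nC = cnt[, "C"], nG = cnt[, "G"], nT = cnt[, "T"],
      stringsAsFactors = FALSE)
    out_e[[chrom]] <- mk_df(dep_e, cnt_e)
    out_c[[chrom]] <- mk_df(dep_c, cnt_c)
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), depth = integer(), nA = integer(),
                      nC = integer(), nG = integer(), nT = integer(),
                      stringsAsFactors = FALSE)
  e <- if (length(out_e)) do.call(rbind, out_e) else empty
  ctl <- if (length(out_c)) do.call(rbind, out_c) else empty
  rownames(e) <- rownames(ctl) <- NULL
  list(edited = e, control = ctl)
}

#' Amplicon read-simulation configuration
#'
#' The default per-position A-to-G profile is Gaussian-shaped with peak 0.44
#' at protospacer position 5 and asymmetric falloff (sigma 2.2 on the
#' PAM-distal side, 3.5 on the PAM-proximal side), which places the 30%-rule
#' editing window at A2-A10 -- the broad-window, high-activity editor regime.
#' Supply `p_profile` directly to override the parametric shape.
#'
#' @param seed Integer seed.
#' @param n_reads Number of reads (>= 100).
#' @param p_profile Optional numeric vector of per-position true A-to-G
#'   probabilities (length = protospacer length).
#' @param p_peak,peak_pos,sigma Parametric profile: peak probability, peak
#'   position, and Gaussian falloff sd (length 1, or 2 for
#'   PAM-distal/PAM-proximal sides).
#' @param c_edit_rate Per-C bystander C-edit probability per read.
#' @param indel_rate Per-read probability of a 1-3 bp indel near the
#'   protospacer.
#' @param err_rate Uniform per-base sequencing error rate.
#' @param engagement Fraction of reads exposed to the editor (read-level
#'   mixture; 1 = every read editable).
#' @return An `amplicon_sim_config` list.
#' @export
amplicon_sim_config <- function(seed = 1L, n_reads = 5000L, p_profile = NULL,
                                p_peak = 0.44, peak_pos = 5L,
                                sigma = c(2.2, 3.5), c_edit_rate = 0.01,
                                indel_rate = 0.01, err_rate = 0.001,
                                engagement = 1) {
  stopifnot(n_reads >= 100L)
  if (!is.null(p_profile) && any(p_profile < 0 | p_profile > 1))
    stop("p_profile probabilities must lie in [0, 1]")
  stopifnot(p_peak >= 0, p_peak <= 1, c_edit_rate >= 0, c_edit_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, err_rate >= 0, err_rate <= 1,
            engagement > 0, engagement <= 1)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 p_profile = p_profile, p_peak = p_peak,
                 peak_pos = as.integer(peak_pos), sigma = sigma,
                 c_edit_rate = c_edit_rate, indel_rate = indel_rate,
                 err_rate = err_rate, engagement = engagement),
            class = "amplicon_sim_config")
}

#' Gaussian-shaped per-position editing profile
#'
#' @param p_peak Peak probability.
#' @param peak_pos Peak protospacer position.
#' @param sigma Falloff sd; length 2 gives distinct PAM-distal (left) and
#'   PAM-proximal (right) widths.
#' @param proto_len Protospacer length.
#' @return Numeric vector of length `proto_len`.
#' @export
gaussian_profile <- function(p_peak, peak_pos, sigma, proto_len = 20L) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  i <- seq_len(proto_len)
  s <- ifelse(i < peak_pos, sigma[1], sigma[2])
  p_peak * exp(-(i - peak_pos)^2 / (2 * s^2))
}

#' Simulate amplicon reads with a configured editing profile
#'
#' Each read starts as the full amplicon; every protospacer adenine (on the
#' protospacer strand) is independently converted to G with its per-position
#' probability, every protospacer C is converted to a uniformly chosen other
#' base with `c_edit_rate`, a 1-3 bp insertion or deletion is introduced near
#' the protospacer with `indel_rate` per read, and uniform per-base
#' sequencing error is applied last. Deterministic for a fixed seed.
#'
#' @param site A [protospacer_site()].
#' @param config An [amplicon_sim_config()].
#' @return List with `reads` (named character vector), `truth` (list with
#'   the realized `p_profile` and the rates), and `site_id`.
#' @export
simulate_amplicon_reads <- function(site, config) {
  stopifnot(inherits(site, "protospacer_site"),
            inherits(config, "amplicon_sim_config"))
  set.seed(config$seed)
  p <- config$p_profile
  if (is.null(p))
    p <- gaussian_profile(config$p_peak, config$peak_pos, config$sigma,
                          site$proto_len)
  if (length(p) != site$proto_len)
    stop("p_profile length must equal the protospacer length")
  ref <- strsplit(protospacer_seq(site), "")[[1]]
  coords <- proto_coords(site)
  amp <- strsplit(site$amplicon_seq, "")[[1]]
  n <- config$n_reads
  L <- length(amp)
  M <- matrix(rep(amp, each = n), nrow = n)
  engaged <- stats::rbinom(n, 1L, config$engagement) == 1L

  a_pos <- which(ref == "A")
  for (i in a_pos) {
    hit <- engaged & stats::rbinom(n, 1L, p[i]) == 1L
    if (any(hit))
      M[hit, coords[i]] <- if (site$strand == "+") "G" else "C"
  }
  c_pos <- which(ref == "C")
  for (i in c_pos) {
    hit <- engaged & stats::rbinom(n, 1L, config$c_edit_rate) == 1L
    if (any(hit)) {
      to <- sample(c("A", "G", "T"), sum(hit), replace = TRUE)
      M[hit, coords[i]] <- if (site$strand == "+") to else comp_base(to)
    }
  }
  if (config$err_rate > 0) {
    err <- matrix(stats::rbinom(n * L, 1L, config$err_rate) == 1L, n, L)
    if (any(err)) {
      cur <- M[err]
      off <- sample.int(3L, sum(err), replace = TRUE)
      base_i <- match(cur, c("A", "C", "G", "T"))
      M[err] <- c("A", "C", "G", "T")[ifelse(off >= base_i, off + 1L, off)]
    }
  }
  reads <- apply(M, 1, paste, collapse = "")

  indel_reads <- which(stats::rbinom(n, 1L, config$indel_rate) == 1L)
  span <- range(coords)
  for (k in indel_reads) {
    at <- sample(max(2L, span[1] - 5L):min(L - 1L, span[2] + 5L), 1L)
    w <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {           # deletion
      reads[k] <- paste0(substr(reads[k], 1L, at - 1L),
                         substr(reads[k], min(at + w, L + 1L), L))
    } else {                               # insertion
      ins <- paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = "")
      reads[k] <- paste0(substr(reads[k], 1L, at - 1L), ins,
                         substr(reads[k], at, L))
    }
  }
  names(reads) <- sprintf("%s_read%05d", site$site_id, seq_len(n))
  list(reads = reads,
       truth = list(p_profile = p, c_edit_rate = config$c_edit_rate,
                    indel_rate = config$indel_rate,
                    err_rate = config$err_rate,
                    engagement = config$engagement,
                    indel_reads = indel_reads),
       site_id = site$site_id)
}

#' Write reads to FASTQ
#' @param reads Named character vector of read sequences.
#' @param path Output path (".gz" suffix compresses).
#' @param qual_char Constant per-base quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      strrep(qual_char, n), character(1))), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path (plain or gzip).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Plant guide-similar decoy sites into a genome
#'
#' For each requested mismatch count, writes a protospacer (spacer with
#' exactly that many substitutions) plus a concrete PAM instance at a random
#' non-overlapping locus, on a random strand, and returns the modified
#' genome together with a BED-like truth table.
#'
#' @param genome Genome (see [count_ta_contexts()]).
#' @param spacer 20-nt spacer.
#' @param pam IUPAC PAM pattern.
#' @param mismatch_list Integer vector: one planted site per element, with
#'   that many spacer mismatches.
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`) and `truth` (data.frame
#'   `chrom, start, end, strand, mismatches, planted_seq`; 0-based half-open
#'   protospacer coordinates).
#' @export
plant_predicted_sites <- function(genome, spacer, pam = "NGG",
                                  mismatch_list, seed = 1L) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stop("spacer must be a 20-mer")
  seqs <- as_genome_seqs(genome)
  set.seed(seed)
  np <- nchar(pam)
  total_w <- 20L + np
  used <- list()
  truth <- list()
  margin <- 30L
  for (m in mismatch_list) {
    sp <- strsplit(spacer, "")[[1]]
    if (m > 0L) {
      at <- sample(20L, m)
      sp[at] <- vapply(sp[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    pam_concrete <- paste(vapply(strsplit(toupper(pam), "")[[1]],
                                 function(cc) sample(IUPAC_SETS[[cc]], 1L),
                                 character(1)), collapse = "")
    full <- paste0(paste(sp, collapse = ""), pam_concrete)
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") full else revcomp(full)
    placed <- FALSE
    for (try in seq_len(1000L)) {
      chrom <- sample(names(seqs), 1L, prob = nchar(seqs))
      len <- nchar(seqs[[chrom]])
      if (len < total_w + 2L * margin) next
      s <- sample(seq.int(margin, len - total_w - margin), 1L)
      clash <- any(vapply(used[[chrom]] %||% integer(),
                          function(u) abs(u - s) < total_w + margin,
                          logical(1)))
      if (clash) next
      substr(seqs[[chrom]], s, s + total_w - 1L) <- ins
      used[[chrom]] <- c(used[[chrom]], s)
      proto_start0 <- if (strand == "+") s - 1L else s - 1L + np
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = proto_start0, end = proto_start0 + 20L,
        strand = strand, mismatches = m,
        planted_seq = paste(sp, collapse = ""), stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place a site with ", m, " mismatches")
  }
  list(genome = Biostrings::DNAStringSet(seqs),
       truth = do.call(rbind, truth))
}

#' Write a BED file of predicted/planted sites
#' @param sites Data.frame with `chrom, start, end` (0-based half-open) and
#'   optionally `strand`, `mismatches`.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$start,
                    end = sites$end,
                    name = if ("mismatches" %in% names(sites))
                      paste0("mm", sites$mismatches) else ".",
                    score = 0L,
                    strand = if ("strand" %in% names(sites)) sites$strand
                             else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
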