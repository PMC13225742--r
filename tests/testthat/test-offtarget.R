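# Minimal pileup builders for caller unit tests.
pileup_row <- function(pos, ref, depth, alt = NULL, n_alt = 0L,
                       chrom = "chr1") {
  counts <- c(nA = 0L, nC = 0L, nG = 0L, nT = 0L)
  counts[paste0("n", ref)] <- depth - n_alt
  if (!is.null(alt)) counts[paste0("n", alt)] <- n_alt
  data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
             nA = counts["nA"], nC = counts["nC"], nG = counts["nG"],
             nT = counts["nT"], row.names = NULL, stringsAsFactors = FALSE)
}

test_that("the paired caller keeps de novo and rejects germline signal", {
  prof <- caller_profile("default")
  ref_pile <- rbind(pileup_row(100, "A", 50), pileup_row(200, "C", 48))

  # identical pileups: no de novo signal
  expect_equal(nrow(call_denovo_snvs(ref_pile, ref_pile, prof)), 0L)

  # implanted variant af = 0.5 in edited only: called
  ed <- rbind(pileup_row(100, "A", 50, alt = "G", n_alt = 25),
              pileup_row(200, "C", 48))
  calls <- call_denovo_snvs(ed, ref_pile, prof)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100)
  expect_equal(calls$alt, "G")
  expect_equal(calls$af, 0.5)

  # same variant present in the control too: germline exclusion
  ctl <- rbind(pileup_row(100, "A", 50, alt = "G", n_alt = 24),
               pileup_row(200, "C", 48))
  expect_equal(nrow(call_denovo_snvs(ed, ctl, prof)), 0L)

  # reference disagreement between samples is a hard error
  bad <- ref_pile; bad$ref[1] <- "T"; bad$nT[1] <- 50L; bad$nA[1] <- 0L
  expect_error(call_denovo_snvs(ed, bad, prof), "mismatch")
})

test_that("caller thresholds act on depth, alt depth, af and control alt", {
  ed <- pileup_row(10, "A", 50, alt = "G", n_alt = 4)   # af = 0.08
  ctl <- pileup_row(10, "A", 50)
  expect_equal(nrow(call_denovo_snvs(ed, ctl, caller_profile("x"))), 0L)
  sens <- caller_profile("s", min_alt_depth = 2L, min_af = 0.05,
                         max_control_alt = 1L)
  expect_equal(nrow(call_denovo_snvs(ed, ctl, sens)), 1L)
  # low depth in the control blocks the call
  ctl_low <- pileup_row(10, "A", 8)
  expect_equal(nrow(call_denovo_snvs(ed, ctl_low, sens)), 0L)
})

test_that("raising any caller threshold never increases the call count", {
  g <- make_genome(5e4, 0.42, seed = 31L)
  cfg <- offtarget_sim_config(seed = 32L, genome_len = 5e4,
                              n_deaminase = 30L, n_background = 5L,
                              n_germline = 10L)
  truth <- simulate_deaminase_snvs(g, cfg)
  pile <- simulate_paired_pileups(g, truth, cfg)
  base <- caller_profile("b", min_depth = 10L, min_alt_depth = 2L,
                         min_af = 0.05, max_control_alt = 1L)
  n_base <- nrow(call_denovo_snvs(pile$edited, pile$control, base))
  bump <- list(list(min_depth = 20L), list(min_alt_depth = 5L),
               list(min_af = 0.2), list(max_control_alt = 0L))
  for (b in bump) {
    args <- utils::modifyList(list(name = "m", min_depth = 10L,
                                   min_alt_depth = 2L, min_af = 0.05,
                                   max_control_alt = 1L), b)
    n <- nrow(call_denovo_snvs(pile$edited, pile$control,
                               do.call(caller_profile, args)))
    expect_lte(n, n_base)
  }
})

test_that("three-set consensus is the key-wise intersection", {
  mk <- function(pos) {
    df <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                     alt_depth = 10L, depth = 50L, af = 0.2,
                     control_alt_depth = 0L, stringsAsFactors = FALSE)
    class(df) <- c("snv_call_set", "data.frame")
    df
  }
  # {a,b}, {b,c}, {b} -> {b}
  cons <- consensus_intersection(list(mk(c(1, 2)), mk(c(2, 3)), mk(2)))
  expect_equal(cons$pos, 2)
  # identity: S,S,S -> S, and order invariance
  s3 <- mk(c(5, 9, 11))
  expect_equal(consensus_intersection(list(s3, s3, s3))$pos, c(5, 9, 11))
  a <- mk(c(1, 2, 3)); b <- mk(c(2, 3, 4)); c3 <- mk(c(3, 2))
  expect_equal(consensus_intersection(list(a, b, c3))$pos,
               consensus_intersection(list(c3, a, b))$pos)
  # consensus is a subset of each input on random sets
  set.seed(9)
  for (k in 1:5) {
    sets <- lapply(1:3, function(i) mk(sample(100, 30)))
    cons <- consensus_intersection(sets)
    for (s in sets) expect_true(all(cons$pos %in% s$pos))
    expect_equal(sort(cons$pos),
                 sort(Reduce(intersect, lapply(sets, `[[`, "pos"))))
  }
  # union mode and arity errors
  expect_equal(sort(consensus_intersection(list(a, b, c3),
                                           mode = "union")$pos), 1:4)
  expect_error(consensus_intersection(list(a, b)), "exactly 3")
})

test_that("replicate overlap produces correct Venn counts", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                 alt = "G", stringsAsFactors = FALSE)
  # disjoint sets share nothing
  ov <- replicate_overlap(list(a = mk(1:3), b = mk(4:6), c = mk(7:9)))
  expect_equal(ov$all_shared, 0L)
  expect_equal(ov$pairwise["a", "b"], 0L)
  # identical sets share everything
  ov2 <- replicate_overlap(list(a = mk(1:5), b = mk(1:5)))
  expect_equal(ov2$all_shared, 5L)
  expect_equal(ov2$pairwise["a", "b"], 5L)
  # random sets from a large genome essentially never overlap
  set.seed(2024)
  sets <- lapply(1:3, function(i) mk(sample(2.5e6, 300)))
  names(sets) <- paste0("e", 1:3)
  ov3 <- replicate_overlap(sets)
  # hypergeometric expectation 300*300/2.5e6 = 0.036 per pair
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(ov3$pairwise[i, j], 2L)
})

test_that("predicted-site enumeration matches planted truth and the scan oracle", {
  g <- make_genome(1e5, 0.42, seed = 71L)
  spacer <- "GATTACAGATTACATTGACA"
  pl <- plant_predicted_sites(g, spacer, "NGG", c(0L, 1L, 2L, 3L),
                              seed = 72L)
  found2 <- enumerate_predicted_sites(pl$genome, spacer, "NGG", max_mm = 2L)
  expect_equal(sum(found2$mismatches == 0), 1L)
  expect_true(all(found2$mismatches <= 2L))
  expect_equal(nrow(found2), 3L)   # the 3-mismatch decoy is invisible
  found3 <- enumerate_predicted_sites(pl$genome, spacer, "NGG", max_mm = 3L)
  expect_equal(found3[, c("chrom", "start", "end", "strand", "mismatches")],
               pl$truth[order(pl$truth$mismatches),
                        c("chrom", "start", "end", "strand", "mismatches")],
               ignore_attr = TRUE)
  # brute-force Hamming scan agrees exactly
  oracle <- hamming_scan_sites(as.character(pl$genome[[1]]), spacer, "NGG",
                               3L)
  o <- oracle[order(oracle$start, oracle$strand), ]
  f <- found3[order(found3$start, found3$strand), ]
  expect_equal(f[, c("start", "end", "strand", "mismatches")],
               o[, c("start", "end", "strand", "mismatches")],
               ignore_attr = TRUE)
  expect_error(enumerate_predicted_sites(g, "ACGT", "NGG", 1L), "20-mer")
})

test_that("SNV/predicted-site overlap matches the quadratic oracle", {
  set.seed(55)
  sites <- data.frame(chrom = "chr1",
                      start = sort(sample(1e6, 40)), stringsAsFactors = FALSE)
  sites$end <- sites$start + 20L
  snvs <- data.frame(chrom = "chr1", pos = sample(1e6, 500),
                     stringsAsFactors = FALSE)
  for (flank in c(0L, 25L, 200L)) {
    ov <- overlap_with_predicted(snvs, sites, flank_bp = flank)
    expect_equal(ov$count, quadratic_overlap_count(snvs, sites, flank))
  }
  # an SNV inside a protospacer is counted; empty site lists give zero
  inside <- data.frame(chrom = "chr1", pos = sites$start[1] + 5L)
  expect_equal(overlap_with_predicted(inside, sites, 0L)$count, 1L)
  expect_equal(overlap_with_predicted(snvs, sites[0, ], 25L)$count, 0L)
})

test_that("group statistics reproduce the closed-form Welch test and folds", {
  res <- group_statistics(list(treated = c(10, 11, 12),
                               control = c(5, 6, 7)), control = "control")
  tr <- res[res$group == "treated", ]
  expect_equal(tr$fold_vs_control, 11 / 6)
  expect_equal(tr$sem, sd(c(10, 11, 12)) / sqrt(3))
  expect_equal(tr$p_value, welch_p(c(10, 11, 12), c(5, 6, 7)))
  # identical groups: fold 1, p ~ 1
  res2 <- group_statistics(list(a = c(4, 5, 6), ctl = c(4, 5, 6)),
                           control = "ctl")
  expect_equal(res2$fold_vs_control[res2$group == "a"], 1)
  expect_gt(res2$p_value[res2$group == "a"], 0.99)
  # zero control mean: undefined fold, warning
  expect_warning(res3 <- group_statistics(list(a = c(1, 2), ctl = c(0, 0)),
                                          control = "ctl"), "zero")
  expect_true(is.na(res3$fold_vs_control[1]))
})
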