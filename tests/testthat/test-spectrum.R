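snv_df <- function(ref, alt, chrom = "chr1", pos = seq_along(ref)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("12-class spectrum counts and combined fractions are exact", {
  sp <- mutation_spectrum(snv_df("A", "G"))
  expect_equal(unname(sp$counts_12["A>G"]), 1L)
  expect_equal(sp$frac_AG_TC, 1.0)

  sp2 <- mutation_spectrum(snv_df(c(rep("A", 6), rep("T", 3), "C"),
                                  c(rep("G", 6), rep("C", 3), "T")))
  expect_equal(sp2$frac_AG_TC, 0.9)
  expect_equal(sp2$frac_CT_GA, 0.1)
  expect_equal(sp2$n_total, 10L)

  # ambiguous bases are excluded and counted
  sp3 <- mutation_spectrum(snv_df(c("A", "N"), c("G", "T")))
  expect_equal(sp3$n_total, 1L)
  expect_equal(sp3$n_excluded, 1L)
})

test_that("a spectrum equals the sum of the spectra of any partition", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 60, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snvs <- snv_df(ref, alt)
  whole <- mutation_spectrum(snvs)
  cut <- sort(sample(2:59, 2))
  parts <- list(snvs[1:cut[1], ], snvs[(cut[1] + 1):cut[2], ],
                snvs[(cut[2] + 1):60, ])
  summed <- Reduce(`+`, lapply(parts,
                               function(p) mutation_spectrum(p)$counts_12))
  expect_equal(whole$counts_12, summed)
})

test_that("context orientation puts the deaminated A at position 0", {
  #        123456789
  ref <- c(chr1 = "GGTACCCTAGG")
  # A>G at pos 4 (forward: TA context); T>C at pos 8 (minus-strand A whose
  # 5' neighbour on the deaminated strand is complement of pos 9 = T... )
  snvs <- snv_df(c("A", "T"), c("G", "C"), pos = c(4L, 8L))
  cm <- context_logo(snvs, ref, flank = 1, pseudocount = 0)
  expect_equal(cm$n, 2L)
  expect_equal(unname(cm$base_counts["0", "A"]), 2L)  # both oriented to A
  # forward event -1 base = T (pos 3); flipped event -1 base = comp(pos 9) = T
  expect_equal(unname(cm$base_counts["-1", "T"]), 2L)
  expect_equal(ta_context_fraction(snvs, ref), 1.0)
  # events in a GA-only context score zero
  ref2 <- c(chr1 = "GGGAGGGAGG")
  snvs2 <- snv_df(c("A", "A"), c("G", "G"), pos = c(4L, 8L))
  expect_equal(ta_context_fraction(snvs2, ref2), 0.0)
})

test_that("information content matches the entropy closed forms", {
  ref <- c(chr1 = paste(rep("TA", 50), collapse = ""))  # TATA...: all A at even pos
  pos <- seq(2, 40, by = 2)
  snvs <- snv_df(rep("A", length(pos)), rep("G", length(pos)), pos = pos)
  cm <- context_logo(snvs, ref, flank = 1, pseudocount = 0)
  # every -1 base is T: zero entropy, ic exactly 2 bits without pseudocount
  expect_equal(unname(cm$ic["-1"]), 2)
  expect_true(all(cm$ic >= 0 & cm$ic <= 2))

  # half T / half A at -1: 1 bit
  ref3 <- c(chr1 = "TTATTAAAAA")
  snvs3 <- snv_df(rep("A", 4), rep("G", 4), pos = c(3L, 6L, 8L, 9L))
  cm3 <- context_logo(snvs3, ref3, flank = 1, pseudocount = 0)
  expect_equal(unname(cm3$ic["-1"]), 1)

  # uniform base usage at -1: 0 bits
  ref4 <- c(chr1 = "GTAGAACATG")
  snvs4 <- snv_df(rep("A", 4), rep("G", 4), pos = c(3L, 5L, 6L, 8L))
  # -1 bases: T, G, A, C -> uniform, ic 0 without pseudocount
  cm4 <- context_logo(snvs4, ref4, flank = 1, pseudocount = 0)
  expect_equal(unname(cm4$ic["-1"]), 0)
})

test_that("pseudocounts shrink ic toward uniform and keep it in [0, 2]", {
  ref <- c(chr1 = paste(rep("TA", 20), collapse = ""))
  pos <- seq(2, 20, by = 2)
  snvs <- snv_df(rep("A", length(pos)), rep("G", length(pos)), pos = pos)
  cm <- context_logo(snvs, ref, flank = 1)   # default pseudocount 0.5
  n <- length(pos)
  f <- (c(A = 0, C = 0, G = 0, T = n) + 0.5) / (n + 2)
  ic_expected <- 2 + sum(f * log2(f))
  expect_equal(unname(cm$ic["-1"]), ic_expected)
  expect_lt(unname(cm$ic["-1"]), 2)
  expect_gt(unname(cm$ic["-1"]), 0)
})

test_that("the oriented context matrix is strand-consistent", {
  set.seed(88)
  seq <- random_seq(400)
  ref <- c(chr1 = seq)
  ch <- strsplit(seq, "")[[1]]
  apos <- which(ch == "A"); apos <- apos[apos > 5 & apos < 395]
  tpos <- which(ch == "T"); tpos <- tpos[tpos > 5 & tpos < 395]
  snvs <- snv_df(c(rep("A", 10), rep("T", 10)),
                 c(rep("G", 10), rep("C", 10)),
                 pos = c(sample(apos, 10), sample(tpos, 10)))
  cm <- context_logo(snvs, ref, flank = 3)

  # flip the world: reverse-complement the genome and mirror the calls
  L <- nchar(seq)
  ref_rc <- c(chr1 = revcomp(seq))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snvs_rc <- snv_df(unname(comp[snvs$ref]), unname(comp[snvs$alt]),
                    pos = L + 1L - snvs$pos)
  cm_rc <- context_logo(snvs_rc, ref_rc, flank = 3)
  expect_equal(cm_rc$base_counts, cm$base_counts)
  expect_equal(cm_rc$ic, cm$ic)
})

test_that("events whose flank leaves the contig are skipped and counted", {
  ref <- c(chr1 = "TAAAAT")
  snvs <- snv_df(c("A", "A"), c("G", "G"), pos = c(2L, 5L))
  cm <- context_logo(snvs, ref, flank = 3)
  expect_equal(cm$n, 0L)
  expect_equal(cm$n_skipped, 2L)
  cm1 <- context_logo(snvs, ref, flank = 1)
  expect_equal(cm1$n, 2L)
})

test_that("rna mode relabels T as U in the reported matrix", {
  ref <- c(tx1 = "GGTACCCTAG")
  snvs <- snv_df("A", "G", chrom = "tx1", pos = 4L)
  cm <- context_logo(snvs, ref, flank = 1, mode = "rna")
  expect_equal(colnames(cm$base_counts), c("A", "C", "G", "U"))
})
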