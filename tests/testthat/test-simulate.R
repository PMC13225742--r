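test_that("random genomes hit the requested GC and are seed-deterministic", {
  g <- make_genome(1e5, gc = 0.5, seed = 101L)
  ch <- strsplit(as.character(g[[1]]), "")[[1]]
  gc_obs <- mean(ch %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 1e5))

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(make_genome(2e4, 0.42, seed = 7L), f1)
  write_fasta(make_genome(2e4, 0.42, seed = 7L), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(make_genome(1e5, gc = 1.0), "gc")
  expect_error(make_genome(100, gc = 0.5), "1e4")
})

test_that("deaminase truth sets respect counts, classes and TA weighting", {
  g <- make_genome(1e5, 0.42, seed = 11L)
  # empty configuration gives an empty truth set
  cfg0 <- offtarget_sim_config(seed = 1L, genome_len = 1e5, n_deaminase = 0L,
                               n_background = 0L, n_germline = 0L)
  expect_equal(nrow(simulate_deaminase_snvs(g, cfg0)$events), 0L)

  cfg <- offtarget_sim_config(seed = 2L, genome_len = 1e5,
                              n_deaminase = 300L, n_background = 20L,
                              n_germline = 10L)
  truth <- simulate_deaminase_snvs(g, cfg)
  ev <- truth$events
  expect_equal(as.vector(table(ev$origin)[c("deaminase", "background",
                                            "germline")]),
               c(300L, 20L, 10L))
  de <- ev[ev$origin == "deaminase", ]
  expect_true(all((de$ref == "A" & de$alt == "G") |
                    (de$ref == "T" & de$alt == "C")))
  expect_false(any(duplicated(paste(ev$chrom, ev$pos))))
  expect_true(all(ev$af > 0 & ev$af < 1))
  expect_true(all(ev$af[ev$origin == "germline"] == 0.5))

  # unweighted sampling reproduces the genomic TA-context proportion
  ctx <- count_ta_contexts(g)
  p_ta <- ctx$n_ta / ctx$n_total
  ta_obs <- ta_context_fraction(de, g)
  expect_lt(abs(ta_obs - p_ta), 3 * sqrt(p_ta * (1 - p_ta) / 300))

  # weighted sampling reaches a calibrated target fraction
  w <- ta_weight_for_fraction(g, 0.8)
  cfgw <- offtarget_sim_config(seed = 3L, genome_len = 1e5,
                               n_deaminase = 300L, ta_weight = w,
                               n_background = 0L, n_germline = 0L)
  tw <- simulate_deaminase_snvs(g, cfgw)
  ta_w <- ta_context_fraction(tw$events, g)
  expect_lt(abs(ta_w - 0.8), 3 * sqrt(0.8 * 0.2 / 300))
})

test_that("truth sets round-trip losslessly through TSV", {
  g <- make_genome(2e4, 0.42, seed = 21L)
  cfg <- offtarget_sim_config(seed = 4L, genome_len = 2e4, n_deaminase = 25L,
                              n_background = 5L, n_germline = 5L)
  truth <- simulate_deaminase_snvs(g, cfg)
  f <- tempfile(fileext = ".tsv")
  write_truth_set(truth, f)
  back <- read_truth_set(f)
  expect_equal(back$events, truth$events)
})

test_that("paired pileups carry truth only in the edited sample", {
  g <- make_genome(2e4, 0.42, seed = 31L)
  # error-free, af = 1: edited all-alt at the event, control all-ref
  cfg <- offtarget_sim_config(seed = 5L, genome_len = 2e4, n_deaminase = 5L,
                              n_background = 0L, n_germline = 0L,
                              af_mean = 0.999, af_sd = 1e-4, err_rate = 0)
  truth <- simulate_deaminase_snvs(g, cfg)
  pile <- simulate_paired_pileups(g, truth, cfg)
  expect_equal(nrow(pile$edited), 5L)
  for (i in seq_len(5)) {
    ev <- truth$events[i, ]
    e <- pile$edited[pile$edited$pos == ev$pos, ]
    ctl <- pile$control[pile$control$pos == ev$pos, ]
    expect_equal(e[[paste0("n", ev$alt)]], e$depth)
    expect_equal(ctl[[paste0("n", ev$ref)]], ctl$depth)
  }
  # empty truth and no error: nothing deviates from the reference
  cfg0 <- offtarget_sim_config(seed = 6L, genome_len = 2e4, n_deaminase = 0L,
                               n_background = 0L, n_germline = 0L,
                               err_rate = 0)
  pile0 <- simulate_paired_pileups(g, simulate_deaminase_snvs(g, cfg0), cfg0)
  expect_equal(nrow(pile0$edited), 0L)
})

test_that("amplicon reads reproduce trivial configurations exactly", {
  s <- example_site("sim0", seed = 41L)
  # all-zero profile and rates: every read equals the amplicon
  cfg <- amplicon_sim_config(seed = 7L, n_reads = 100L,
                             p_profile = rep(0, 20), c_edit_rate = 0,
                             indel_rate = 0, err_rate = 0)
  sim <- simulate_amplicon_reads(s, cfg)
  expect_true(all(sim$reads == s$amplicon_seq))

  # p[5] = 1 and nothing else: a2g[5] exactly 1
  p <- rep(0, 20); p[5] <- 1
  cfg2 <- amplicon_sim_config(seed = 8L, n_reads = 100L, p_profile = p,
                              c_edit_rate = 0, indel_rate = 0, err_rate = 0)
  sim2 <- simulate_amplicon_reads(s, cfg2)
  prof <- quantify_site(align_reads(sim2$reads, s), s)
  expect_equal(unname(prof$a2g[5]), 1)
  expect_equal(unname(prof$a2g[4]), 0)

  expect_error(amplicon_sim_config(p_profile = c(rep(0, 19), 1.5)),
               "0, 1")
})

test_that("indel and engagement rates shape the simulated reads", {
  s <- example_site("simI", seed = 42L)
  cfg <- amplicon_sim_config(seed = 9L, n_reads = 1000L,
                             p_profile = rep(0, 20), c_edit_rate = 0,
                             indel_rate = 0.2, err_rate = 0)
  sim <- simulate_amplicon_reads(s, cfg)
  prof <- quantify_site(align_reads(sim$reads, s), s)
  expect_lt(abs(prof$indel_fraction - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))

  # engagement mixture halves the effective editing rate
  p <- rep(0, 20); p[5] <- 0.8
  cfgE <- amplicon_sim_config(seed = 10L, n_reads = 4000L, p_profile = p,
                              c_edit_rate = 0, indel_rate = 0, err_rate = 0,
                              engagement = 0.5)
  simE <- simulate_amplicon_reads(s, cfgE)
  profE <- quantify_site(align_reads(simE$reads, s), s)
  expect_lt(abs(profE$a2g[5] - 0.4), 3 * sqrt(0.4 * 0.6 / 4000))
})

test_that("all generators are byte-deterministic under a fixed seed", {
  s <- example_site("det", seed = 43L)
  cfg <- amplicon_sim_config(seed = 11L, n_reads = 200L)
  expect_identical(simulate_amplicon_reads(s, cfg),
                   simulate_amplicon_reads(s, cfg))
  g <- make_genome(2e4, 0.42, seed = 12L)
  ocfg <- offtarget_sim_config(seed = 13L, genome_len = 2e4,
                               n_deaminase = 20L, n_background = 5L,
                               n_germline = 5L)
  t1 <- simulate_deaminase_snvs(g, ocfg)
  t2 <- simulate_deaminase_snvs(g, ocfg)
  expect_identical(t1, t2)
  expect_identical(simulate_paired_pileups(g, t1, ocfg),
                   simulate_paired_pileups(g, t1, ocfg))
  p1 <- plant_predicted_sites(g, "GATTACAGATTACATTGACA", "NGG", 0:2,
                              seed = 14L)
  p2 <- plant_predicted_sites(g, "GATTACAGATTACATTGACA", "NGG", 0:2,
                              seed = 14L)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  expect_identical(p1$truth, p2$truth)
})

test_that("fastq output round-trips through the reader", {
  s <- example_site("fq", seed = 44L)
  cfg <- amplicon_sim_config(seed = 15L, n_reads = 150L)
  sim <- simulate_amplicon_reads(s, cfg)
  f <- tempfile(fileext = ".fastq.gz")
  write_fastq(sim$reads, f)
  back <- read_fastq(f)
  expect_equal(back, sim$reads)
})
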