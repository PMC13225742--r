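#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream analyses need, with known
# ground truth. Produces (i) a demonstration amplicon site with 5,000
# simulated deep-sequencing reads from the broad-window editor profile
# (peak 0.44 at A5), and (ii) a 2.5-Mb genome with one edited/control
# embryo pair: 350 deaminase off-target SNVs (TA-biased so the expected
# TA-context fraction is 0.8), 13 spontaneous background SNVs, 50 germline
# variants, sequenced at 50x with 0.1% error.

suppressMessages(library(abequant))
seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("== amplicon inputs ==")
site <- example_site("demo", seed = seed, intended_positions = 5L)
write_fasta(setNames(site$amplicon_seq, "amp_demo"),
            file.path(out, "amplicons.fa"))
writeLines(c("site_id\tamplicon_id\tproto_start\tstrand\tpam\tintended_positions",
             sprintf("demo\tamp_demo\t%d\t+\tNGG\t5", site$proto_start)),
           file.path(out, "sites.tsv"))
acfg <- amplicon_sim_config(seed = seed + 100L, n_reads = 5000L)
sim <- simulate_amplicon_reads(site, acfg)
write_fastq(sim$reads, file.path(out, "reads_demo.fastq.gz"))
write.table(data.frame(position = seq_along(sim$truth$p_profile),
                       true_a2g = sim$truth$p_profile),
            file.path(out, "amplicon_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("wrote %d reads; true peak %.2f at A%d",
                length(sim$reads), max(sim$truth$p_profile),
                which.max(sim$truth$p_profile)))

message("== GOTI inputs (embryo 1) ==")
genome <- make_genome(2.5e6, gc = 0.42, seed = seed + 200L)
write_fasta(genome, file.path(out, "genome.fa"))
ta_w <- ta_weight_for_fraction(genome, 0.8)
message(sprintf("TA weight for an expected 0.8 TA fraction: %.2f", ta_w))
cfg <- offtarget_sim_config(seed = seed + 301L, n_deaminase = 350L,
                            ta_weight = ta_w, n_background = 13L)
truth <- simulate_deaminase_snvs(genome, cfg)
write_truth_set(truth, file.path(out, "embryo1_truth.tsv"))
pile <- simulate_paired_pileups(genome, truth, cfg)
write_pileup_tsv(pile$edited, file.path(out, "embryo1_edited.pileup.tsv"))
write_pileup_tsv(pile$control, file.path(out, "embryo1_control.pileup.tsv"))
message(sprintf("embryo 1: %d truth events (%s), %d informative pileup positions",
                nrow(truth$events),
                paste(names(table(truth$events$origin)),
                      table(truth$events$origin), collapse = ", "),
                nrow(pile$edited)))
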