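#!/usr/bin/env Rscript
# Stage 3: paired de novo SNV calling. First calls embryo 1 from the
# pileup files written by stage 1 (three threshold profiles, consensus =
# intersection) and measures recall / false positives / germline leakage
# against the truth set. Then runs the full 3 edited + 3 control embryo
# cohort in memory and writes per-embryo consensus counts.

suppressMessages(library(abequant))
seed <- 1L
ind <- "results/simulated"
out <- "results/goti"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
key <- function(df) paste(df$chrom, df$pos, df$alt)

message("== embryo 1 (from files) ==")
edited <- read_pileup_tsv(file.path(ind, "embryo1_edited.pileup.tsv"))
control <- read_pileup_tsv(file.path(ind, "embryo1_control.pileup.tsv"))
calls <- lapply(default_caller_profiles(), function(p)
  call_denovo_snvs(edited, control, p))
message(sprintf("per-profile calls: %s",
                paste(names(calls), sapply(calls, nrow), collapse = ", ")))
cons <- consensus_intersection(calls)
write_snv_tsv(cons, file.path(out, "embryo1_consensus.tsv"))

truth <- read_truth_set(file.path(ind, "embryo1_truth.tsv"))
ev <- truth$events
denovo <- key(ev[ev$origin != "germline", ])
germ <- key(ev[ev$origin == "germline", ])
found <- key(cons)
message(sprintf("consensus %d calls; recall %.3f; false positives %d; germline called %d",
                nrow(cons), mean(denovo %in% found),
                sum(!found %in% c(denovo, germ)), sum(germ %in% found)))

message("== 3 + 3 embryo cohort (in memory) ==")
genome <- make_genome(2.5e6, gc = 0.42, seed = seed + 200L)
ta_w <- ta_weight_for_fraction(genome, 0.8)
run_embryo <- function(embryo_seed, n_deaminase) {
  cfg <- offtarget_sim_config(seed = embryo_seed, n_deaminase = n_deaminase,
                              ta_weight = ta_w, n_background = 13L)
  truth <- simulate_deaminase_snvs(genome, cfg)
  pile <- simulate_paired_pileups(genome, truth, cfg)
  consensus_intersection(lapply(default_caller_profiles(), function(p)
    call_denovo_snvs(pile$edited, pile$control, p)))
}
cohort <- data.frame(
  group = rep(c("edited", "control"), each = 3),
  embryo = rep(1:3, 2),
  seed = c(seed + 301:303, seed + 401:403))
cohort$consensus_snvs <- mapply(function(g, s)
  nrow(run_embryo(s, if (g == "edited") 350L else 0L)),
  cohort$group, cohort$seed)
write.table(cohort, file.path(out, "cohort_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(paste(capture.output(print(cohort)), collapse = "\n"))

# replicate overlap across the three edited embryos: de novo events are
# private to each embryo, so shared counts should be ~0
sets <- lapply(cohort$seed[cohort$group == "edited"], function(s)
  run_embryo(s, 350L))
names(sets) <- paste0("embryo", 1:3)
ov <- replicate_overlap(sets)
write.table(ov$venn, file.path(out, "replicate_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("SNVs shared by all three edited embryos: %d",
                ov$all_shared))
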