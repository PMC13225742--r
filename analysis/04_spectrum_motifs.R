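#!/usr/bin/env Rscript
# Stage 4: mutation spectrum and sequence-context analysis of the embryo-1
# consensus calls from stage 3. Classifies calls into the 12 directed
# substitution classes, orients A>G / T>C events onto the deaminated-A
# strand, and reports the flanking-context matrix, per-position
# information content, and the TA-motif fraction. Also enumerates
# guide-similar decoy sites planted into the genome and checks that the
# de novo SNVs do not overlap them (the deaminase events are
# guide-independent).

suppressMessages(library(abequant))
ind <- "results/simulated"
out <- "results/spectrum"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snvs <- read_snv_calls("results/goti/embryo1_consensus.tsv")
genome <- file.path(ind, "genome.fa")

sp <- mutation_spectrum(snvs)
write.table(data.frame(class = names(sp$counts_12), count = sp$counts_12),
            file.path(out, "spectrum.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("A>G + T>C fraction: %.1f%% of %d SNVs",
                100 * sp$frac_AG_TC, sp$n_total))

logo <- context_logo(snvs, genome, flank = 3)
write.table(data.frame(position = rownames(logo$base_counts),
                       logo$base_counts, ic_bits = logo$ic),
            file.path(out, "context_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ta <- ta_context_fraction(snvs, genome)
message(sprintf("TA-context fraction of oriented events: %.3f (ic at -1: %.2f bits)",
                ta, logo$ic["-1"]))

# guide-similar decoys: plant, enumerate, and test SNV overlap
spacer <- "GATTACAGATTACATTGACA"
pl <- plant_predicted_sites(genome, spacer, "NGG", c(0L, 1L, 2L, 3L),
                            seed = 11L)
found <- enumerate_predicted_sites(pl$genome, spacer, "NGG", max_mm = 3L)
write_sites_bed(found, file.path(out, "predicted_sites.bed"))
ov <- overlap_with_predicted(snvs, found, flank_bp = 25L)
message(sprintf("planted %d decoys, enumerated %d sites; %d of %d SNVs overlap them",
                nrow(pl$truth), nrow(found), ov$count, nrow(snvs)))
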