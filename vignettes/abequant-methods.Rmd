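---
title: "Methods: quantifying adenine base editing and its genome-wide off-targets"
author: "abequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying adenine base editing and its genome-wide off-targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abequant)
```

# Scope and model

Adenine base editors (ABEs) convert A•T base pairs to G•C within a window of
the 20-nt protospacer bound by a Cas9 nickase. Characterizing an ABE variant
requires two complementary measurements:

1. **On-target behaviour** from targeted amplicon deep sequencing:
   per-position A→G efficiency across the protospacer, the *editing window*,
   bystander edits (A→G at unintended positions, C edits anywhere in the
   protospacer), indels, and the fraction of reads carrying a *perfect* edit.
2. **Guide-independent off-target behaviour** from paired whole-genome
   comparisons in the GOTI design: an edited and an unedited cell population
   from the same embryo are sequenced and de novo SNVs (present in the edited
   sample, absent from its matched control) are called and characterized by
   substitution spectrum and sequence context. Deaminase-driven off-targets
   show A→G/T→C symmetry and enrichment of a 5′ T next to the deaminated A
   (the TA motif).

`abequant` implements both quantification arms plus the synthetic-data
generators that make every stage testable end-to-end with known truth, with
the workflow organized as numbered driver scripts under `analysis/` over the
package functions.

# Position convention

Protospacer positions are numbered A1…A20 from the PAM-distal (5′) end, with
the PAM immediately 3′-adjacent, and all observed bases are reported on the
protospacer strand. For a minus-strand site, amplicon bases are complemented
and coordinates mirrored; quantifying a site and its reverse-complemented
amplicon with mirrored coordinates yields identical profiles (this is a
tested invariant).

# Amplicon quantification

**Alignment.** Reads are aligned to the amplicon with a fitting alignment
(pattern-global, free end gaps on the amplicon) under affine gap scoring:
match +2, mismatch −3, and a gap of length $L$ costing $8 + L$. Published
pipelines do not standardize these values; they are exposed as arguments and
the suite verifies the scores against an independent full
dynamic-programming oracle. A read is an *indel read* when any alignment gap
overlaps the protospacer ±10 bp. Reads with non-ACGTN characters or shorter
than 30 nt are rejected and counted, not fatal.

**Denominators.** Indel reads are excluded from substitution-frequency
denominators and reported separately as `indel_fraction`
(`include_indel_reads = TRUE` switches to the inclusive convention, since
published reports rarely state which one they use). `N` bases count neither
as edits nor as coverage. At a position,
$\mathrm{a2g}_i = \#\{\text{G at } i\}/\#\{\text{covering substitution-only reads}\}$
for reference-A positions; `c_edit` is the analogous C→(A/G/T) frequency at
reference-C positions. Zero-coverage positions get `NA` and are flagged.

**Editing window.** The window is the set of positions whose mean efficiency
is ≥ 30% of the peak (`threshold_frac = 0.30`), computed on the mean profile
across sites rather than per-site-then-voted, matching how panel-level
windows are reported. The rule yields a *set*; because measured profiles are
unimodal in practice but need not be, `contiguous_window()` additionally
reports the largest contiguous run through the peak, which is the
conventional "A2–A10"-style display. Ties at the peak break to the smallest
position; the window is invariant under uniform scaling of the profile.

**Purity.** `purity_metrics()` forms A2/A5, A8/A5 (bystander ratios) and
C5/A5. Ratios are `NaN` with a warning when A5 efficiency is zero, and `NA`
when the reference base required at a position is absent. Note that a single
site cannot carry both an A and a C at position 5, so the C5/A5 ratio is a
*library-level* quantity: `aggregate_purity()` averages per-position
frequencies over the sites carrying the required base before forming
ratios.

**Perfect and dual edits.** A perfect read has no indel, G at every intended
position, and the reference base at every other protospacer position. When a
site defines two intended positions, the dual fraction counts reads with G
at both regardless of other positions; indel reads cannot display the
protospacer faithfully and count as non-dual. Both fractions are over all
aligned reads.

# Paired de novo SNV calling

Pileups (`chrom, pos, ref, depth, nA, nC, nG, nT`; 1-based positions,
BED-style 0-based half-open intervals for site lists, conversions
centralized) from the edited and control samples are compared per position
and alt base. A call requires depth ≥ `min_depth` in *both* samples,
`alt_depth ≥ min_alt_depth` and allele fraction ≥ `min_af` in the edited
sample, and at most `max_control_alt` alt reads in the control (germline
exclusion). Reference disagreement between the samples is a hard error.

The three external somatic callers used in GOTI-style studies are emulated
as three threshold profiles of this one caller — strict (5 alt reads, AF
0.15), default (3, 0.10) and sensitive (2, 0.05, one control alt tolerated),
all with `min_depth` 10 — and the consensus is their **intersection**,
following the original GOTI convention; a union mode is available because
published descriptions do not always state the rule. Raising any threshold
can only shrink the call set (tested monotonicity).

At the simulated study conditions (50× Poisson depth, mosaic allele
fractions ~ truncated Normal(0.5, 0.1), 0.1%/base error), the dominant loss
mechanism is a single sequencing-error read in the control hitting the true
alt base (probability ≈ 50 × 0.001/3 ≈ 1.7% per site under
`max_control_alt = 0`), which bounds expected recall near 0.98 — comfortably
above the 0.95 design target — while error-only false calls require ≥ 5
alt-matching errors at one position and are vanishingly rare genome-wide.

# Spectrum, context and motif analysis

`mutation_spectrum()` tabulates the 12 directed substitution classes and the
combined A→G + T→C fraction (the adenine-deamination signature read on
either strand). For context analysis, A→G calls are read on the forward
strand and T→C calls reverse-complemented so position 0 is always the
deaminated A; other classes are excluded. Per flanking position (±3 by
default; the width is not standardized, so it is an argument) the
information content is $2 - H$ bits, with a pseudocount of 0.5 per base to
stabilize small-$n$ columns (raw counts are reported alongside; closed-form
checks use pseudocount 0). The TA-motif fraction is the fraction of oriented
events whose −1 base is T; RNA mode reports U for T and consumes
transcript-strand-resolved calls (strand assignment is an input, not
inferred). The context matrix is strand-consistent: reverse-complementing
the reference and flipping all calls leaves it unchanged (tested).

# Synthetic data generators

The generators define the study conditions; their defaults are fixed to the
regime the quantification machinery is designed for and are not tuned per
run:

* **Genome**: i.i.d. bases, default GC 0.42 (mouse-like), ≥ 10 kb,
  byte-deterministic per seed. Default length for cohort simulations is
  2.5 Mb — large enough that 350 events are sparse (no position reuse,
  negligible replicate overlap) while a full 3+3-embryo cohort runs in about
  a minute on one CPU.
* **Deaminase off-targets**: 350 events per edited embryo over a background
  of 13 spontaneous SNVs, mirroring the reported per-embryo burden of a
  high-activity broad-window editor versus control; events are drawn without
  replacement over both strands' adenines (exponential-key weighted
  sampling), weighted by `ta_weight` when the 5′ neighbour on the deaminated
  strand is T. `ta_weight_for_fraction()` solves
  $w\,n_{TA}/(w\,n_{TA}+n_{other}) = f$ by exhaustive context enumeration;
  the workflow calibrates $w$ for an expected TA fraction of 0.8, matching
  strong TA preference. Background events are uniform over positions and the
  six substitution types — the control spectrum of spontaneous mutations is
  roughly uniform but not parameterized in published data, so uniform is the
  neutral choice.
* **Mosaicism**: allele fractions per event ~ Normal(0.5, 0.1) truncated to
  (0, 1), reflecting a single-blastomere lineage after sorting; no published
  AF distribution exists, so these defaults are stated, not inferred.
  Germline variants (default 50; present in both samples at AF 0.5) exercise
  the germline-exclusion path.
* **Pileups**: per-position depth ~ Poisson(50); errors ~
  Binomial(depth, 0.001) to a uniform other base in both samples; truth alt
  reads ~ Binomial(depth, AF) in the edited sample (both samples for
  germline). Pileups are *sparse*: only positions with any non-reference
  observation in either sample, plus all truth positions, are emitted — a
  position absent from both carries no calling information.
* **Amplicon reads**: each protospacer A edited independently per read with
  its per-position probability (default Gaussian shape, peak 0.44 at A5,
  asymmetric σ = 2.2/3.5 so the 30% rule yields window A2–A10); C positions
  edited at 0.01/read; 1–3 bp indels at 0.01/read near the protospacer;
  uniform error 0.001/base. Per-position independence ignores processivity
  correlation along a read; the optional `engagement` mixture (fraction of
  reads exposed to the editor) reintroduces read-level correlation when
  needed.
* **Decoy sites**: `plant_predicted_sites()` writes protospacer+PAM
  sequences with exact mismatch counts at random non-overlapping loci, for
  validating the exhaustive guide-similarity scan.

**What the generators do not emulate**: quality-score-dependent error
profiles, PCR duplicates, alignment/mapping artefacts, structural variants,
chromatin- or replication-driven ssDNA exposure, and real genome composition
(repeats, CpG structure). Passing tests therefore demonstrate correctness of
the quantification arithmetic and calling logic under a clean error model,
not robustness to real-data artefacts upstream of pileups.

# Numerical choices and degenerate inputs

* Window of an all-zero profile: empty set, peak 0, peak position `NA`.
* Frequencies at zero-coverage positions: `NA`, listed in an attribute.
* Ratio denominators equal to zero: `NaN` with a warning (never silently
  dropped).
* Consensus of call sets requires exactly three sets; fewer or more is an
  error, set keys are `(chrom, pos, alt)`.
* Alignment tie-breaks are deterministic (leftmost gap placement via the
  alignment engine); all simulators are byte-deterministic per seed, and
  `run_pipeline()` reports (including `summary.json`) hash identically for
  identical configs and seeds.
* Truncated-normal AF draws resample rather than clip, so no AF mass
  accumulates at the bounds.

# Problem sizes used in tests and scripts

Unit tests run on 10–100 kb genomes and 100–5,000-read simulations; the
acceptance checks use the full study conditions (5,000 reads per site;
2.5-Mb genome, 350+13 events, 50×, 3+3 embryos; 1-Mb exhaustive-scan oracle
comparisons). These sizes were chosen as the smallest at which the binomial
3-SD tolerances are decisive for the effects being measured.

# Known limitations

* The aligner targets pre-merged single amplicon reads; paired-end merging,
  UMI handling and demultiplexing are out of scope, as is quality trimming
  beyond rejecting malformed reads.
* Indel *calling* in the paired arm is limited to what pileup gap counts
  would support and is not a focus; the amplicon arm quantifies indel reads
  only as a fraction.
* The guide-similarity scan is exhaustive and intended for desk-scale
  genomes (≤ ~50 Mb), not a genome-scale replacement for dedicated
  off-target search tools.
* RNA-mode context analysis consumes variant calls with transcript strand
  already resolved; discovering RNA edits from raw RNA-seq is out of scope.
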