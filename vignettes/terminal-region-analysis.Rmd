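---
title: "Analysing terminal-region turnover in linear bacterial replicons"
author: "linearends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing terminal-region turnover in linear bacterial replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linearends)
```

## The biological problem

Streptomyces and several other bacteria carry *linear* chromosomes and
plasmids with an invertron architecture: the two ends are occupied by
terminal inverted repeats (TIRs) — identical sequences in inverse
orientation that can span hundreds of kilobases — and terminate in a
telomere of roughly 180 nt that folds into an array of palindromic
stem-loops, capped by a terminal protein complex (Tpg plus its Tap
partner, or the GtpA/GtpB counterpart). Within a population of closely
related strains, these terminal regions turn over rapidly: TIRs expand,
shrink and exchange material; telomeres can be replaced wholesale, for
example by recombination with a linear plasmid; and the genes encoding
the terminal protein machinery travel alongside the telomeres they
serve.

`linearends` packages the analyses needed to characterise that turnover
on assemblies plus short reads: TIR delimitation from read depth,
telomere recovery by read walking, stem-loop typing, telomere-vs-genome
phylogenetic congruence, consensus recombination scanning, and a
terminal-protein inventory. A population simulator with complete ground
truth makes every stage testable without external data.

## The population simulator

`simulate_population()` defines the study conditions. An ancestor is
drawn at a configurable GC content (default 0.72, the high-GC regime of
Streptomyces) and evolved along a fixed sub-clade tree (a caterpillar of
caterpillars; 11 strains split 4+3+2+2 across sub-clades I–IV by
default) with independent per-site substitutions on every branch
(default 10^-3^ per site per branch). Each sub-clade receives its own
telomere, derived from one ancestral telomere by *compensatory* stem
mutations (G↔C flips mirrored across the two arms, so pairing is
preserved) plus its own loop motif — CTTG for sub-clade I, GGA
elsewhere, GCA available for plasmids. Terminal-protein operons
(gtpB–gtpA in every strain, tap–tpg in sub-clade I) are reverse-
translated with GC-biased codons and planted inside the left TIR;
substitutions applied to them revert nonsense changes, emulating
purifying selection. Finally the right arm is recopied as the reverse
complement of the left arm, the homogenisation that break-induced
replication (BIR) between chromosome arms maintains in vivo; the truth
annotation records the exact TIR length as the longest terminal
reverse-complement match, so events that alter it are reflected
faithfully.

Rearrangement events are applied per strain in order:
`substitution_burst`, `terminal_indel`, `bir_homogenize` (recopy one arm
from a breakpoint through the telomere — upstream breakpoints grow both
TIR copies), `telomere_swap` (replace one end's terminal 180 nt with a
donor telomere — from a plasmid, another strain, or a literal payload —
then homogenise, installing it at both ends), `hgt_insert`,
`translocation` and `inversion`.

Two deliberate simplifications matter for interpretation. First,
telomeres and planted TP genes are protected from background
substitutions (strains within a sub-clade share identical telomeres);
real populations show exactly this within-clade identity, but the
protection means passing tests say nothing about telomere *calling*
under within-clade polymorphism. Second, between-sub-clade telomere
divergence defaults to 20% per-position change. Real telomere families
can diverge to the point of barely aligning; such pairs would saturate
the K2P correction (a non-positive logarithm argument), which the
distance code flags and refuses rather than guessing. The simulator
therefore emulates *related* telomere families inside the model's
validity domain.

### Telomere construction

`build_telomere()` places `n_stems` hairpins (arms 4–8 bp by default,
loop = the class motif) separated by spacers into 180 nt. Stems are
drawn over {G,C} and spacers are poly-A: spacers cannot pair with
themselves, and spacer–arm pairing requires the rare sheared geometry
only. Because random padding would plant spurious stems (a random
180-mer contains several small inverted repeats), each construction is
verified by folding — the built sequence must contain exactly the
planted stems, all loops equal to the motif — and resampled otherwise.
This is what makes the generator's postcondition ("exactly n stems")
deterministic for a fixed seed.

### Read simulation

`simulate_reads()` models shearing of a *linear* molecule: fragment
starts are uniform over an extended range and reads are clipped at the
physical ends (clipped reads shorter than 31 nt are dropped). Interior
coverage is uniform at the requested fold while the termini remain
covered — fragment ends pile up at a physical DNA end. A model with
strictly interior full-length reads would leave the last read-length of
the molecule nearly uncovered and no read-walking procedure could ever
recover a telomere from it. Read count follows a Poisson law with mean
coverage·L/read-length; errors are i.i.d. substitutions (default
10^-3^); qualities are constant placeholders because depth analysis
ignores them.

## TIR detection from read-depth doubling

NGS assemblies represent a large terminal duplication once, so the reads
of both physical copies map onto the single retained copy: the TIR is
the terminal region with twice the read depth of the replicon's central
region. `map_reads()` is a deterministic seed-and-extend mapper (exact
21-mer seeds, best full-read placement up to 5 mismatches, ties broken
leftmost then forward strand). `detect_tir()` operationalises the
doubling rule: baseline = median of 500-bp window means over the central
50% of the assembly; per end, a two-segment least-squares change-point
on the window means, refined to base resolution by a local per-base
change-point scan; a terminal segment is *detected* when its mean/baseline
ratio falls in [1.6, 2.4] and its length reaches 1 kb. Undetected ends
report size 0 — the state of a linear plasmid with no measurable TIR.

The windowing, the central-50% baseline, the ratio window and the
change-point model are this package's operational choices: the doubling
rule itself does not specify them, and they were chosen to be robust to
Poisson depth noise and simple to verify by brute force. Reads spanning
the copy-junction boundary map nowhere, so the depth does not step but
ramps down over one read length, and a two-segment mean fit places its
split mid-ramp — half a read length inside the true boundary. When the
profile records its read length, `detect_tir()` therefore shifts the
detected boundary outward by half a read length; this is derived from
the mapping geometry, not fitted. Residual uncertainty remains on the
order of a read length, the same resolution limit one has on real
data; profiles loaded from external depth tables carry no read length
and receive no correction.

External pileups are accepted as two-column TSV (`read_depth_tsv()`), so
a production mapper can substitute for the built-in one.

## Telomere recovery by consensus read walking

`extend_end()` walks off a terminus: reads overlapping the current end
by ≥ 31 nt with ≤ 1 mismatch (either strand, anchored on an exact
terminal 31-mer) vote on the next base, which is appended only with
support ≥ 5 reads and agreement ≥ 0.8. The walk stops with an explicit
reason — `no_overlap`, `low_support`, `ambiguous`, or `max_length`
(cap 1000 nt) — rather than guessing; at a physical end, support thins
and the very last nucleotides may remain unrecoverable, which is
reported, not papered over. The left end is extended as the right end of
the reverse complement.

## Stem-loop typing

Thermodynamic folding is replaced by a combinatorial model that captures
what telomere typing actually uses: the stems and their loop motifs.
`find_hairpins()` exhaustively enumerates inverted repeats with arm ≥ 3,
loop length 3 or 4 (the observed GNA/GCA and CTTG classes), at most one
mismatched stem position, and sheared purine–purine G·A pairs tolerated
at the two loop-proximal stem positions only — sheared pairing is a
loop-adjacent phenomenon. The tolerated set also contains T·C, the image
of a sheared pair read from the complementary strand; including it makes
folding exactly reverse-complement symmetric in total paired bases.
`fold_telomere()` selects the non-overlapping subset maximising
canonically paired bases by weighted-interval scheduling (ties: fewer
hairpins, then scan order); counting only canonical pairs in the
objective prevents mismatch-and-sheared-heavy fragments from displacing
clean stems. `classify_loops()` takes the strict majority loop among the
selected hairpins within {GCA, GGA, CTTG} (GNA other than GCA collapses
to the GGA class), else `other`. On inputs of ≤ 40 nt both the
enumeration and the packing are verified against naive exhaustive
search in the test suite.

## Telomere phylogeny and congruence

`align_telomeres()` is a deterministic progressive aligner: all-pairs
global alignments (match +1, mismatch −1, gap open −5, extend −1) give
identity distances, UPGMA orders the merges, profiles merge by affine
profile–profile alignment. `filter_sites()` drops columns with < 80%
coverage (the 0.80 boundary is kept, reading the threshold strictly).
`k2p_distance()` uses pairwise deletion (only mutually ungapped sites
per pair) with d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q); saturated pairs are
flagged and `nj_tree()` refuses them unless overridden. NJ is
Saitou–Nei with lexicographic tie-breaking and negative branch lengths
clamped to zero, the deficit moved to the sister branch.
`bootstrap_support()` resamples columns (default 100 replicates,
seeded); support is the percentage of replicates containing each
internal bipartition of the full-data tree. Zero-length internal edges
are treated as unresolved polytomies and excluded from bipartition
bookkeeping — distance ties between identical sequences otherwise
manufacture arbitrary, meaningless splits.

`compare_topologies()` reports shared and incompatible bipartitions
(four-point incompatibility test; the symmetric difference is the RF
distance) and lists leaf pairs grouped in the telomere tree but
separated in the genome tree — the operational telomere-exchange
signal. `pairwise_identity()` uses global alignment with terminal gap
runs excluded from the denominator: recovered telomeres differ in
length, so the missing ends are not penalised, but the alignment cannot
collapse onto a short shared repeat the way a local or overlap
alignment would (diverged telomeres share poly-A spacer runs that would
otherwise report near-perfect identity).

## Recombination scanning

Three detectors share one substrate (`informative_sites()`: variable,
biallelic triplet columns labelled by which parent the recombinant
matches). `maxchi_scan()` slides a breakpoint and computes a 2×2
chi-square of A- vs B-matching counts in 20-site flanking windows;
`chimaera_scan()` does the same on the sites where the recombinant
differs from exactly one parent; `triplet_descent_scan()` walks +1/−1
over the site sequence and takes the maximum descent from the running
maximum. All three use seeded permutation nulls (site-order shuffles) in
place of the original tools' analytic or exact p-values — uniform,
testable and reproducible. `scan_triplets()` preserves the published
two-step structure: an exploratory scan of every ordered triplet at the
nominal alpha with a reduced permutation count, then a confirmatory
rescan of flagged triplets at the full count with Bonferroni correction
across the flagged set (correcting across all triplets at realistic
permutation counts would make significance unreachable by construction;
the two-step design concentrates the multiplicity cost where the
confirmatory tests are). `consensus_events()` merges events across
methods within a 50-column breakpoint tolerance, keeps those supported
by ≥ 2 of the 3 detectors (the original protocol votes 3 of 5 across
five tools; with three detectors the default is 2, and the rule is
configurable), attributes each event to the candidate donor with maximal
segment identity (floor 0.9, else `unknown`), and deduplicates across
triplets sharing the recombinant. The result is independent of input
event order.

## Terminal-protein inventory

`find_orfs()` reports ORFs of ≥ 100 codons from ATG/GTG starts on both
strands (overlaps allowed); a GFF3 + protein FASTA path bypasses it.
`find_homologues()` performs exact Smith–Waterman (BLOSUM62, gap
−11/−1) of each query against each protein — at desk scale proteomes are
small enough that a heuristic search would add nothing — and filters at
50% identity over aligned columns and 98% *query* coverage (the
published cutoff does not say which sequence the coverage is measured
on; query coverage is this package's documented reading). Because
genuine terminal proteins have been reported just below the 50% line,
hits at 45–50% identity meeting coverage are kept in a separate `review`
tier instead of being silently dropped. `call_operons()` pairs adjacent
same-strand tap+tpg or gtpB+gtpA hits within 200 bp into
`type_I_tap_tpg` / `type_II_tap_tpg` / `gtpBA` calls. `hth_flag()` is a
purely advisory position-weight-matrix scan for helix-turn-helix-like
motifs against a user-supplied pattern; no NLS or conserved-domain
prediction is attempted.

## The pipeline and its determinism

`run_pipeline()` executes simulate → tir → extend → fold → phylo →
recomb → tp with per-stage seeds derived deterministically from the
global seed, so stages can be rerun in isolation. Artifacts are written
with an MD5 manifest; identical config and seed give identical
checksums. `emit_report()` joins the stages into one row per strain —
TIR size and status, depth ratio, loop class, telomere group (single
linkage at 92% identity), congruence flag, TP systems, recombination
burden — printing an em-dash wherever a stage did not run or detect,
never a fabricated value. The `analysis/` scripts are thin numbered
drivers over these functions and write their tables under `results/`.

## Problem sizes and numerical choices

Desk-scale defaults — 200-kb chromosomes with 20-kb TIRs, 50× coverage
of 300-bp reads, 100 bootstrap replicates, 1000 permutations — keep a
full population analysis in minutes on one core while preserving every
qualitative feature of the real scale (6–12-Mb chromosomes, 300–580-kb
TIRs), which is available as the `preset = "full"` configuration. The
test suite checks TIR recovery over 50 seeded replicates, extension
round-trips over 50, swap detection over 20 populations, detector
calibration over 200 null triplets, and telomere round-trips over
3 motifs × 8 stem counts × 20 seeds; these sizes are the package's
choice of evidence strength.

Remaining limitations: no indel sequencing errors, no paired-end reads
and no quality model; no gapped read alignment (mosaic TIRs with large
indels need pre-cut colinear input for the recombination scan); the
folding model has no free energies, multiloops or bulges longer than
the single tolerated mismatch; coordinates in truth annotations are not
remapped through user-supplied indel events (TP gene coordinates go
stale after an upstream insertion); and the ML phylogenomic genome tree
is an *input* (Newick), never computed here.
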