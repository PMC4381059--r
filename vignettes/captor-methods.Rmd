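---
title: "Screening CRISPR-Cas9 off-target activity by targeted sequence capture"
author: "captor package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CRISPR-Cas9 off-target activity by targeted sequence capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captor)
```

## The problem

*S. pyogenes* Cas9 is guided to a genomic locus by a 20-nt protospacer
sequence followed by an NGG protospacer-adjacent motif (PAM). Cleavage at
unintended loci — off-target activity — is the central safety concern of
CRISPR genome editing. Candidate off-target sites come from two routes:
sequence similarity (genomic loci within a few mismatches of the
protospacer, adjacent to a PAM) and genome-wide binding maps (dCas9
ChIP-seq peaks). Neither route predicts *cleavage* well, so candidates must
be validated by measuring indel frequencies — the scar left by NHEJ repair
of a double-strand break — at each locus. Targeted sequence capture makes
that validation scalable: hundreds to thousands of 200-bp candidate windows
are enriched by hybridization baits, sequenced, and screened for indels
simultaneously, treated sample against untreated control.

`captor` implements the full desk-side arm of that workflow:

1. **`scan_genome()`** — mismatch+PAM scan for predicted off-target loci,
   plus `seed_match()`/`core_match()` for partial-match statistics over
   peak sequences.
2. **Peak-set algebra** — `split_grna_specific()`,
   `intersect_replicates()`, `overlap_fraction()`, `subtract_blacklist()`,
   and `pam_density()` with `compare_density_groups()`.
3. **`make_capture_regions()` / `tile_baits()` /
   `pick_random_controls()`** — 200-bp capture windows tiled by three
   100-bp baits at a 50-bp step.
4. **The capture indel pipeline** — `preprocess_reads()`,
   `assign_to_regions()`, `remove_clonal()`, `merge_pairs()`,
   `classify_read()`, `summarize_regions()`, `fisher_significance()`,
   `indel_profiles()`, `coverage_stats()`.
5. **A synthetic-data generator** (`make_genome()`, `plant_sites()`,
   `simulate_capture_reads()`, `simulate_peak_sets()`) producing every
   input with known ground truth, and **`run_screen()`** chaining it all.

## Coordinate and orientation conventions

Interval inputs and outputs follow the BED convention (0-based, half-open)
in plain data frames; functions returning `GRanges` use the 1-based
Bioconductor convention internally and say so in their documentation.
Protospacers are written 5'→3' with the PAM 3' of position 20; mismatch
positions are numbered 1–20 with **20 PAM-adjacent**, so the 12-bp seed is
positions 9–20 and the 5-bp core positions 16–20. A minus-strand hit is
reported over its plus-strand footprint with the matched sequence and PAM
reverse-complemented into protospacer orientation.

## The genome scan

Every 23-bp window on both strands is a candidate: the scan reports windows
whose PAM trinucleotide matches an IUPAC pattern (NGG by default, NAG
supported) and whose 20-mer is within `max_mm` substitutions of the
protospacer (default 4). Candidate 20-mers are located with
`Biostrings::matchPattern` and then PAM-filtered; windows containing
non-ACGT bases are skipped rather than guessed at. No repeat masking is
applied by default — a mask BED can be supplied — because masking choices
belong to the caller. The scan is validated in the test suite against a
character-level brute-force enumeration of all windows; note that random
sequence essentially never lies within 6 mismatches of a 20-mer, so those
comparisons run on genomes seeded with constructed near-miss variants.

## PAM density and statistical groupings

`pam_density()` counts NGG occurrences on both strands (CCN on the plus
strand stands for the minus-strand NGG) of the central 100 bp of each
region, overlapping occurrences included, and reports the count as a
percentage of the window. On a random 42%-GC genome the expected density is
about `2 * 98 * 0.21^2 ≈ 8.6%`, and the synthetic screen reproduces a
median of 8–9%; GC-rich regulatory sequence scores far higher, which is the
proposed explanation for sequence-nonspecific dCas9 binding at open, GC-rich
loci. Group letters are assigned from pairwise Welch t-tests at
`alpha = 1e-4`: maximal cliques of the "not significantly different" graph
each receive a letter, so two groups share a letter exactly when no test
separates them. Zero-variance pairs are flagged and compared on means.

## The capture indel pipeline

**Filtering.** 3' bases under the quality threshold, adapter read-through
and terminal N bases are trimmed; a pair is dropped whole if either mate
falls below 35 bp.

**Assignment.** A pair is assigned to the unique region whose reference
shares its best anchor (longest common substring, either orientation).
Implementation: an exact 20-mer index over both strands of every reference
is probed every 10 bases along each mate, which detects any shared anchor
of ≥ 29 bp; only pairs touching several regions pay for explicit
longest-common-substring scoring. Ties — including genuinely duplicated
reference sequences — leave the pair unassigned.

**Clonal removal.** Capture libraries are made by random shearing, so
independent fragments are staggered. Pairs with identical (region, start1,
start2, orientation) keys are PCR clones; the first is kept. Start
coordinates come either from an external SAM alignment
(`read_sam_coords()`) or from the k-mer anchors of the built-in assigner.

**Merging.** Mate 2 is reverse-complemented and the longest exact 3'/5'
overlap of at least 5 bp joins the pair into one fragment-length sequence;
unmergeable pairs are classified as two separate reads.

**Classification.** The longest common substring between read and
reference is the primary anchor (< 20 bp ⇒ discarded). Anchors of ≥ 5 bp
are then chained outward over the unanchored flanks, so a read carrying
both an indel and a sequencing error is still measured end to end; anchors
under 5 bp are ignored because a few-base remainder matches the reference
flank by chance and would fake a length difference. The implied reference
span between the outer anchor endpoints must reach 100 bp (shorter ⇒
discarded). The net length difference between read and reference across
that span sets the class: negative = deletion, positive = insertion, zero
with identical gap bases = WT, zero otherwise = SNP. The indel position is
the midpoint of the indel-bearing gap relative to the region center. The
suite validates the classifier against `Biostrings::pairwiseAlignment`
(unit costs): agreement is exact on error-free reads whose edit lies ≥ 10 bp
from the read ends, and ≥ 99% at a 0.1% substitution-error rate.

**Summaries, filters and significance.** Per region,
`indel_pct = 100 × (n_ins + n_del) / n_total` with SNP reads kept in the
denominator. Regions are excluded from testing when: classified reads
number fewer than `min_reads = 25`; the reference contains a homopolymer
run of `homopolymer_len = 5` or more (the documented stricter variant 6 is
accepted — indel-calling artefacts concentrate in homopolymers); or the
untreated sample already shows more than `background_pct = 5%` indels,
which indicates a strain/reference mismatch, a property of the cell line
rather than of the nuclease. Significance is a one-sided Fisher's exact
test of indel enrichment in the treated sample over the untreated control
on the (indel / non-indel) × (treated / control) table at raw
`alpha = 0.01`; no multiple-testing correction is applied by default (the
test count is reported alongside), with Bonferroni/BH available, and a
`direction = "reverse"` mode tests the opposite enrichment as a negative
control.

## What the synthetic generator emulates — and what it does not

`simulate_capture_reads()` draws, per 200-bp region, `depth_per_region`
fragments of Normal(150, 20) length — the shearing target of the emulated
library — sequenced as 100 + 100 paired ends; 150 reads per region matches
the coverage such capture experiments actually deliver. Fragment starts are
uniform (staggered, as shearing produces) over the window in which the
fragment still overlaps the baited region by at least
`min_capture_overlap = 100` bp; hybridization does not retain
barely-touching fragments, and the unrestricted window would make most
read pairs span too little reference to classify. A fraction
`true_indel_freq` of fragments is designated mutant and carries one indel
whose left edge sits at the cut site, 3 bp upstream of the PAM on the
PAM-bearing strand; sizes are uniform on 1–5 bp and deletions outnumber
insertions 4:1 (the observed predominance of deletions; the exact ratio is
a free parameter). Substitution errors are applied per base; a fraction
`clonal_rate` of pairs is re-emitted as exact PCR duplicates; qualities are
constant Q40 by default so that quality trimming is exercised explicitly,
not incidentally.

Two deliberate simplifications matter when reading test results. First, a
mutant fragment whose cut site lies outside the fragment or within 5 bp of
its edge reads as wild type — as it would in a real library — so measured
frequencies sit a few relative percent below the planted values; the
recovery tests therefore compare at three binomial standard errors.
Second, the generator does not model capture-hybridization dropout of
large indels, PCR chimeras, or quality-profile decay, so passing tests
demonstrate correctness of the analysis, not robustness to every
real-library artefact.

The paper-scale quantities that depend on the real mm9 genome and the
deposited sequencing runs (precise genome-wide hit counts, the measured
ChIP peak statistics, the published per-site indel frequencies) are not
reproducible from synthetic data; the synthetic screen plants its target
frequencies at the published point estimates (16.8% and 15.6% at the two
target sites, 11.3% at the one active off-target) so the whole analysis
path is exercised at realistic effect sizes.

## The end-to-end screen

`run_screen()` builds the genome, plants the two targets (S1
`GCTCCCTACGCATGCGTCCC`, PAM AGG; S2 `AATGGCTCAGGTTTGTCGCG`, PAM CGG) plus
mismatched off-target sites, one of which (S2_OT1) is nuclease-active;
scans for predicted sites; builds capture regions and baits plus random
controls; simulates treated and untreated libraries; runs the pipeline on
both; and calls significance. Planting slots are nudged onto
homopolymer-free windows — a capture design would not target sequences
destined for exclusion. Capture efficiency is reported against additional
*non-baited* random windows, which receive no fragments, so the fold
enrichment is effectively the mean targeted coverage over a floor of one
read per random region. Two runs with the same config produce identical
tables; the report carries the config hash and seed.

Problem sizes throughout (120-kb genome, 14 planted sites, 150 pairs per
region; 200 regions at depth 300 in the recovery tests) are chosen so the
full suite and the acceptance script each complete in minutes on a single
core while keeping every statistical check adequately powered — e.g. the
weakest planted signal, 11.3% at ~145 classified reads, yields ≈ 16
expected indel reads against a near-zero control, far past the 0.01 Fisher
threshold.

## Numerical and degenerate-input choices

* Overlap criterion everywhere: ≥ 1 shared base, the interval-toolkit
  default; "common" peaks are materialized from the first set's
  coordinates.
* Peak/site center: `floor((start + end) / 2)` in 0-based coordinates.
* Merging takes the longest exact overlap; a contained read merges to the
  container.
* `fisher_significance()` marks regions with zero classified reads on
  either side as undefined and excluded; `pam_density()` skips (with a
  warning) regions whose window would run off the contig; degenerate
  variance in `compare_density_groups()` is flagged and compared on means.
* All randomness flows from a single integer seed; simulation functions
  accept `seed = NA` to continue an existing RNG stream inside a larger
  reproducible computation.

## Known limitations

The assigner requires a shared ~29-bp exact stretch, so reads wholly inside
highly diverged or heavily mutated regions go unassigned rather than
mis-assigned. The classifier reports one net indel per read; a read with
several separated indels yields their net sum. Bulged (gapped) protospacer
matches and position-weighted off-target scores are out of scope, as are
peak calling, motif discovery, and GC-skew detection — peak and feature
sets are consumed as BED intervals.
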