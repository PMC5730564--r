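---
title: "Evidence-based transcript boundary annotation with tbone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based transcript boundary annotation with tbone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbone)
```

## The model

Spliced-leader (SL) trans-splicing replaces the native 5' end of a pre-mRNA
with a short conserved leader RNA. Two consequences matter for genome
annotation. First, the observable 5' end of a mature mRNA is the
trans-splice acceptor site, not the transcription start site; a read that
begins with a 3' suffix of the leader pinpoints that site at single-base
resolution once the leader-derived prefix is trimmed. Second, genes can be
transcribed as polycistronic precursors: one assembled transcriptional unit
(TU) then carries several internal trans-splice sites and encodes several
proteins. An assembler cannot see this — only 5'/3'-end evidence can.

`tbone` therefore treats annotation as a cutting problem. Inputs are a
genome, TUs from any genome-guided assembler (GTF), and two kinds of read
evidence: SL-trimmed read 5' ends and 3'-end (T-fill) read ends, either as
raw FASTQ (trimmed by `detect_and_trim_sl()` / `detect_polya_tail()`) or as
pre-mapped placements (SAM or BED; mapping itself is out of scope).
Placements are piled into strand-specific per-base tracks and grouped into
peaks. Peaks are assigned to TUs, and each TU is partitioned at its SL
summits; within each resulting segment the strongest poly(A) summit defines
the 3' boundary.

All internal coordinates are 0-based half-open; GTF I/O converts to 1-based
inclusive and BED/bedGraph are natively 0-based. One conversion site
prevents off-by-one drift, and all computations on the minus strand run in
"oriented" coordinates (genomic position negated), so 5'/3' logic is written
once and strand symmetry holds by construction — a property the test suite
checks by reflecting a fixture through the scaffold.

## Peak calling

The peak definition is deliberately minimal: per (scaffold, strand),
positions with signal are grouped into runs whose consecutive members are
at most `merge_distance` (default 10 nt) apart; a group is a peak iff its
total count reaches `min_site_count` (default 5 reads). The summit is the
highest-count position, ties breaking toward the transcript 5' direction,
which yields the longest mature mRNA and is conservative for promoter
selection. The rule is deterministic, recovers planted sites exactly on
clean data, and its grouping is checked against an exhaustive partition
oracle in the tests. Raising `min_site_count` can only remove peaks
(monotonicity), and group totals conserve the track total.

## Cutting rules and their edge cases

Given SL summits $s_1 < \dots < s_k$ in transcript orientation:

* gene $i$ spans $[s_i, e_i]$, where $e_i$ is the summit of the
  highest-count poly(A) peak strictly between $s_i$ and $s_{i+1}$ (count
  ties break 3'-wards — again the longest mRNA); without poly(A) evidence
  $e_i$ is the base immediately 5' of $s_{i+1}$, or the TU 3' end for the
  last gene, and the gene is flagged accordingly;
* a 5' leader segment upstream of $s_1$ is emitted as an unspliced gene
  only if its exonic length exceeds `min_gene_len`;
* $k = 0$ returns the TU unchanged as one `NO_SL` gene;
* evidence summits within `end_slack` (default 50 nt) outside the TU span
  extend the terminal exons instead of cutting: assemblers systematically
  under-assemble transcript ends, and evidence just outside an end almost
  always belongs to this TU;
* an SL summit falling in a parent intron snaps 3'-wards to the nearest
  exonic base, a poly(A) summit 5'-wards; boundaries are genomic and the
  intron chain is inherited from the parent;
* genes whose clipped exonic length falls below `min_gene_len`
  (default 100 nt) are dropped. The default keeps everything a mature
  transcriptome of this kind retains (the shortest transcripts reported for
  such assemblies are just above 100 nt).

Alternative poly(A) sites within a segment are not emitted as extra models;
one evidence-defined 3' end per gene is reported, the strongest. Parent TUs
are classified by SL multiplicity (none / single / multiple), and the
summary table reports parent-level percentages alongside gene-level poly(A)
rates.

## Filters

The antisense filter compares exon-overlapping transcripts on opposite
strands of the same coordinates and discards the lower-expressing strand
when the strand-specific exonic read counts differ at least fivefold
(inclusive threshold, read verbatim from the procedure it reimplements).
"Same genomic coordinates" is made precise as: the exonic overlap must
cover at least half of the lower-expressed transcript's exonic length
(`min_overlap_frac` = 0.5). A zero count against a positive one counts as
an infinite ratio; two zero counts demonstrate no fold difference and keep
both. Decisions are taken on the original counts, so a discarded transcript
cannot rescue another, and the filter is idempotent.

The novel-transcript filter drops TUs with RPKM < 0.5 (strict) that also
lack any overlap with a trusted reference set — a conjunction, checked as
such in the tests.

## ORF calling and split-gene merging

`find_longest_orf()` scans the three forward frames only — gene models are
stranded mature mRNAs, so reverse frames are meaningless — and returns the
longest ATG-to-stop candidate of at least `min_aa` = 100 amino acids (the
conventional minimum for coding-potential calling), ties to the 5'-most
start; an ATG-to-sequence-end candidate is returned as incomplete. The
implementation is validated against a brute-force enumeration on thousands
of random sequences.

Repetitive regions break assemblies, so a gene can be split into an
upstream fragment carrying the ORF but no poly(A) site and a downstream
fragment carrying the poly(A) site but no ORF. `merge_split_transcripts()`
merges exactly this flag combination — the 4-bit truth table is tested
exhaustively — when the genomic gap is at most 10 kb and at least half of
it (`min_repeat_frac` = 0.5, a made-precise reading of "repetitive") is
repeat-covered. Merging is a single 5'-to-3' pass; the gap becomes an
intron, and the ORF is re-called on the merged sequence (both the pre- and
post-merge calls are kept in the records).

## Redundancy and naming

Transcript clustering is greedy and incremental: sequences sorted by length
descending (ties by identifier) join the first representative they match at
95% identity or found a new cluster. Identity is identical aligned bases
over the length of the shorter sequence — the conventional semantics of the
`-c` parameter of greedy clustering tools — computed by global alignment;
reverse-complement comparison is disabled, mirroring `-r 0`. A shared-k-mer
prefilter was considered and rejected: with this identity denominator,
unpenalized insertions in the longer sequence can break every shared k-mer
while identity stays 1.0, so no q-gram bound is lossless; all candidate
pairs are aligned. The greedy result is compared against an independent
full-pairwise-matrix implementation in the tests. ORFs are additionally
deduplicated at 100% amino-acid identity, keeping the longest source
transcript. Cluster members share a zero-padded numeric prefix
(`Mlig000001.g1`, `.g2`, ...), assigned deterministically.

## Codon tools

`build_weight_matrix()` takes the 100 most abundantly expressed
non-redundant genes (redundancy removal is delegated to the clustering
module), counts codons over their CDS excluding the terminal stop, and
scores each codon by relative adaptiveness — count divided by the maximal
synonymous count, so every family has a weight-1 codon. Zero-count codons
receive `0.5 / max_count`, strictly below any observed codon, so the
optimizer never selects them; a fully unobserved family falls back to
uniform weight 1 and is flagged. Optimization is deterministic by default
(one amino acid, one best codon, ties alphabetical; the most frequently
observed stop codon is appended) because transgene design wants a fixed
sequence; a seeded sampling mode exists but is not the default. Weights
depend only on expression ranks, and `translate(optimize(p)) == p` holds by
construction and is verified on a thousand random proteins. One documented
ambiguity: a protein written entirely in A/C/G/T residues that also parses
as a clean CDS (whole codons, single terminal stop) is treated as a CDS.

## Duplicated blocks

For duplication analysis the genome is repeat-masked to N and compared
against itself: exact 16-mers (canonicalized, so inverted copies are found;
windows containing N are skipped) anchor candidate pairs, collinear anchors
on a diagonal are chained, and chained candidates are refined by local
alignment with 60 nt flanks. Blocks are reported when the alignment exceeds
500 columns (strict) at 95% identity or better (inclusive), identity being
matches over alignment columns; same-scaffold blocks whose intervals
overlap are discarded as self-hits. Two numerical choices deserve note.
The anchor-chain gap limit is 300 nt: at 95% identity exact 16-mers recur
every ~20 nt on average, but the waiting-time tail produces occasional
>100 nt anchor droughts inside blocks of a few hundred nt, and a broken
chain splits a qualifying block into two sub-threshold halves; 300 nt is
far above the tail yet far below the 500 nt length floor, so it cannot fuse
genuinely distinct qualifying blocks. The refining alignment scores
mismatches at three times a match: extension then requires over 75% local
match density, so random flanking sequence (~25%) cannot stretch a block
and dilute the identity of a block sitting exactly at the 0.95 threshold,
while dense terminal mismatches are trimmed. Gaps cost more than a
mismatch so substitutions are never re-coded as indel pairs, keeping the
column denominator honest. `duplicated_fraction()` reports union coverage
of all block sides, optionally excluding masked positions.

## What the generator emulates — and what it does not

`simulate_dataset()` draws, per seed: two 120 kb scaffolds of uniform
random sequence; 50 TUs with 1–3 exons per gene (200–600 nt exons,
150–500 nt introns, 40–120 nt exonic spacers between genes of a
polycistron) in proportions 45% single-gene, 25% polycistronic (2–3
genes), 30% no-evidence; Poisson(20) reads per SL and poly(A) site with
configurable Gaussian positional jitter and substitution errors (defaults
0 — the clean regime is the reference condition, jitter is the robustness
dial); antisense partners on 20% of TUs at the filter's fivefold count
ratio; 5% repeat content; and optional planted duplications with exact
realized identity (substitutions only). Every output stream draws from its
own RNG substream derived from the master seed, so adding one output never
perturbs the others, and identical seeds give byte-identical files. The
default SL leader is a fixed synthetic 20-mer; real leaders are
species-specific and are passed as configuration.

The generator intentionally omits several features of real data: uniform
base composition (no GC structure or repeat families beyond the mask),
substitution-only duplications (no indels), no internal priming artifacts
at A-rich genomic positions, no quality-score model, and perfectly
strand-clean placements. Passing the closure tests therefore demonstrates
the correctness of the algorithms under their stated assumptions — exact
recovery at zero noise, graceful degradation under jitter — not performance
on any particular organism's library chemistry.

## Problem sizes and runtime choices

The reference conditions (50 TUs on 240 kb, ~20 reads per site, ~100
evidence sites) run the full pipeline in a couple of seconds; redundancy
clustering of the resulting ~65 gene sequences is the most expensive stage
because it performs global alignments, and `run_pipeline(cluster = FALSE)`
skips it where only boundaries are studied. The duplication grid used in
validation plants 35 blocks (lengths 300–800 nt, identities 0.90–1.00) in
a 150 kb genome. These sizes were chosen so that the complete validation
suite, including ten jittered replicates and thousand-case oracle
comparisons, completes in a few minutes on one CPU while still exercising
every code path at realistic per-gene scale.

## Known limitations

Boundaries are single-base summits; no uncertainty is attached. Alternative
3' ends are recorded only implicitly (the strongest wins). The antisense
filter uses a single overlap-fraction rule rather than positional models of
sense/antisense structure. The duplication scanner targets desk-scale
genomes; a whole 700 Mb assembly needs a dedicated aligner. Internal
priming at genomic A-runs — a known artifact of poly(A)-site protocols —
is not modelled or filtered.
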