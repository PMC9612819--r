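---
title: "Targeted k-mer screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted k-mer screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerscreen)
```

## The screening model

kmerscreen answers a narrow question quickly: *is a specific, already-known
alteration present in this RNA-seq sample?* Rather than aligning reads, it
reduces the sample to a k-mer count table and interrogates that table with
short curated target sequences, one per alteration. This trades discovery
power for speed and specificity: nothing outside the target catalog can be
found, but within the catalog an exact-match criterion makes false
positives rare and the evidence statistic transparent.

Two detection modes share the count table:

**Presence mode** (fusion junctions, deletion-isoform junctions,
IG-rearrangement candidates, expression windows). A target is present iff
every one of its `L - k + 1` windows has a non-zero count. The *minimum
k-mer coverage* over the windows is the evidence statistic: because any
single read spanning the whole target contributes to every window, it
behaves like "number of reads spanning the weakest point". The flip side is
a known failure mode, reproduced in the test suite: a patient polymorphism
inside the first or final window breaks an anchor that no divergent path
can route around, yielding a false negative. The catalog builder therefore
supports emitting alternate targets carrying common population SNPs
(allele frequency > 0.01).

**Path mode** (SNV/indel targets). The target's first and last windows
anchor a walk through the implicit de Bruijn graph of the count table:
successors of a window are the up-to-four words obtained by appending one
base to its (k−1)-suffix, admitted when their count reaches `min_count`.
The walk follows the target's own window sequence and opens a branch
wherever an off-target successor exists or the target's next window is
absent; a branch completes when it re-enters a target window downstream of
its divergence point (with the remaining target walkable to the end).
Completed branches are spelled out, deduplicated by sequence, aligned back
to the target and classified as Substitution, Insertion, Deletion or
MultiVariant. Each path carries its own minimum window count, and

\[ \text{ratio} = \frac{\min \text{cov(alt path)}}{\min \text{cov(alt path)} + \min \text{cov(reference path)}} \]

approximates the variant allele fraction. This holds only when reads span
the entire target, so that the allele-specific windows of each path see the
full depth of their allele: the 62–72 b targets guarantee it for reads of
75 b and longer. For shorter reads, or for targets embedded at the end of a
transcript where terminal windows see reduced depth, the ratio compresses
toward 0.5 — a documented limitation, and the reason the calibration test
embeds its target inside a longer transcript.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 31 | bases | word length of the index; long enough that random 31-mers essentially never collide with targets, short enough that a 62 b junction target still has 32 windows |
| `canonical` | `TRUE` | — | collapse each word with its reverse complement so detection is independent of library strandedness |
| `min_count` | 1 | count | graph admission threshold; kept at 1 so raw sensitivity is maximal and *all* clinical thresholds live in one place, the filter policy |
| `max_extra_length` | 60 | bases | longest excess of an assembled path over its target; bounds insertions (and pathological walks on repetitive targets) |
| `max_branches` | 1000 | branches | global exploration budget per target; exhaustion sets a truncation flag rather than erroring |
| `max_cycle` | 2 | visits | a branch may revisit one word at most twice, bounding walks through short repeats |
| `dux4_min_targets` / `dux4_min_cov` | 4 / 10 | windows / count | an expression call needs at least 4 tiled windows at minimum coverage 10; separates genuine expression (many windows, high coverage) from spurious assembly of one or two windows at minimal coverage |
| `deletion_min_cov` | 10 | count | junctions below this likely reflect low-level aberrant splicing rather than a clonal deletion |
| `variant_min_support` | 5 | count | "five reads spanning the target carrying the alternate allele", expressed as minimum coverage of the variant path — the two coincide when reads span the target |
| `fusion_low_conf_cov` | 5 | count | presence below this is retained but flagged; the regime where read-through and cis-splicing chimeras are known to occur |
| `snp_af_threshold` / `benign_af_threshold` | 0.01 | frequency | population-SNP alternates are built, and detected variants flagged likely-benign, strictly above this allele frequency |
| `homopolymer_flag_len` | 5 | bases | indels extending a homopolymer run of this length are flagged as possible sequencing artifacts; the length is a package choice, exposed in the policy |

Every exclusion rule is phrased "less than", so thresholds keep the
boundary value: a deletion junction at coverage exactly 10 is reported, 4
expression windows at exactly 10 suffice, a variant path at exactly 5 is
kept.

## Target construction rules

* **Fusion**: last 31 transcript-sense bases of the donor exon + first 31
  of the acceptor exon; 62 b, junction at offset 31. The reciprocal fusion
  is a separate target built by the swapped invocation.
* **SNV/indel**: the targeted codon(s) plus 33 coding bases on each side,
  taken from the spliced CDS so flanks cross introns when needed; 69 b for
  one codon, 72 b for two. The target is in frame (frame offset 0, codon
  anchor at offset 33), which is what makes `p.` annotation possible
  directly from target coordinates.
* **Intragenic deletion**: last 31 b of the exon before the deleted range +
  first 31 b of the exon after it. Ranges touching the first or last exon
  are rejected: such transcripts have no junction observable in RNA.
* **Expression markers**: the first 700 b of the marker transcript minus
  excluded intervals (defaults to 141–210, a region homologous to multiple
  genomic loci), tiled left-to-right with non-overlapping 70 b windows;
  residues shorter than a window are discarded, and identical windows from
  homologous source transcripts are deduplicated by sequence. Tiling is
  anchored at the left edge of each kept interval; the phase is otherwise
  arbitrary and this choice is fixed for determinism.
* **IG rearrangement**: 50 b immediately 5′ of the partner breakpoint +
  each IG allele in full. Keeping the allele untrimmed is a defined
  behaviour of this package; published target sets appear to have trimmed
  or windowed alleles in a way that is not reconstructible from their
  description, so lengths here are `50 + allele length` exactly.

All internal coordinates are 0-based half-open; the GTF convention
(1-based inclusive) is converted at import and nowhere else.

## Numerical and algorithmic choices

* **Classification alignment.** Paths are classified by unit-cost global
  alignment after stripping the longest common prefix and suffix. A single
  local difference therefore reduces to a trivial comparison, and the
  remaining alignment is deterministic: traceback prefers continuing a gap
  (fewest gap openings), then the diagonal, and indels are subsequently
  left-normalized to their smallest equivalent position — the same
  convention as VCF normalization, and the one the test oracle checks by
  enumerating equivalent placements.
* **MultiVariant.** Two or more separated difference runs, or one run that
  both consumes and adds bases of different lengths, are reported as
  MultiVariant rather than forced into a single shape.
* **Degenerate inputs.** Empty read streams give an empty table (not an
  error); `k` exceeding every read length gives an empty table with a
  warning; targets shorter than `k` are a hard error (unusable target);
  non-ACGT symbols invalidate only the windows containing them, not the
  whole read. Counting raw reads without quality filtering is intentional:
  the index is built from raw FASTQ.
* **Determinism.** Path results are ordered Reference-first then by
  sequence; written target FASTAs sort by id; reports sort by class, gene,
  id; all simulation is seeded with a private RNG stream that neither
  perturbs nor depends on the caller's RNG state. Re-running any stage is
  byte-identical.

## What the simulator does and does not emulate

`simulate_reads()` draws reads from a transcript mixture proportional to
abundance, with uniform start positions, independent per-base substitution
errors, and optional proper pairs (mate 2 reverse-complemented from the
fragment end). Together with `make_toy_genome()` and `mutate_transcript()`
it produces every read structure the caller must detect: exon–exon fusion
junctions, point variants at a chosen allele fraction, exon-skip deletion
isoforms, and a high- or zero-expression marker.

It deliberately does **not** model coverage bias (GC, positional,
fragmentation), indel sequencing errors, quality-score structure, or
genome-scale background transcription. Passing tests on simulated data
therefore demonstrate the correctness of the counting, assembly,
classification and filtering machinery under the stated read model — not
detection rates on real patient libraries, where coverage unevenness and
lowly expressed genes dominate sensitivity.

## Problem sizes used by the test suite

The suite generates all fixtures in code: toy genomes of five genes,
targets of 62–100 b, and read sets of a few hundred to 4,000 reads of 75 b.
Oracle-equivalence checks run on 2,200-read inputs against an independent
brute-force dictionary; planted-variant recovery runs 200 randomized trials
(substitutions, insertions ≤ 10 b, deletions ≤ 30 b, all at least k from
the target ends); ratio calibration uses 1,200 simulated reads per allele
fraction and a ±0.15 tolerance; the end-to-end check screens a
four-alteration sample at 4,000 reads and expects exactly four report rows.
These sizes were chosen so each property is tested well inside binomial
noise margins while the whole suite stays fast.

## Known limitations

* Whole-gene deletions and deletions removing exon 1 silence the allele
  entirely and leave no junction in RNA; they are undetectable by design
  and out of scope.
* Variants breaking a target's first or final window are invisible unless
  an alternate target carrying the interfering polymorphism is included in
  the catalog.
* The coverage-ratio VAF proxy is only calibrated when reads span the whole
  target (see above).
* Sensitivity for lowly expressed genes is bounded by the
  `variant_min_support` threshold; screening is not a substitute for
  alignment-based small-variant calling when expression is low.
* Branch budgets can truncate exploration on highly repetitive targets; the
  result then carries a truncation flag rather than silently missing paths.
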