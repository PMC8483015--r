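---
title: "Assembling and annotating fosmid inserts: methods and design"
author: "fosmidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and annotating fosmid inserts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Activity-based (functional) metagenomics screens libraries of large
environmental DNA fragments — typically 35–40 kb inserts cloned into a
fosmid such as pCC1FOS and maintained circularly in an *E. coli* host — for
clones expressing an activity of interest. Hit clones are sequenced, and the
computational task is to turn each clone's reads into one clean contig of
the *insert*: the cloning vector is present in every clone, and because the
molecule is circular, a linear assembly can start anywhere on the circle,
with the vector landing at an extremity or in the middle of the contig.

`fosmidr` implements that workflow as a tested toolkit: read counting,
filtering and coverage-targeted subsampling; assembly (a built-in de Bruijn
graph assembler for offline, reproducible testing, plus an adapter for an
external production assembler); vector detection, masking and removal with
circularity-aware contig re-organization; ORF calling with GFF3/protein
output; and alignment-based precision/recall evaluation against simulated
truth. A simulator generates constructs and reads with a machine-readable
truth manifest so that every stage can be scored exactly.

## Simulation model

A construct is built from a genomic *chunk* (default 40,000 bp, drawn
uniformly over valid start positions of a source genome; chunks may overlap)
and the vector sequence:

* `extremity_left` / `extremity_right`: `full = vector + chunk` or
  `chunk + vector`.
* `internal` at position `p` (0 < p < chunk length):
  `linear = chunk[0:p] + vector + chunk[p:]`, then a copy of the first
  `overlap_len` bases (default 500 bp) of `linear` is appended to its end.
  The duplication mimics circularity: reads can span the junction between
  the "end" and the "start" of the circle. Which end carries the duplicate
  is not observable downstream; duplicating the start at the end makes the
  join detection symmetric and is recorded in the truth manifest.

Reads are drawn uniformly: single-end reads of `read_len` (default 150 bp),
or paired-end fragments with Normal(`fragment_mean` = 200, `fragment_sd` =
10) lengths clamped to `[read_len, construct length]`; mate 2 is the reverse
complement of the fragment end and fragment strand is sampled so both
orientations occur. The read count `n` always satisfies
`n * read_len >= coverage * construct_length`. Errors are substitution-only
at a configurable per-base rate with fixed (Q37) quality strings.

What this emulates and what it does not: the simulator reproduces the
geometry of a simulated fosmid study (insert size, vector placement,
circularity overlap, read length, fragment distribution, coverage), but not
platform-specific error spectra (position-dependent quality, indels,
PCR duplicates, chimeras). Tests passing on these reads demonstrate the
pipeline's logic — vector geometry, circular re-organization, metric
definitions — not robustness to every artefact of real instruments; the
external-assembler adapter exists precisely because a production assembler
is the right tool for real data.

## Read preparation

Coverage is estimated as summed read length (both mates counted) over the
*expected* insert length, which defaults to the nominal 40 kb fosmid insert
rather than the unknown true construct length — the same convention is used
for the subsampling target, so the two cancel in practice. Quality
filtering removes reads with mean phred < 20, N fraction > 0.1 or length
< 50 bp (invented but conventional defaults; all configurable), and drops
the whole pair when either mate fails so pairing never breaks. Subsampling
to the target coverage (default 300X) samples units — pairs stay together —
uniformly without replacement until the summed length reaches
`target * expected_len`, preserving input order, and is a no-op when the
set is already at or below the target.

## The built-in assembler

A deliberately minimal de Bruijn graph assembler over canonical k-mers
(lexicographic minimum of k-mer and reverse complement; odd `k`, default 31,
2-bit packed so `k <= 63`):

* k-mers with abundance below `min_count` are dropped;
* dead-end tips shorter than `2k` are removed iteratively;
* unbranched paths are compacted into contigs; at any branch, extension
  simply stops — no greedy tie-break, favouring correctness over
  contiguity. There is no bubble popping, scaffolding or repeat resolution.
* contig coverage is the mean k-mer abundance along the path, and the
  traversal order is fixed (sorted k-mers), so identical input yields
  byte-identical output.

Two consequences matter downstream. First, `min_count` does the error
handling: at the pipeline's post-subsampling coverage (~240X k-mer depth), a
recurrent sequencing error at a given position is expected in well under one
read per alternative base, so the default `min_count = 10` removes
essentially every error k-mer while true k-mers (depth ≈ 170–240) are never
at risk; error substructures that do survive as short dead ends are caught
by tip removal. At much lower coverage a smaller `min_count` is needed —
the parameter is exposed everywhere.

Second, an internal-mode construct reads as a *circle*: the 500 bp terminal
duplication closes the k-mer graph into a single cycle. The assembler opens
a cycle at a deterministic k-mer and emits it with a `k-1` bp terminal
duplication (the natural unitig representation of a circle). The circular
join after vector removal therefore re-finds a `k-1` bp overlap rather than
the original 500 bp copy — the recovered contig is still an exact rotation
of the source chunk, which is what the round-trip tests assert.

## Vector detection and removal

Detection is seed–chain–extend local alignment of the vector against each
contig, both strands: exact 15-mer seeds, co-linear chains grouped by
diagonal (tolerance 75 bp, merging hits on the same diagonal), and a banded
affine dynamic program over each chain's window (match +1, mismatch −2,
gap −3 per base). Problems small enough for a full local DP skip the
heuristic entirely, which is also how the implementation is pinned to a
full Smith–Waterman oracle in the tests. Matches require identity ≥ 0.9
over ≥ 50 aligned bases by default. Masking replaces the interval union
with `X` and is purely presentational — excision works from coordinates, and
a test asserts that masking before re-organization changes nothing.

Re-organization distinguishes, per contig:

* no match — contig passes through;
* a terminal match (within `end_slack = 10` bp of a contig end, a tolerance
  required by ragged assembly ends) — the vector span, extended through the
  residual slack bases, is trimmed off;
* an internal match — the contig splits into `left`/`right` flanks; if a
  suffix of `right` aligns to a prefix of `left` (exact fast path, then an
  overlap-mode DP; ≥ 20 bp at identity ≥ 0.95 by default) the flanks are
  joined with one copy of the overlap — the circular clone restored — else
  both flanks are returned (`split_two`);
* a match wrapped across *both* extremities (the assembler opened the
  circle inside the vector) — recognized as a single occurrence and trimmed
  at both ends;
* two or more genuinely disjoint occurrences (chimeric assembly) — all
  spans are excised, no join is attempted, and the contig is flagged
  (`multi_excised`). This conservative fifth outcome is ours: the source
  workflow does not define the case.

Join thresholds are deliberate choices where the underlying workflow never
quantifies "overlap": 20 bp at 0.95 identity accepts both the assembler's
`k−1` duplication and a 500 bp overlap carrying sequencing differences,
while a random 20-mer coincidence at both break ends is vanishingly
unlikely. Keeping exactly one copy of the overlap makes recovered lengths
match the source chunk.

Contig filtering retains contigs strictly longer than 1000 bp with mean
coverage strictly above 8 ("longer than"/"above" read as strict
inequalities; both parameters configurable). Contigs with unknown coverage
(plain FASTA headers from an external assembler) are retained with a
warning rather than silently dropped.

## ORF calling and annotation output

The built-in caller scans all six frames for ATG/GTG/TTG → stop ORFs under
NCBI genetic code 11, keeps those with ≥ `min_aa_len` codons (default 100),
and resolves overlapping same-frame ORFs sharing a stop to the longest
(earliest start). Nested ORFs on opposite strands are both reported.
Coordinates are 0-based half-open internally and 1-based inclusive in GFF3;
the phase column is 0 (complete CDS), and the strand-local frame is
recoverable from the coordinates. Attribute values are percent-encoded per
the GFF3 reserved-character rules. Translations keep the raw start-codon
amino acid (no methionine forcing), exclude the stop, and are emitted as
protein FASTA. External homology results (a tab-separated hit table) can be
attached as GFF attributes; homology search itself is out of scope. The
caller is a testable stand-in, not a prokka replacement: an external
gene-caller adapter is the production path, and no ribosome-binding-site or
start-refinement model is attempted.

## Evaluation metrics

Assembly metrics align each contig to the reference (both strands,
seed-chain-extend, affine scoring match +1 / mismatch −2 / open −4 /
extend −1) and count identically matching bases, the in-R equivalent of
mapping contigs and counting matches in a pileup. Two rules keep the counts
honest: secondary alignments reusing more than half of an already-aligned
contig region are discarded (so a repeat collapsed once in the contig
credits only one reference copy), and matched reference positions are
credited once via interval union, which also makes the aggregate
order-independent. Then per contig and in aggregate:

* precision = matched bases / contig length,
* recall = matched bases / reference length.

The reference is the vector-free insert, matching what the pipeline
outputs; the truth manifest records the full construct as well so either
can be selected.

Annotation metrics call a detected CDS a true positive when its nucleotide
sequence aligns to a reference CDS covering that reference from its start
to its end (strictly full-length, identity ≥ 0.95; each reference consumed
at most once, assigned greedily by identity). The default ratios follow the
source convention of this pipeline family — precision = TP / reference CDS
count, recall = TP / detected CDS count — which is *swapped* relative to
the usual definitions. We implement the formulas as printed rather than
guessing intent, and provide `conventional = TRUE` to swap them back.

## Numerical and design choices

| parameter | default | unit | rationale |
|---|---|---|---|
| `expected_len` | 40000 | bp | nominal fosmid insert; coverage denominator |
| `coverage` (subsample) | 300 | X | diminishing assembly returns above it |
| `k` | 31 | bp | no repeats ≥ 31 expected at fosmid scale |
| `min_count` | 10 | k-mers | error-kmer floor at ~240X k-mer depth |
| `min_identity` (vector) | 0.9 | — | tolerant of diverged vector copies |
| `min_match_len` | 50 | bp | below it, chance local hits appear |
| `min_contig_len` / `min_contig_cov` | 1000 / 8 | bp / X | strict, per the workflow's filter |
| `min_join_overlap` / `min_join_identity` | 20 / 0.95 | bp / — | accepts k−1 and 500 bp joins, rejects chance |
| `end_slack` | 10 | bp | ragged-end tolerance for "terminal" |
| `min_aa_len` | 100 | codons | conventional ORF floor for real contigs |

Degenerate inputs are handled explicitly: empty read sets error at
assembly but merely warn (coverage 0) at estimation; an all-filtered sample
is recorded as failed without stopping a batch; empty contig sets or CDS
sets yield zero metrics with a flag rather than NaN; contigs shorter than
the seed length return an empty match list.

## The round-trip study

`round_trip_study()` is the package's evaluation harness and the
computation behind `scripts/acceptance.R`: three synthetic 200 kb genomes,
twenty 40 kb constructs with an 8.1 kb synthetic vector (random mode mixes
extremity and internal placements), paired 150 bp reads at 300X, alternating
error-free and 0.5%-substitution sets, full pipeline, exact scoring against
truth. These sizes are desk-scale choices: large enough that insert,
vector and overlap geometry are at realistic scale, small enough to run
routinely. The annotation comparison inside the study lowers the ORF floor
to 30 codons because uniform random sequence rarely contains 100-codon
ORFs; with the floor at 30 a 40 kb insert yields a few hundred reference
ORFs, enough for the ratio formulas to be exercised meaningfully.

```{r study}
library(fosmidr)
res <- round_trip_study(n_constructs = 20, seed = 1)
dplyr::count(res, mode, n_final)
summary(res[, c("precision", "recall")])
```

## Known limitations

* The built-in assembler targets single-fosmid, high-coverage, low-error
  read sets; it will fragment on long repeats, true polymorphism or low
  coverage, by design. Use the external adapter for production assembly.
* Vector detection assumes the supplied vector sequence is the clone's
  backbone; partially deleted or rearranged vectors yield multiple matches
  and the conservative `multi_excised` path.
* The ORF caller has no gene model beyond start/stop codons; its
  sensitivity/specificity are not comparable to a trained gene finder.
* The strict full-length rule for annotation true positives means a single
  terminal mismatch on the reference demotes a detection; this matches the
  stated definition but is unforgiving on noisy contigs.
* Adapter trimming is delegated to an external-tool hook; only quality/N
  filtering is native.
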