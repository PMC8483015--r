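# fosmidr

Assembly and annotation of fosmid inserts from activity-based (functional)
metagenomics, in R.

Functional metagenomics screens libraries of ~35–40 kb environmental DNA
fragments cloned into a fosmid (e.g. pCC1FOS) for clones expressing an
activity of interest, then sequences the hit clones. The clone is a
*circular* molecule of insert + cloning vector, so turning its reads into a
clean insert sequence needs more than an assembler: the vector must be
located and excised, and because a linear contig can open the circle
anywhere, the vector may sit at a contig extremity or internally — in which
case the two flanks must be re-joined (when their extremities overlap) or
split, to restore the geometry of the clone.

`fosmidr` implements that workflow end to end:

* **simulate** — fosmid constructs with known truth (chunk + vector at an
  extremity or internal with a 500 bp circularity overlap) and
  paired/single reads with a substitution error model;
* **readprep** — read counting, coverage estimation (bases / expected
  insert length), quality/N filtering with pair integrity, and seeded
  subsampling to a target coverage (300X by default);
* **assembly** — a deterministic built-in de Bruijn assembler over
  canonical k-mers (abundance filter `min_count`, tip removal, unitig
  compaction; circular components open with a k−1 bp terminal duplication),
  plus an adapter for an external production assembler;
* **vectorops** — seed–chain–extend local alignment of the vector against
  contigs (match +1 / mismatch −2 / gap −3), X-masking, strict contig
  filtering (length > 1000 bp and coverage > 8X), and circularity-aware
  removal: trim terminal hits, join internal flanks over a detected
  terminal overlap, or split;
* **annotate** — six-frame ORF calling (ATG/GTG/TTG → stop, genetic code
  11), GFF3 + protein FASTA output, optional external homology hits;
* **evaluate** — alignment-based metrics with reference bases credited
  once:
  assembly precision = matched bases / contig length and
  recall = matched bases / reference length; annotation
  precision = TP / reference CDS and recall = TP / detected CDS (the
  source convention of this pipeline family — note the swap; a
  `conventional` switch restores the usual definitions). A detected CDS is
  a TP when it aligns full-length over its reference at identity ≥ 0.95.

Everything user-facing takes and returns tibbles, chains with the pipe, and
has `tidy()`/`glance()`/`autoplot()` methods where a fitted-object summary
makes sense.

## Worked example

Simulate one internal-mode construct, assemble, remove the vector, and
score against truth:

```r
library(fosmidr)

genome <- random_genome(50000, "demo_genome", seed = 11)
vector <- random_genome(1500, "demo_vector", seed = 22)

chunk <- extract_chunks(genome, n_chunks = 1, chunk_len = 8000, seed = 3)
construct <- build_construct(chunk, vector$seq, mode = "internal",
                             overlap_len = 500, seed = 4)
construct
#> <fosmid_construct> demo_genome_chunk01
#>   mode: internal @ 5624
#>   insert 8000 bp + vector 1500 bp + 500 bp overlap = 10000 bp
#>   vector at [5624, 7124)

reads <- simulate_reads(construct,
                        read_profile("paired", coverage = 200,
                                     subst_error_rate = 0.005, seed = 5))
reads <- subsample_reads(reads, target_cov = 150, expected_len = 8000, seed = 6)

contigs <- assemble_reads(reads, k = 31, min_count = 8)
contigs[, c("contig_id", "length", "mean_cov", "is_cycle")]
#> # A tibble: 1 × 4
#>   contig_id length mean_cov is_cycle
#> 1 contig_1    9530     86.4 TRUE
```

The 10,000 bp construct reads as a circle (its 500 bp terminal duplication
closes the k-mer graph), so the assembler emits one 9,530 bp contig — the
9,500 bp circle opened with a k−1 = 30 bp duplicated end — at ~86X k-mer
coverage. The vector is found (here on the minus strand, full length,
identity 1.0), excised, and the flanks re-joined over the 30 bp overlap:

```r
matches <- detect_vector(contigs, vector$seq)
matches
#> # A tibble: 1 × 8
#>   contig_id start   end strand identity n_match vstart  vend
#> 1 contig_1   1431  2931 -             1    1500      0  1500

cleaned <- reorganize_contigs(contigs, matches)
cleaned$outcomes
#> # A tibble: 1 × 5
#>   contig_id case            join_overlap_len flagged n_out
#> 1 contig_1  joined_circular               30 FALSE       1

metrics <- assembly_metrics(cleaned$contigs, construct$insert_seq)
glance(metrics)
#> # A tibble: 1 × 5
#>   matched_bases total_contig_len reference_len precision recall
#> 1          8000             8000          8000         1      1
```

The recovered contig is exactly 8,000 bp — a rotation of the source chunk —
with every base matching the truth insert: precision and recall are both 1.

For batches, `run_assemble(samples_dir, vector_fasta, out_dir)` executes
the whole pipeline per sample (a failing sample is recorded, not fatal),
writes per-sample and pooled FASTA, vector GFF3, a JSON run manifest and a
self-contained HTML report; `run_annotate()` adds CDS calls with GFF3 and
protein FASTA. A thin command-line wrapper with `simulate`, `assemble`,
`annotate` and `evaluate` subcommands ships in `inst/scripts/fosmidr`. See
the vignette (`vignettes/fosmid-assembly.Rmd`) for the models, parameter
rationale and design decisions.

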