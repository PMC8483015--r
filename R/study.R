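#' Simulated round-trip recovery study
#'
#' The package's end-to-end evaluation harness: synthetic genomes and a
#' synthetic cloning vector are generated, fosmid constructs are built with
#' the vector at an extremity or internal (with a terminal circularity
#' overlap), paired reads are simulated, and each read set is pushed through
#' the assembly pipeline (quality filter, subsample to the target coverage,
#' de Bruijn assembly, vector detection, contig filtering, circularity-aware
#' vector removal). Final contigs are scored against the truth insert with
#' [assembly_metrics()]; internally inserted constructs are additionally
#' checked for rotation equivalence (the joined contig, doubled, must
#' contain the source chunk in either orientation). When `annotate = TRUE`,
#' ORFs called on the recovered contigs are compared to ORFs on the truth
#' insert with [annotation_metrics()].
#'
#' @param n_constructs Number of constructs (default 20).
#' @param n_genomes Number of synthetic source genomes (default 3).
#' @param genome_len Genome length in bp (default 200000).
#' @param chunk_len Insert length in bp (default 40000).
#' @param vector_len Synthetic vector length in bp (default 8100).
#' @param overlap_len Internal-mode terminal overlap (default 500 bp).
#' @param coverage Simulated read coverage in X (default 300; the pipeline
#'   subsamples to its own target afterwards).
#' @param error_rates Per-base substitution error rates cycled over the
#'   constructs (default `c(0, 0.005)`).
#' @param seed Master seed; every random step derives from it.
#' @param config Pipeline [fosmid_config()].
#' @param annotate Also compute annotation precision/recall.
#' @param min_aa_len_annot ORF length floor (codons) used for the annotation
#'   comparison; random sequence holds few long ORFs, so this is lower than
#'   the pipeline's annotation default.
#' @return A tibble, one row per construct: mode, error rate, contig counts,
#'   re-organization case, assembly precision/recall, rotation check, and
#'   (optionally) annotation precision/recall.
#' @export
round_trip_study <- function(n_constructs = 20, n_genomes = 3,
                             genome_len = 200000, chunk_len = 40000,
                             vector_len = 8100, overlap_len = 500,
                             coverage = 300, error_rates = c(0, 0.005),
                             seed = 1, config = fosmid_config(),
                             annotate = TRUE, min_aa_len_annot = 30) {
  seeds <- withr::with_seed(seed, sample.int(2^30, n_genomes + 1 + 4 * n_constructs))
  genomes <- dplyr::bind_rows(lapply(seq_len(n_genomes), function(j) {
    random_genome(genome_len, sprintf("genome%d", j), seed = seeds[j])
  }))
  vec <- random_genome(vector_len, "vector_synthetic",
                       seed = seeds[n_genomes + 1])
  s0 <- n_genomes + 1

  purrr::map_dfr(seq_len(n_constructs), function(i) {
    err <- error_rates[(i - 1) %% length(error_rates) + 1]
    gi <- (i - 1) %% n_genomes + 1
    chunk <- extract_chunks(genomes[gi, ], 1, chunk_len,
                            seed = seeds[s0 + 4 * i - 3])
    chunk$chunk_id <- sprintf("fosmid%02d", i)
    cs <- build_construct(chunk, vec$seq, mode = "random",
                          overlap_len = overlap_len,
                          seed = seeds[s0 + 4 * i - 2])
    prof <- read_profile("paired", coverage = coverage,
                         subst_error_rate = err,
                         seed = seeds[s0 + 4 * i - 1])
    reads <- simulate_reads(cs, prof)
    reads <- filter_reads(reads, config$min_mean_q, config$max_n_frac,
                          config$min_read_len)
    reads <- subsample_reads(reads, config$coverage, config$expected_len,
                             seed = seeds[s0 + 4 * i])
    contigs <- assemble_reads(reads, k = config$k,
                              min_count = config$min_count)
    matches <- detect_vector(contigs, vec$seq,
                             min_identity = config$min_identity,
                             min_match_len = config$min_match_len)
    kept <- filter_contigs(contigs, config$min_contig_len,
                           config$min_contig_cov)
    reorg <- reorganize_contigs(kept, matches,
                                min_join_overlap = config$min_join_overlap,
                                min_join_identity = config$min_join_identity,
                                end_slack = config$end_slack)
    final <- reorg$contigs
    am <- assembly_metrics(final, cs$insert_seq)

    rotation_ok <- NA
    if (cs$insertion_mode == "internal" && nrow(final) == 1) {
      dbl <- paste0(final$seq[1], final$seq[1])
      rotation_ok <- grepl(cs$insert_seq, dbl, fixed = TRUE) ||
        grepl(revcomp(cs$insert_seq), dbl, fixed = TRUE)
    }

    ann_p <- NA_real_; ann_r <- NA_real_
    if (annotate && nrow(final) > 0) {
      ref_ct <- contig_tbl(tibble(contig_id = "truth_insert",
                                  seq = cs$insert_seq,
                                  length = nchar(cs$insert_seq),
                                  mean_cov = NaN, is_cycle = FALSE))
      ref_cds <- cds_sequences(ref_ct, find_orfs(ref_ct, min_aa_len_annot))
      det_cds <- cds_sequences(final, find_orfs(final, min_aa_len_annot))
      if (nrow(ref_cds) > 0 && nrow(det_cds) > 0) {
        anm <- annotation_metrics(det_cds, ref_cds)
        ann_p <- anm$precision; ann_r <- anm$recall
      }
    }

    tibble(
      construct_id = cs$construct_id, mode = cs$insertion_mode,
      error_rate = err, contigs_raw = nrow(contigs),
      n_final = nrow(final),
      case = paste(reorg$outcomes$case, collapse = ","),
      precision = am$aggregate$precision, recall = am$aggregate$recall,
      rotation_ok = rotation_ok,
      ann_precision = ann_p, ann_recall = ann_r
    )
  })
}
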