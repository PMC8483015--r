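test_that("an exact embedded vector is located base-perfectly", {
  vec <- rnd_dna(900, seed = 300)
  flank1 <- rnd_dna(2000, seed = 301)
  flank2 <- rnd_dna(7100, seed = 302)
  contig <- as_contigs(paste0(flank1, vec, flank2))
  mm <- detect_vector(contig, vec)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$start, 2000)
  expect_equal(mm$end, 2900)
  expect_equal(mm$strand, "+")
  expect_equal(mm$identity, 1)
  expect_equal(c(mm$vstart, mm$vend), c(0, 900))
})

test_that("a reverse-complement vector copy matches the DP oracle coordinates", {
  vec <- rnd_dna(600, seed = 310)
  contig_seq <- paste0(rnd_dna(700, seed = 311),
                       revcomp(mutate_bases(vec, 6, seed = 312)),
                       rnd_dna(600, seed = 313))
  mm <- detect_vector(as_contigs(contig_seq), vec)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$strand, "-")
  ora <- oracle_local(revcomp(vec), contig_seq)
  expect_equal(mm$start, ora$t_start)
  expect_equal(mm$end, ora$t_end)
  expect_equal(mm$n_match, ora$n_match)
})

test_that("random sequence yields no vector matches", {
  mm <- detect_vector(as_contigs(rnd_dna(3000, seed = 320)),
                      rnd_dna(800, seed = 321))
  expect_equal(nrow(mm), 0)
})

test_that("masking replaces exactly the interval union with X", {
  contig <- as_contigs(rnd_dna(100, seed = 330))
  m1 <- tibble::tibble(contig_id = "contig_1", start = 10, end = 20,
                       strand = "+", identity = 1, n_match = 10,
                       vstart = 0, vend = 10)
  out <- mask_vector(contig, m1)
  expect_equal(nchar(out$seq), 100)
  expect_equal(stringr::str_count(out$seq, "X"), 10)
  expect_equal(substring(out$seq, 11, 20), strrep("X", 10))
  expect_equal(substring(out$seq, 1, 10), substring(contig$seq, 1, 10))

  # overlapping intervals: oracle is a per-position marking loop
  m2 <- dplyr::bind_rows(m1, dplyr::mutate(m1, start = 15, end = 30))
  out2 <- mask_vector(contig, m2)
  marked <- rep(FALSE, 100)
  for (i in seq_len(nrow(m2))) marked[(m2$start[i] + 1):m2$end[i]] <- TRUE
  expect_equal(which(strsplit(out2$seq, "")[[1]] == "X"), which(marked))
  expect_equal(sum(marked), 20)

  # no matches: identity
  expect_identical(mask_vector(contig, m1[0, ]), contig)
})

test_that("contig filtering uses strict length and coverage inequalities", {
  ct <- as_contigs(c(strrep("A", 1000), strrep("C", 1001), strrep("G", 1001),
                     strrep("T", 5000)),
                   cov = c(50, 8.0, 8.01, 150))
  kept <- filter_contigs(ct, min_len = 1000, min_cov = 8)
  expect_equal(kept$contig_id, c("contig_3", "contig_4"))
  nan_ct <- as_contigs(strrep("A", 2000), cov = NaN)
  expect_warning(kept2 <- filter_contigs(nan_ct), "coverage")
  expect_equal(nrow(kept2), 1)
})

test_that("terminal overlap detection finds exact and mismatched overlaps", {
  core <- rnd_dna(1500, seed = 340)
  ov <- substring(core, 1, 500)
  right <- paste0(rnd_dna(800, seed = 341), ov)
  expect_equal(detect_terminal_overlap(right, core, min_len = 20), 500L)

  right2 <- paste0(rnd_dna(800, seed = 342), mutate_bases(ov, 2, seed = 343))
  expect_equal(detect_terminal_overlap(right2, core, min_len = 20,
                                       min_identity = 0.98), 500L)

  expect_true(is.na(detect_terminal_overlap(rnd_dna(600, seed = 344),
                                            rnd_dna(600, seed = 345))))
})

test_that("re-organization covers trim, join, split and wrap-around cases", {
  vec <- rnd_dna(700, seed = 350)
  chunk <- rnd_dna(3000, seed = 351)

  # vector occupying the contig start: trim
  c1 <- as_contigs(paste0(vec, chunk))
  m1 <- detect_vector(c1, vec)
  r1 <- reorganize_contig(c1, m1)
  expect_equal(r1$case, "trimmed_extremity")
  expect_equal(r1$contigs$seq, chunk)

  # internal vector with a 30 bp circular join
  left <- substring(chunk, 1, 1200)
  right <- paste0(substring(chunk, 1201, 3000), substring(left, 1, 30))
  c2 <- as_contigs(paste0(left, vec, right))
  m2 <- detect_vector(c2, vec)
  r2 <- reorganize_contig(c2, m2)
  expect_equal(r2$case, "joined_circular")
  expect_equal(r2$join_overlap_len, 30L)
  joined <- r2$contigs$seq
  expect_equal(nchar(joined), 3000)
  expect_true(grepl(chunk, paste0(joined, joined), fixed = TRUE))

  # internal vector, unrelated flanks: split in two
  fl <- rnd_dna(1500, seed = 352); fr <- rnd_dna(1500, seed = 353)
  c3 <- as_contigs(paste0(fl, vec, fr))
  m3 <- detect_vector(c3, vec)
  r3 <- reorganize_contig(c3, m3)
  expect_equal(r3$case, "split_two")
  expect_equal(nrow(r3$contigs), 2)
  expect_equal(r3$contigs$seq, c(fl, fr))

  # occurrence wrapped across both extremities of an opened circle
  c4 <- as_contigs(paste0(substring(vec, 301, 700), fl,
                          substring(vec, 1, 300)))
  m4 <- detect_vector(c4, vec)
  r4 <- reorganize_contig(c4, m4)
  expect_equal(r4$case, "trimmed_extremity")
  expect_equal(r4$contigs$seq, fl)

  # two genuinely disjoint internal occurrences: conservative excision
  c5 <- as_contigs(paste0(fl, vec, fr, vec, rnd_dna(1200, seed = 354)))
  m5 <- detect_vector(c5, vec)
  r5 <- reorganize_contig(c5, m5)
  expect_equal(r5$case, "multi_excised")
  expect_true(r5$flagged)
  expect_equal(nrow(r5$contigs), 3)
})

test_that("sequence is conserved and outputs are X-free in every outcome", {
  vec <- rnd_dna(500, seed = 360)
  for (i in 1:6) {
    fl <- rnd_dna(1400, seed = 360 + 2 * i)
    fr <- rnd_dna(1400, seed = 361 + 2 * i)
    contig <- as_contigs(paste0(fl, vec, fr))
    mm <- detect_vector(contig, vec)
    r <- reorganize_contig(contig, mm)
    expect_equal(paste(r$contigs$seq, collapse = ""), paste0(fl, fr))
    expect_false(any(grepl("X", r$contigs$seq, fixed = TRUE)))
  }
})

test_that("masking before re-organization changes nothing (coordinates drive excision)", {
  vec <- rnd_dna(600, seed = 370)
  contig <- as_contigs(paste0(rnd_dna(1300, seed = 371), vec,
                              rnd_dna(1300, seed = 372)))
  mm <- detect_vector(contig, vec)
  direct <- reorganize_contig(contig, mm)
  masked <- mask_vector(contig, mm)
  via_mask <- reorganize_contig(masked, mm)
  expect_equal(via_mask$case, direct$case)
  expect_equal(via_mask$contigs$seq, direct$contigs$seq)
})

test_that("simulated internal constructs round-trip to a rotation of the chunk", {
  vec <- rnd_dna(1200, seed = 380)
  for (s in 1:20) {
    chunk <- rnd_dna(5000, seed = 400 + s)
    cs <- build_construct(chunk, vec, mode = "internal", overlap_len = 500,
                          seed = 420 + s)
    rds <- simulate_reads(cs, read_profile("paired", coverage = 150,
                                           subst_error_rate = 0,
                                           seed = 440 + s))
    ct <- assemble_reads(rds, k = 31, min_count = 5)
    mm <- detect_vector(ct, vec)
    r <- reorganize_contigs(ct, mm)
    expect_equal(nrow(r$contigs), 1)
    dbl <- paste0(r$contigs$seq[1], r$contigs$seq[1])
    expect_true(grepl(chunk, dbl, fixed = TRUE) ||
                  grepl(revcomp(chunk), dbl, fixed = TRUE))
    expect_equal(nchar(r$contigs$seq[1]), 5000)
  }
})
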