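test_that("construct length identities hold across modes, positions and overlaps", {
  chunk <- rnd_dna(600, seed = 1)
  vec <- rnd_dna(200, seed = 2)

  cs <- build_construct(chunk, vec, mode = "extremity_left")
  expect_equal(cs$full_seq, paste0(vec, chunk))
  expect_equal(cs$vector_interval, c(0L, 200L))
  expect_equal(nchar(cs$full_seq), 600 + 200)

  cs <- build_construct(chunk, vec, mode = "extremity_right")
  expect_equal(cs$full_seq, paste0(chunk, vec))
  expect_equal(cs$vector_interval, c(600L, 800L))

  for (p in c(1L, 300L, 599L)) {
    for (ov in c(0L, 1L, 500L)) {
      cs <- build_construct(chunk, vec, mode = "internal",
                            insertion_pos = p, overlap_len = ov)
      expect_equal(nchar(cs$full_seq), 600 + 200 + ov)
      if (ov > 0) {
        expect_equal(substring(cs$full_seq, nchar(cs$full_seq) - ov + 1),
                     substring(cs$full_seq, 1, ov))
      }
      expect_equal(cs$insert_seq, chunk)
      expect_equal(substring(cs$full_seq, p + 1, p + 200), vec)
    }
  }
})

test_that("trivial concatenation example gives the documented construct", {
  cs <- build_construct("ACGTACGT", "TT", mode = "extremity_left",
                        overlap_len = 0)
  expect_equal(cs$full_seq, "TTACGTACGT")
  expect_equal(cs$vector_interval, c(0L, 2L))
})

test_that("internal insertion at the chunk boundary is rejected", {
  chunk <- rnd_dna(100, seed = 3)
  expect_error(build_construct(chunk, "ACGT", mode = "internal",
                               insertion_pos = 0, overlap_len = 50),
               "extremity")
  expect_error(build_construct(chunk, "ACGT", mode = "internal",
                               insertion_pos = 100, overlap_len = 50),
               "extremity")
})

test_that("constructs are byte-identical across repeated seeded calls", {
  chunk <- rnd_dna(2000, seed = 4)
  vec <- rnd_dna(300, seed = 5)
  a <- build_construct(chunk, vec, mode = "random", seed = 99)
  b <- build_construct(chunk, vec, mode = "random", seed = 99)
  expect_identical(a, b)
})

test_that("chunk extraction respects lengths, coordinates and determinism", {
  g <- random_genome(2089645, "bifido_like", seed = 10)
  ch <- extract_chunks(g, 15, 40000, seed = 7)
  expect_equal(nrow(ch), 15)
  expect_true(all(nchar(ch$seq) == 40000))
  expect_true(all(ch$start >= 0 & ch$end <= 2089645))
  expect_equal(ch$end - ch$start, rep(40000L, 15))
  # coordinates really address the genome
  expect_equal(substring(g$seq, ch$start[3] + 1, ch$end[3]), ch$seq[3])
  expect_identical(ch, extract_chunks(g, 15, 40000, seed = 7))

  g1 <- random_genome(40000, "tiny", seed = 11)
  one <- extract_chunks(g1, 1, 40000, seed = 1)
  expect_equal(one$seq, g1$seq)
  expect_equal(c(one$start, one$end), c(0L, 40000L))

  g2 <- random_genome(39999, "short", seed = 12)
  expect_error(extract_chunks(g2, 1, 40000), "39999")
  g3 <- tibble::tibble(id = "bad", seq = "ACGTQACGT")
  expect_error(extract_chunks(g3, 1, 4), "characters")
})

test_that("single-end read count follows the coverage formula and reads are exact substrings", {
  cs <- build_construct(rnd_dna(800, seed = 20), rnd_dna(200, seed = 21),
                        mode = "extremity_right")
  expect_equal(nchar(cs$full_seq), 1000)
  prof <- read_profile("single", read_len = 150, coverage = 10,
                       subst_error_rate = 0, seed = 5)
  rds <- simulate_reads(cs, prof)
  expect_equal(nrow(rds), ceiling(10 * 1000 / 150))  # 67
  expect_equal(nrow(rds), 67)
  ok <- vapply(rds$seq, function(s) {
    grepl(s, cs$full_seq, fixed = TRUE) ||
      grepl(revcomp(s), cs$full_seq, fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))
})

test_that("paired mates are co-oriented substrings with in-bounds fragments", {
  cs <- build_construct(rnd_dna(1500, seed = 22), rnd_dna(300, seed = 23),
                        mode = "internal", insertion_pos = 700,
                        overlap_len = 100)
  prof <- read_profile("paired", read_len = 100, fragment_mean = 250,
                       fragment_sd = 20, coverage = 30,
                       subst_error_rate = 0, seed = 6)
  rds <- simulate_reads(cs, prof)
  full <- cs$full_seq
  L <- nchar(full)
  m1 <- rds$seq[rds$mate == 1L]
  m2 <- rds$seq[rds$mate == 2L]
  expect_equal(length(m1), length(m2))
  for (i in seq_along(m1)) {
    fwd <- regexpr(m1[i], full, fixed = TRUE)
    if (fwd > 0) {
      p2 <- regexpr(revcomp(m2[i]), full, fixed = TRUE)
      expect_gt(p2, 0)
      frag <- (p2 + 100 - 1) - fwd + 1
    } else {
      p1 <- regexpr(revcomp(m1[i]), full, fixed = TRUE)
      p2 <- regexpr(m2[i], full, fixed = TRUE)
      expect_gt(p1, 0)
      expect_gt(p2, 0)
      frag <- (p1 + 100 - 1) - p2 + 1
    }
    expect_gte(frag, 100)
    expect_lte(frag, L)
  }
})

test_that("read simulation is deterministic down to the FASTQ bytes", {
  cs <- build_construct(rnd_dna(1000, seed = 30), rnd_dna(200, seed = 31),
                        mode = "extremity_left")
  prof <- read_profile("paired", coverage = 40, subst_error_rate = 0.01,
                       seed = 77)
  r1 <- simulate_reads(cs, prof)
  r2 <- simulate_reads(cs, prof)
  expect_identical(r1$seq, r2$seq)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1, f2)
  write_fastq(r2, fa, fb)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(fa)))
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(fb)))
})

test_that("error-free read k-mers are a subset of construct k-mers", {
  cs <- build_construct(rnd_dna(1200, seed = 40), rnd_dna(250, seed = 41),
                        mode = "internal", insertion_pos = 600,
                        overlap_len = 200)
  prof <- read_profile("paired", coverage = 50, subst_error_rate = 0,
                       seed = 8)
  rds <- simulate_reads(cs, prof)
  ck <- kmer_canon(cs$full_seq, 31)
  rk <- unique(unlist(lapply(rds$seq, kmer_canon, k = 31)))
  expect_true(all(rk %in% ck))
})

test_that("observed coverage is within 5% of the profile for coverage >= 100", {
  cs <- build_construct(rnd_dna(3000, seed = 50), rnd_dna(500, seed = 51),
                        mode = "extremity_right")
  L <- nchar(cs$full_seq)
  for (cov in c(100, 300)) {
    prof <- read_profile("paired", coverage = cov, subst_error_rate = 0,
                         seed = cov)
    rds <- simulate_reads(cs, prof)
    obs <- sum(nchar(rds$seq)) / L
    expect_lt(abs(obs - cov) / cov, 0.05)
  }
})

test_that("the batch generator writes FASTQ, constructs and truth that agree", {
  out <- tempfile("simset")
  genomes <- dplyr::bind_rows(random_genome(8000, "gA", seed = 60),
                              random_genome(8000, "gB", seed = 61))
  res <- simulate_fosmid_set(genomes, rnd_dna(600, seed = 62),
                             n_constructs = 3, chunk_len = 3000,
                             mode = "random", overlap_len = 300,
                             profile = read_profile("paired", coverage = 20),
                             seed = 5, out_dir = out)
  expect_length(res$constructs, 3)
  expect_equal(nrow(res$truth), 3)
  expect_true(file.exists(file.path(out, "truth.json")))
  expect_true(file.exists(file.path(out, "constructs.fasta")))
  man <- read_truth_manifest(file.path(out, "truth.json"))
  expect_length(man, 3)
  expect_equal(man[[2]]$insert_seq, res$constructs[[2]]$insert_seq)
  # reads on disk match the in-memory sets
  nm <- res$truth$construct_id[1]
  rs <- read_fastq(file.path(out, paste0(nm, "_R1.fastq.gz")),
                   file.path(out, paste0(nm, "_R2.fastq.gz")))
  expect_equal(rs$seq, res$read_sets[[nm]]$seq)
})
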