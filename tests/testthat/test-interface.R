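# a small three-sample batch shared by the interface tests
setup_batch <- function(root, n = 3, with_bad_sample = FALSE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  genomes <- dplyr::bind_rows(random_genome(12000, "gA", seed = 800),
                              random_genome(12000, "gB", seed = 801))
  vec <- random_genome(700, "vec_synthetic", seed = 802)
  sim <- simulate_fosmid_set(
    genomes, vec, n_constructs = n, chunk_len = 3000, mode = "random",
    overlap_len = 300,
    profile = read_profile("paired", coverage = 100, subst_error_rate = 0),
    seed = 42, out_dir = root)
  write_fasta(vec, file.path(root, "vector.fasta"))
  if (with_bad_sample) {
    # a sample whose reads are all poor quality: everything gets filtered
    bad <- read_set(sprintf("bad%03d", 1:50), rep(strrep("N", 100), 50),
                    rep(strrep("#", 100), 50))
    write_fastq(bad, file.path(root, "badsample_single.fastq.gz"))
  }
  sim
}

batch_config <- function() {
  fosmid_config(coverage = 80, expected_len = 3000, min_count = 4,
                min_contig_len = 800, seed = 7)
}

test_that("collect_samples pairs R1/R2 and single files by sample name", {
  root <- tempfile("batch")
  setup_batch(root, n = 2)
  tb <- collect_samples(root)
  expect_equal(nrow(tb), 2)
  expect_true(all(!is.na(tb$r1) & !is.na(tb$r2)))
  expect_true(all(is.na(tb$single)))
  expect_true(all(grepl("_R1\\.fastq\\.gz$", tb$r1)))
})

test_that("the assembly pipeline runs a batch end to end and reports it", {
  root <- tempfile("batch")
  sim <- setup_batch(root, n = 3)
  out <- file.path(root, "out")
  run <- run_assemble(root, file.path(root, "vector.fasta"), out,
                      config = batch_config())

  tb <- tidy(run)
  expect_equal(nrow(tb), 3)
  expect_true(all(tb$status == "ok"))
  expect_true(all(tb$contigs_final >= 1))

  # pooled fasta holds the union of the per-sample outputs
  pooled <- read_fasta(file.path(out, "assembled.fasta"))
  per_sample <- unlist(lapply(tb$sample, function(sm) {
    read_fasta(file.path(out, paste0(sm, "_assembled.fasta")))$id
  }))
  expect_setequal(pooled$id, per_sample)

  # manifest exists, parses, and records parameters and checksums
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(length(man$samples), 3)
  expect_equal(man$parameters$coverage, 80)
  expect_true(all(file.exists(file.path(out, basename(names(man$checksums))))))

  # vector GFF uses 1-based inclusive coordinates
  gff <- readLines(file.path(out, paste0(tb$sample[1], "_vector.gff3")))
  rows <- gff[!startsWith(gff, "#")]
  if (length(rows) > 0) {
    f <- stringr::str_split_fixed(rows, "\t", 9)
    expect_true(all(as.integer(f[, 4]) >= 1))
    expect_true(all(as.integer(f[, 5]) > as.integer(f[, 4])))
  }

  # report: one table row per sample, an inline SVG plot, no remote assets
  html <- paste(readLines(file.path(out, "report.html")), collapse = "\n")
  for (sm in tb$sample) expect_true(grepl(sm, html, fixed = TRUE))
  expect_true(grepl("<svg", html, fixed = TRUE))
  expect_false(grepl("src=\"http", html))
  expect_false(grepl("href=\"http", html))

  expect_s3_class(autoplot(run), "ggplot")
  g <- glance(run)
  expect_equal(g$n_failed, 0)
  expect_equal(g$n_samples, 3)
})

test_that("a failing sample is recorded and skipped without killing the batch", {
  root <- tempfile("batch")
  setup_batch(root, n = 2, with_bad_sample = TRUE)
  out <- file.path(root, "out")
  run <- run_assemble(root, file.path(root, "vector.fasta"), out,
                      config = batch_config())
  tb <- tidy(run)
  expect_equal(nrow(tb), 3)
  expect_equal(sum(tb$status == "failed"), 1)
  expect_equal(sum(tb$status == "ok"), 2)
  bad <- tb[tb$status == "failed", ]
  expect_equal(bad$sample, "badsample")
  html <- paste(readLines(file.path(out, "report.html")), collapse = "\n")
  expect_true(grepl("failed", html, fixed = TRUE))
})

test_that("identical inputs and seed reproduce identical outputs", {
  root <- tempfile("batch")
  setup_batch(root, n = 2)
  out1 <- file.path(root, "out1"); out2 <- file.path(root, "out2")
  run1 <- run_assemble(root, file.path(root, "vector.fasta"), out1,
                       config = batch_config())
  run2 <- run_assemble(root, file.path(root, "vector.fasta"), out2,
                       config = batch_config())
  expect_identical(tidy(run1), tidy(run2))
  for (f in c("assembled.fasta", paste0(tidy(run1)$sample[1],
                                        "_assembled.fasta"))) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
})

test_that("YAML configuration round-trips with CLI-style overrides", {
  cfgfile <- tempfile(fileext = ".yml")
  writeLines(c("coverage: 150", "k: 33", "min_contig_len: 1200"), cfgfile)
  cfg <- read_config(cfgfile, seed = 99)
  expect_equal(cfg$coverage, 150)
  expect_equal(cfg$k, 33)
  expect_equal(cfg$min_contig_len, 1200)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$min_count, 10)  # untouched default
  expect_error(fosmid_config(nope = 1), "unknown config key")
})

test_that("annotation runs on cleaned contigs and writes GFF + proteins", {
  root <- tempfile("annot")
  sim <- setup_batch(root, n = 1)
  out <- file.path(root, "out")
  run <- run_assemble(root, file.path(root, "vector.fasta"), out,
                      config = batch_config())
  ann <- run_annotate(file.path(out, "assembled.fasta"),
                      file.path(root, "ann"), min_aa_len = 30)
  expect_true(file.exists(ann$gff))
  expect_true(file.exists(ann$faa))
  back <- parse_gff3(ann$gff)
  expect_equal(nrow(back), nrow(ann$features))
  expect_true(file.exists(file.path(root, "ann", "annotation_report.html")))
})
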