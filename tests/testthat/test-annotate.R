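# a codon sampler that avoids stop codons
orf_body <- function(n_codons, seed) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all_codons, stops)
  withr::with_seed(seed, paste(sample(ok, n_codons, TRUE), collapse = ""))
}

make_orf_contig <- function(seed = 500) {
  orf <- paste0("ATG", orf_body(149, seed), "TAA")  # 150 codons + stop
  # an in-frame stop right before the ATG pins the ORF start: without it a
  # chance in-frame GTG/TTG in the flank would legitimately extend the call
  contig <- paste0(rnd_dna(197, seed + 1), "TAA", orf, rnd_dna(200, seed + 2))
  list(contig = contig, orf = orf, start = 200L, end = 200L + 453L)
}

test_that("a single constructed forward ORF is found with exact coordinates", {
  fx <- make_orf_contig()
  ct <- as_contigs(fx$contig)
  orfs <- find_orfs(ct, min_aa_len = 100)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, fx$start)
  expect_equal(orfs$end, fx$end)
  expect_equal(orfs$strand, "+")
  expect_equal(nchar(orfs$translation), 150)
  expect_equal(substring(orfs$translation, 1, 1), "M")
})

test_that("the reverse complement mirrors coordinates and matches brute force", {
  fx <- make_orf_contig(seed = 510)
  L <- nchar(fx$contig)
  rc_ct <- as_contigs(revcomp(fx$contig))
  orfs <- find_orfs(rc_ct, min_aa_len = 100)
  fw <- orfs[orfs$strand == "-", ]
  expect_equal(nrow(fw), 1)
  expect_equal(fw$start, L - fx$end)
  expect_equal(fw$end, L - fx$start)

  bf <- orf_bruteforce(revcomp(fx$contig), min_aa_len = 100)
  expect_equal(orfs$start, bf$start)
  expect_equal(orfs$end, bf$end)
  expect_equal(orfs$strand, bf$strand)
})

test_that("six-frame calls equal brute-force enumeration on mixed sequences", {
  for (s in c(520, 521, 522)) {
    seq <- paste0(rnd_dna(300, s), "ATG", orf_body(60, s + 40), "TGA",
                  rnd_dna(150, s + 80))
    got <- find_orfs(as_contigs(seq), min_aa_len = 40)
    bf <- orf_bruteforce(seq, min_aa_len = 40)
    expect_equal(nrow(got), nrow(bf))
    expect_equal(got$start, bf$start)
    expect_equal(got$end, bf$end)
    expect_equal(got$strand, bf$strand)
  }
})

test_that("short-ORF-only sequences yield nothing and CDS invariants hold", {
  expect_equal(nrow(find_orfs(as_contigs(rnd_dna(400, seed = 530)),
                              min_aa_len = 100)), 0)
  fx <- make_orf_contig(seed = 540)
  big <- as_contigs(paste0(fx$contig, revcomp(make_orf_contig(541)$contig)))
  orfs <- find_orfs(big, min_aa_len = 60)
  expect_gt(nrow(orfs), 0)
  expect_true(all((orfs$end - orfs$start) %% 3 == 0))
  expect_equal(nchar(orfs$translation), (orfs$end - orfs$start) / 3 - 1)
  expect_false(any(grepl("*", orfs$translation, fixed = TRUE)))
  # translations restart-checked on the coding strand
  withseq <- cds_sequences(big, orfs)
  expect_true(all(substring(withseq$seq, 1, 3) %in% c("ATG", "GTG", "TTG")))
})

test_that("masked contigs are rejected by the ORF caller", {
  expect_error(find_orfs(as_contigs("ACGTXXXXACGTACGTACGT")), "masked")
})

test_that("GFF3 output round-trips and validates structurally", {
  fx <- make_orf_contig(seed = 550)
  ct <- as_contigs(paste0(fx$contig, revcomp(make_orf_contig(551)$contig)))
  orfs <- find_orfs(ct, min_aa_len = 60)
  gff <- tempfile(fileext = ".gff3")
  faa <- tempfile(fileext = ".faa")
  write_annotation(ct, orfs, gff, faa)

  back <- parse_gff3(gff, contigs = ct)
  expect_equal(back$start, orfs$start)
  expect_equal(back$end, orfs$end)
  expect_equal(back$strand, orfs$strand)
  expect_equal(back$frame, orfs$frame)
  expect_equal(back$cds_id, orfs$cds_id)

  # 1-based inclusive on disk: a [0, 300) feature prints 1..300
  lines <- readLines(gff)
  body <- lines[!startsWith(lines, "#")]
  f <- stringr::str_split_fixed(body, "\t", 9)
  expect_equal(as.integer(f[1, 4]), orfs$start[1] + 1L)
  expect_equal(as.integer(f[1, 5]), orfs$end[1])

  # independent structural validation
  gr <- rtracklayer::import(gff)
  expect_equal(length(gr), nrow(orfs))
  expect_equal(BiocGenerics::start(gr), orfs$start + 1L)

  prots <- read_fasta(faa)
  expect_equal(prots$id, orfs$cds_id)
  expect_equal(prots$seq, orfs$translation)
})

test_that("reserved attribute characters are percent-encoded", {
  fx <- make_orf_contig(seed = 560)
  ct <- as_contigs(fx$contig)
  orfs <- find_orfs(ct, min_aa_len = 100)
  hits <- tibble::tibble(query = orfs$cds_id, subject = "sp|P12345",
                         identity = 98.2, evalue = 1e-50, bitscore = 321,
                         description = "beta;galactosidase=like, partial")
  gff <- tempfile(fileext = ".gff3")
  write_annotation(ct, orfs, gff, hits = hits)
  line <- grep("\tCDS\t", readLines(gff), value = TRUE)
  expect_true(grepl("beta%3Bgalactosidase%3Dlike%2C partial", line,
                    fixed = TRUE))
  # GFF3 conformance: 9 columns, attribute values free of raw ; = ,
  attr_field <- stringr::str_split_fixed(line, "\t", 9)[, 9]
  vals <- sub("^[^=]*=", "", strsplit(attr_field, ";")[[1]])
  expect_false(any(grepl("[;=\t]", vals)))
})

test_that("features outside contig bounds are rejected", {
  ct <- as_contigs(rnd_dna(100, seed = 570))
  bad <- tibble::tibble(contig_id = "contig_1", start = 50L, end = 200L,
                        strand = "+", frame = 0L, cds_id = "x",
                        translation = "M")
  expect_error(write_annotation(ct, bad, tempfile()), "bounds")
})
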