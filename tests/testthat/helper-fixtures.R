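# Shared fixture builders: everything is generated in code under fixed seeds.

rnd_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# exactly n_sub substitutions at distinct positions
mutate_bases <- function(seq, n_sub, seed = 1) {
  withr::with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    idx <- sample(length(v), n_sub)
    v[idx] <- vapply(v[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    paste(v, collapse = "")
  })
}

# error-free reads tiling a sequence end to end (guarantees full k-mer
# coverage, including the terminal k-mers)
tiling_reads <- function(seq, read_len = 150, step = 25, prefix = "tile") {
  L <- nchar(seq)
  starts <- unique(c(seq(0, L - read_len, by = step), L - read_len))
  read_set(id = sprintf("%s_%04d", prefix, seq_along(starts)),
           seq = substring(seq, starts + 1, starts + read_len),
           qual = strrep("F", read_len))
}

# canonical k-mer set of a sequence (both strands), pure R
kmer_canon <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, 1:(L - k + 1), k:L)
  rc <- substring(revcomp(seq), 1:(L - k + 1), k:L)
  unique(pmin(km, rev(rc)))
}

# Biostrings local-alignment oracle with the vector-detection scoring
# (match +1 / mismatch -2 / linear gap -3)
oracle_local <- function(query, target) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(query, target, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 3)
  list(t_start = Biostrings::start(Biostrings::subject(al)) - 1L,
       t_end = Biostrings::end(Biostrings::subject(al)),
       n_match = Biostrings::nmatch(al),
       score = Biostrings::score(al),
       width = Biostrings::nchar(al))
}

# Biostrings global oracle with the align_pair scoring
# (match +1 / mismatch -2 / gap open -4 / extend -1)
oracle_global <- function(query, target) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(query, target, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 4, gapExtension = 1)
  list(n_match = Biostrings::nmatch(al), score = Biostrings::score(al))
}

# small contig tibble from raw sequences
as_contigs <- function(seqs, cov = 100, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("contig_%d", seq_along(seqs))
  tibble::tibble(contig_id = ids, seq = seqs, length = nchar(seqs),
                 mean_cov = cov, is_cycle = FALSE)
}

# brute-force six-frame ORF enumerator, structured differently from the
# implementation: enumerate every start-codon occurrence, walk to its stop,
# then keep the longest ORF per (strand, stop)
orf_bruteforce <- function(seq, min_aa_len = 100) {
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    L <- nchar(s)
    for (p0 in 0:(L - 3)) {
      cod <- substring(s, p0 + 1, p0 + 3)
      if (!(cod %in% starts)) next
      q <- p0 + 3
      stop_at <- NA
      while (q + 3 <= L) {
        cq <- substring(s, q + 1, q + 3)
        if (cq %in% stops) { stop_at <- q; break }
        q <- q + 3
      }
      if (is.na(stop_at)) next
      aa_len <- (stop_at - p0) / 3
      if (aa_len < min_aa_len) next
      out[[length(out) + 1L]] <- tibble::tibble(
        strand = strand, s_start = p0, s_end = stop_at + 3)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character()))
  }
  tb <- dplyr::bind_rows(out)
  # longest ORF per (strand, stop)
  tb <- dplyr::slice_min(dplyr::group_by(tb, strand, s_end), s_start,
                         with_ties = FALSE)
  tb <- dplyr::ungroup(tb)
  L <- nchar(seq)
  tibble::tibble(
    start = ifelse(tb$strand == "+", tb$s_start, L - tb$s_end),
    end = ifelse(tb$strand == "+", tb$s_end, L - tb$s_start),
    strand = tb$strand
  )[order(ifelse(tb$strand == "+", tb$s_start, L - tb$s_end)), ]
}
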