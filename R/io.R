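#' Read a FASTA file into a tibble
#'
#' Sequences are returned as plain character strings so that masked bases
#' (`X`) survive round-trips. The id is the first whitespace-delimited word
#' of the header; the full header is kept in `desc`.
#'
#' @param path Path to a FASTA file (gzip transparent).
#' @return A tibble with columns `id`, `seq` and `desc`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  desc <- names(x)
  tibble(
    id = unname(sub("\\s.*$", "", desc)),
    seq = unname(toupper(as.character(x))),
    desc = unname(desc)
  )
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `id` (or `contig_id`) and `seq` (a
#'   `desc` column, when present, becomes the header).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x))
  if (!"id" %in% names(x) && "contig_id" %in% names(x)) {
    x$id <- x$contig_id
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  hdr <- if ("desc" %in% names(x) && !anyNA(x$desc)) x$desc else x$id
  set <- Biostrings::BStringSet(setNames(x$seq, hdr))
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Construct a read set tibble
#'
#' A read set is an ordered tibble of reads with phred+33 quality strings.
#' Paired layouts interleave nothing: mates are matched by `pair_id`, and
#' mate 1/2 is recorded in `mate` (0 for single-end reads).
#'
#' @param id,seq,qual Character vectors of equal length.
#' @param mate Integer vector (0 = single, 1/2 = mates). Scalar recycled.
#' @param pair_id Integer pair index (NA for single reads).
#' @return A tibble with class `read_set` and columns
#'   `id`, `seq`, `qual`, `mate`, `pair_id`.
#' @export
read_set <- function(id, seq, qual, mate = 0L, pair_id = NA_integer_) {
  n <- length(seq)
  if (length(mate) == 1) mate <- rep(as.integer(mate), n)
  if (length(pair_id) == 1) pair_id <- rep(as.integer(pair_id), n)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("malformed read record(s) at index ", paste(head(bad, 5), collapse = ", "),
         ": sequence and quality lengths differ")
  }
  if (anyDuplicated(id[mate != 2L]) || anyDuplicated(id[mate == 2L])) {
    stop("read ids must be unique within a file")
  }
  out <- tibble(id = id, seq = seq, qual = qual,
                mate = as.integer(mate), pair_id = pair_id)
  class(out) <- c("read_set", class(out))
  out
}

read_set_layout <- function(reads) {
  if (nrow(reads) > 0 && any(reads$mate > 0L)) "paired" else "single"
}

#' Read FASTQ file(s) into a read set
#'
#' @param r1 Path to the single-end or mate-1 FASTQ (gzip transparent).
#' @param r2 Optional path to the mate-2 FASTQ; mates are paired by index.
#' @return A [read_set()] tibble.
#' @export
read_fastq <- function(r1, r2 = NULL) {
  rd <- function(path) {
    # Biostrings warns about dropped metadata columns on FASTQ input;
    # nothing of ours is lost
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    list(id = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  a <- rd(r1)
  if (is.null(r2)) {
    return(read_set(a$id, a$seq, a$qual, mate = 0L))
  }
  b <- rd(r2)
  if (length(a$id) != length(b$id)) {
    stop("paired FASTQ files have different read counts (",
         length(a$id), " vs ", length(b$id), ")")
  }
  n <- length(a$id)
  read_set(
    id = c(rbind(a$id, b$id)),
    seq = c(rbind(a$seq, b$seq)),
    qual = c(rbind(a$qual, b$qual)),
    mate = rep(c(1L, 2L), n),
    pair_id = rep(seq_len(n), each = 2L)
  )
}

#' Write a read set to FASTQ file(s)
#'
#' Paired read sets go to separate `_R1`/`_R2` files; `r2` is required for
#' a paired layout and ignored for single-end sets.
#'
#' @param reads A [read_set()] tibble.
#' @param r1,r2 Output paths; `.gz` suffixes trigger compression.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fastq <- function(reads, r1, r2 = NULL) {
  wr <- function(ids, seqs, quals, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  }
  if (read_set_layout(reads) == "paired") {
    if (is.null(r2)) stop("paired read set needs both r1 and r2 paths")
    m1 <- reads[reads$mate == 1L, ]
    m2 <- reads[reads$mate == 2L, ]
    wr(m1$id, m1$seq, m1$qual, r1)
    wr(m2$id, m2$seq, m2$qual, r2)
    return(invisible(c(r1, r2)))
  }
  wr(reads$id, reads$seq, reads$qual, r1)
  invisible(r1)
}

#' Reverse complement of character DNA sequences
#'
#' @param x Character vector over the DNA alphabet (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence", allow = "ACGTN") {
  bad <- grepl(sprintf("[^%s]", allow), x)
  if (any(bad)) {
    stop(what, " contains characters outside {",
         paste(strsplit(allow, "")[[1]], collapse = ","), "}")
  }
  invisible(x)
}
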