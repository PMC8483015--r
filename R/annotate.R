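#' Find open reading frames on contigs
#'
#' Scans all six frames for ORFs running from a start codon (ATG/GTG/TTG)
#' to the next in-frame stop, under the bacterial genetic code by default.
#' Within a frame, overlapping ORFs sharing a stop are resolved to the
#' longest (earliest start). Coordinates are 0-based half-open on the
#' forward strand and include the stop codon; translations exclude the stop
#' and keep the raw start-codon amino acid (no methionine forcing).
#'
#' @param contigs A contig tibble (columns `contig_id`, `seq`); sequences
#'   must be X-free.
#' @param min_aa_len Minimum protein length in codons, stop excluded
#'   (default 100).
#' @param genetic_code NCBI genetic code id (default `"11"`, bacteria).
#' @return A tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `cds_id`, `translation`, sorted by contig and start.
#' @export
find_orfs <- function(contigs, min_aa_len = 100, genetic_code = "11") {
  code <- Biostrings::getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  starts <- c("ATG", "GTG", "TTG")

  scan_strand <- function(s, L) {
    hits <- list()
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < min_aa_len + 1) next
      pos <- f + 3 * (seq_len(ncod) - 1) + 1
      codons <- substring(s, pos, pos + 2)
      stop_idx <- which(codons %in% stops)
      start_idx <- which(codons %in% starts)
      if (length(stop_idx) == 0 || length(start_idx) == 0) next
      prev_stop <- 0L
      si <- 1L
      for (st in stop_idx) {
        # earliest start codon strictly after the previous stop
        while (si <= length(start_idx) && start_idx[si] <= prev_stop) {
          si <- si + 1L
        }
        if (si <= length(start_idx) && start_idx[si] < st) {
          aa_len <- st - start_idx[si]
          if (aa_len >= min_aa_len) {
            hits[[length(hits) + 1L]] <- c(
              f = f,
              nt_start = f + 3L * (start_idx[si] - 1L),  # 0-based
              nt_end = f + 3L * st                        # incl. stop
            )
          }
        }
        prev_stop <- st
      }
    }
    hits
  }

  out <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    s <- contigs$seq[i]
    if (grepl("X", s, fixed = TRUE)) {
      stop("contig ", contigs$contig_id[i],
           " contains masked (X) bases; run re-organization first")
    }
    L <- nchar(s)
    rc <- revcomp(s)
    fw <- scan_strand(s, L)
    rv <- scan_strand(rc, L)
    rows <- list()
    for (h in fw) {
      rows[[length(rows) + 1L]] <- tibble(
        contig_id = contigs$contig_id[i], start = h[["nt_start"]],
        end = h[["nt_end"]], strand = "+", frame = h[["f"]],
        nt = substring(s, h[["nt_start"]] + 1, h[["nt_end"]]))
    }
    for (h in rv) {
      rows[[length(rows) + 1L]] <- tibble(
        contig_id = contigs$contig_id[i], start = L - h[["nt_end"]],
        end = L - h[["nt_start"]], strand = "-", frame = h[["f"]],
        nt = substring(rc, h[["nt_start"]] + 1, h[["nt_end"]]))
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) == 0) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character(), frame = integer(),
                  cds_id = character(), translation = character()))
  }
  out <- out[order(out$contig_id, out$start, out$end), ]
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(out$nt), genetic.code = code))
  out$translation <- sub("\\*$", "", aa)
  out$nt <- NULL
  out$cds_id <- sprintf("%s_cds%03d", out$contig_id,
                        stats::ave(seq_len(nrow(out)), out$contig_id,
                                   FUN = seq_along))
  out[, c("contig_id", "start", "end", "strand", "frame", "cds_id",
          "translation")]
}

#' Extract nucleotide sequences of CDS features
#'
#' @param contigs Contig tibble the features refer to.
#' @param features CDS tibble from [find_orfs()].
#' @return `features` with an added `seq` column (coding strand).
#' @export
cds_sequences <- function(contigs, features) {
  seqs <- setNames(contigs$seq, contigs$contig_id)
  nt <- substring(seqs[features$contig_id], features$start + 1, features$end)
  neg <- features$strand == "-"
  if (any(neg)) nt[neg] <- revcomp(nt[neg])
  features$seq <- unname(nt)
  features
}

gff3_escape <- function(x) {
  # percent-encode characters reserved in GFF3 attribute values
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

gff3_unescape <- function(x) {
  utils::URLdecode(x)
}

#' Write CDS annotation as GFF3 and protein FASTA
#'
#' Coordinates are converted to the 1-based inclusive GFF3 convention; the
#' phase column is 0 (features are complete CDS). An optional external-hit
#' table (columns `query`, `subject`, `identity`, `evalue`, `bitscore`,
#' `description`, with `query` matching `cds_id`) is merged into the GFF
#' attributes with proper escaping.
#'
#' @param contigs Contig tibble the features refer to.
#' @param features CDS tibble from [find_orfs()].
#' @param gff_path Output GFF3 path.
#' @param faa_path Optional protein FASTA path.
#' @param hits Optional external homology hit table.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(contigs, features, gff_path, faa_path = NULL,
                             hits = NULL) {
  known <- setNames(nchar(contigs$seq), contigs$contig_id)
  if (nrow(features) > 0) {
    if (!all(features$contig_id %in% names(known))) {
      stop("features reference unknown contigs")
    }
    if (any(features$start < 0 | features$end > known[features$contig_id])) {
      stop("feature coordinates outside contig bounds")
    }
  }
  attrs <- paste0("ID=", gff3_escape(features$cds_id))
  if (!is.null(hits) && nrow(features) > 0) {
    h <- hits[match(features$cds_id, hits$query), , drop = FALSE]
    has <- !is.na(h$query)
    extra <- sprintf(
      "Name=%s;note=%s;identity=%s;evalue=%s;bitscore=%s",
      gff3_escape(h$subject), gff3_escape(h$description),
      h$identity, h$evalue, h$bitscore)
    attrs[has] <- paste0(attrs[has], ";", extra[has])
  }
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", contigs$contig_id,
                     nchar(contigs$seq)))
  if (nrow(features) > 0) {
    lines <- c(lines, sprintf(
      "%s\tfosmidr\tCDS\t%d\t%d\t.\t%s\t0\t%s",
      features$contig_id, features$start + 1L, features$end,
      features$strand, attrs))
  }
  writeLines(lines, gff_path)
  if (!is.null(faa_path)) {
    if (nrow(features) > 0) {
      write_fasta(tibble(id = features$cds_id, seq = features$translation),
                  faa_path)
    } else {
      writeLines(character(0), faa_path)
    }
  }
  invisible(gff_path)
}

#' Parse a GFF3 file of CDS features
#'
#' Minimal structural parser for files written by [write_annotation()] (and
#' compatible CDS GFF3); converts coordinates back to 0-based half-open.
#'
#' @param path GFF3 path.
#' @param contigs Optional contig tibble; when given, the strand-local frame
#'   is recomputed from the coordinates (the phase column of a complete CDS
#'   is always 0 and does not encode the genomic frame).
#' @return A tibble with `contig_id`, `start`, `end`, `strand`, `frame`,
#'   `cds_id`, `attributes`.
#' @export
parse_gff3 <- function(path, contigs = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character(), frame = integer(),
                  cds_id = character(), attributes = character()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 9)
  if (ncol(f) < 9) stop("malformed GFF3: expected 9 tab-separated columns")
  ids <- stringr::str_match(f[, 9], "(?:^|;)ID=([^;]*)")[, 2]
  out <- tibble(
    contig_id = f[, 1],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    strand = f[, 7],
    frame = suppressWarnings(as.integer(f[, 8])),
    cds_id = vapply(ids, gff3_unescape, "", USE.NAMES = FALSE),
    attributes = f[, 9]
  )
  if (!is.null(contigs)) {
    L <- setNames(nchar(contigs$seq), contigs$contig_id)[out$contig_id]
    out$frame <- ifelse(out$strand == "+", out$start %% 3L,
                        (L - out$end) %% 3L)
  }
  out
}
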