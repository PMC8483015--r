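#' Assemble reads with the built-in de Bruijn graph assembler
#'
#' Builds a graph over canonical k-mers (lexicographic minimum of a k-mer
#' and its reverse complement) with abundance at least `min_count`, removes
#' dead-end tips shorter than 2k, and compacts unbranched paths into contigs.
#' Branches stop extension (no greedy resolution), so correctness is
#' preferred over contiguity. Circular components are opened at a
#' deterministic k-mer and carry a (k-1) bp terminal duplication, which the
#' circularity re-organization step later detects as the join overlap. The
#' per-contig mean coverage is the mean k-mer abundance along the path.
#'
#' Intended for fosmid-scale, high-coverage, low-error read sets; an external
#' assembler adapter ([run_external_assembler()]) is the production path.
#'
#' @param reads A [read_set()] tibble.
#' @param k Odd k-mer size in 15..63 (2-bit packing limits k to 63).
#' @param min_count Minimum k-mer abundance; at the pipeline's default 300X
#'   subsampled coverage a value around 10 removes virtually all
#'   sequencing-error k-mers.
#' @return A contig tibble (class `contig_tbl`) with columns `contig_id`,
#'   `seq`, `length`, `mean_cov`, `is_cycle`, sorted by decreasing length.
#' @export
assemble_reads <- function(reads, k = 31, min_count = 10) {
  if (nrow(reads) == 0) stop("cannot assemble an empty read set")
  res <- cpp_assemble(reads$seq, as.integer(k), as.integer(min_count))
  out <- tibble(seq = res$seq, mean_cov = res$mean_cov,
                is_cycle = res$is_cycle)
  if (nrow(out) == 0) {
    warning("no k-mer reached min_count = ", min_count,
            "; returning an empty contig set")
    return(contig_tbl(tibble(contig_id = character(), seq = character(),
                             length = integer(), mean_cov = numeric(),
                             is_cycle = logical())))
  }
  out$length <- nchar(out$seq)
  ord <- order(-out$length)  # stable: construction order breaks ties
  out <- out[ord, ]
  out$contig_id <- sprintf("contig_%d", seq_len(nrow(out)))
  contig_tbl(out[, c("contig_id", "seq", "length", "mean_cov", "is_cycle")])
}

contig_tbl <- function(x) {
  x <- as_tibble(x)
  class(x) <- unique(c("contig_tbl", class(x)))
  x
}

#' Parse an external assembler's FASTA output into a contig set
#'
#' Headers of the form `NODE_<i>_length_<L>_cov_<C>` (as written by common
#' de Bruijn assemblers) provide the per-contig mean coverage; other headers
#' yield `NaN` coverage, flagged for downstream re-estimation. When the
#' header length disagrees with the actual sequence length, the sequence
#' wins with a warning.
#'
#' @param path FASTA path.
#' @return A contig tibble with columns `contig_id`, `seq`, `length`,
#'   `mean_cov`, `cov_known`.
#' @export
parse_assembler_fasta <- function(path) {
  fa <- read_fasta(path)
  m <- stringr::str_match(fa$id, "^NODE_(\\d+)_length_(\\d+)_cov_([0-9.]+)$")
  len <- nchar(fa$seq)
  hdr_len <- suppressWarnings(as.integer(m[, 3]))
  bad <- !is.na(hdr_len) & hdr_len != len
  if (any(bad)) {
    warning(sum(bad), " contig header(s) disagree with sequence length; ",
            "using the sequence length")
  }
  cov <- suppressWarnings(as.numeric(m[, 4]))
  cov[is.na(cov)] <- NaN
  contig_tbl(tibble(
    contig_id = ifelse(is.na(m[, 1]), fa$id, sprintf("NODE_%s", m[, 2])),
    seq = fa$seq,
    length = len,
    mean_cov = cov,
    cov_known = !is.nan(cov)
  ))
}

#' Run an external assembler through a command template
#'
#' Executes a shell command template with the placeholders `{r1}`, `{r2}`,
#' `{single}` and `{outdir}` substituted, then collects `contigs.fasta` (or
#' `scaffolds.fasta`) from the output directory.
#'
#' @param cmd_template Shell command template.
#' @param r1,r2,single FASTQ paths (NULL when absent).
#' @param outdir Working/output directory (created if needed).
#' @return A contig tibble from [parse_assembler_fasta()].
#' @export
run_external_assembler <- function(cmd_template, r1 = NULL, r2 = NULL,
                                   single = NULL, outdir = tempfile("asm")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cmd <- cmd_template
  for (ph in c("r1", "r2", "single", "outdir")) {
    val <- switch(ph, r1 = r1, r2 = r2, single = single, outdir = outdir)
    cmd <- gsub(paste0("{", ph, "}"), if (is.null(val)) "" else val, cmd,
                fixed = TRUE)
  }
  status <- system(cmd)
  if (status != 0) stop("external assembler failed (exit status ", status, ")")
  for (f in c("contigs.fasta", "scaffolds.fasta")) {
    p <- file.path(outdir, f)
    if (file.exists(p)) return(parse_assembler_fasta(p))
  }
  stop("external assembler produced neither contigs.fasta nor scaffolds.fasta in ",
       outdir)
}
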