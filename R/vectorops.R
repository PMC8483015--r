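#' Detect the cloning vector in contigs
#'
#' Seed-chain-extend local alignment (exact 15-mer seeds, co-linear chains,
#' banded DP extension with match +1, mismatch -2, gap -3 per base) of the
#' vector against each contig, on both strands; problems small enough for a
#' full local dynamic program skip the seeding heuristic. Matches on the
#' same diagonal within the gap tolerance are merged by the chaining step.
#' Coordinates are reported 0-based half-open on the contig forward strand.
#'
#' @param contigs A contig tibble (columns `contig_id`, `seq`).
#' @param vector_seq Cloning-vector sequence (string or one-row data frame).
#' @param min_identity Minimum alignment identity in \[0.5, 1\] (default 0.9).
#' @param min_match_len Minimum aligned length on the contig (default 50 bp).
#' @return A tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   `identity`, `n_match`, `vstart`, `vend` (span on the vector), sorted by
#'   contig and start. Zero rows when nothing is found.
#' @export
detect_vector <- function(contigs, vector_seq, min_identity = 0.9,
                          min_match_len = 50) {
  stopifnot(min_identity >= 0.5, min_identity <= 1)
  if (is.data.frame(vector_seq)) vector_seq <- vector_seq$seq[1]
  stopifnot(nzchar(vector_seq))
  vl <- nchar(vector_seq)
  vrc <- revcomp(vector_seq)

  empty <- tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), identity = numeric(),
                  n_match = integer(), vstart = integer(), vend = integer())

  one_strand <- function(query, target, strand) {
    res <- local_matches(query, target)
    if (is.null(res)) return(NULL)
    res <- res[res$identity >= min_identity &
                 (res$t_end - res$t_start) >= min_match_len, , drop = FALSE]
    if (nrow(res) == 0) return(NULL)
    vs <- res$q_start; ve <- res$q_end
    if (strand == "-") { vs <- vl - res$q_end; ve <- vl - res$q_start }
    tibble(start = res$t_start, end = res$t_end, strand = strand,
           identity = res$identity, n_match = res$n_match,
           vstart = vs, vend = ve)
  }

  out <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    tseq <- contigs$seq[i]
    if (nchar(tseq) < min_match_len) return(NULL)
    hits <- dplyr::bind_rows(one_strand(vector_seq, tseq, "+"),
                             one_strand(vrc, tseq, "-"))
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    # the two strands can rediscover the same locus; keep the better one
    hits <- hits[order(-hits$n_match), ]
    keep <- rep(TRUE, nrow(hits))
    if (nrow(hits) > 1) {
      for (a in seq_len(nrow(hits) - 1)) {
        if (!keep[a]) next
        for (b in seq(a + 1, nrow(hits))) {
          if (!keep[b]) next
          ov <- min(hits$end[a], hits$end[b]) - max(hits$start[a], hits$start[b])
          if (ov > 0.5 * (hits$end[b] - hits$start[b])) keep[b] <- FALSE
        }
      }
    }
    hits <- hits[keep, ]
    hits$contig_id <- contigs$contig_id[i]
    hits[order(hits$start), c("contig_id", "start", "end", "strand",
                              "identity", "n_match", "vstart", "vend")]
  })
  if (nrow(out) == 0) empty else out
}

#' Mask vector matches with X characters
#'
#' Bases inside the union of the match intervals are replaced by `X`;
#' lengths are unchanged. Masking is presentational: the re-organization
#' step works from coordinates, not from the mask.
#'
#' @param contigs A contig tibble.
#' @param matches Match tibble from [detect_vector()].
#' @return The contig tibble with masked sequences.
#' @export
mask_vector <- function(contigs, matches) {
  if (nrow(matches) == 0) return(contigs)
  out <- contigs
  for (i in seq_len(nrow(out))) {
    mm <- matches[matches$contig_id == out$contig_id[i], , drop = FALSE]
    if (nrow(mm) == 0) next
    L <- nchar(out$seq[i])
    stopifnot(all(mm$start >= 0), all(mm$end <= L), all(mm$start < mm$end))
    iv <- IRanges::reduce(IRanges::IRanges(start = mm$start + 1, end = mm$end))
    ch <- strsplit(out$seq[i], "", fixed = TRUE)[[1]]
    for (k in seq_along(iv)) {
      ch[IRanges::start(iv)[k]:IRanges::end(iv)[k]] <- "X"
    }
    out$seq[i] <- paste(ch, collapse = "")
  }
  out
}

#' Filter contigs by length and coverage
#'
#' Retains contigs strictly longer than `min_len` with mean coverage
#' strictly above `min_cov`. Contigs with unknown (NaN) coverage are
#' retained with a warning. Order is preserved.
#'
#' @param contigs A contig tibble with `length` and `mean_cov`.
#' @param min_len Length threshold in bp (default 1000; strict).
#' @param min_cov Coverage threshold in X (default 8; strict).
#' @return The filtered contig tibble.
#' @export
filter_contigs <- function(contigs, min_len = 1000, min_cov = 8) {
  if (nrow(contigs) == 0) return(contigs)
  nan_cov <- is.nan(contigs$mean_cov) | is.na(contigs$mean_cov)
  if (any(nan_cov)) {
    warning(sum(nan_cov), " contig(s) lack a coverage estimate and are ",
            "retained; re-estimate coverage by read mapping")
  }
  keep <- contigs$length > min_len & (nan_cov | contigs$mean_cov > min_cov)
  contigs[keep, ]
}

#' Detect a terminal overlap between two sequence ends
#'
#' Looks for an alignment of a suffix of `right_end` with a prefix of
#' `left_start` (the join test for fosmid circularity). An exact-match fast
#' path is tried first, then an overlap-mode dynamic program.
#'
#' @param right_end,left_start Character sequences.
#' @param min_len Minimum overlap length in bp (default 20).
#' @param min_identity Minimum overlap identity (default 0.95).
#' @param window Maximum window examined at each end (default 1000 bp).
#' @return The overlap length in bp (bases of `left_start` covered), or
#'   `NA_integer_` when no acceptable overlap exists.
#' @export
detect_terminal_overlap <- function(right_end, left_start, min_len = 20,
                                    min_identity = 0.95, window = 1000) {
  w <- min(window, nchar(right_end), nchar(left_start))
  if (w < min_len) return(NA_integer_)
  rs <- substring(right_end, nchar(right_end) - w + 1, nchar(right_end))
  lp <- substring(left_start, 1, w)
  # exact fast path: longest suffix(rs) == prefix(lp)
  for (l in seq(w, min_len)) {
    if (substring(rs, w - l + 1, w) == substring(lp, 1, l)) return(l)
  }
  r <- run_affine(rs, lp, "overlap", match = 1, mismatch = -2,
                  gap_open = 0, gap_ext = 3)
  left_span <- r$t_end
  right_span <- w - r$q_start
  if (left_span >= min_len && right_span >= min_len &&
      r$identity >= min_identity) {
    return(as.integer(left_span))
  }
  NA_integer_
}

#' Re-organize a vector-containing contig for fosmid circularity
#'
#' Removes the detected vector and restores the circular geometry of the
#' clone: a terminal vector hit is trimmed off (the excised span is extended
#' through any residual bases within `end_slack` of the contig end); an
#' internal hit splits the contig into its two flanks, which are joined into
#' a single contig when the end of the right flank overlaps the start of the
#' left flank (the clone's circular join), and otherwise returned as two
#' contigs. A vector occurrence wrapped across both extremities (the
#' assembler opened the circle inside the vector) is trimmed at both ends.
#' Two or more genuinely disjoint internal occurrences are excised
#' conservatively without any join and flagged.
#'
#' @param contig One contig row (tibble with `contig_id`, `seq`, `mean_cov`).
#' @param matches [detect_vector()] rows for this contig.
#' @param min_join_overlap Minimum join overlap in bp (default 20).
#' @param min_join_identity Minimum join overlap identity (default 0.95).
#' @param end_slack Distance (bp) within which a hit counts as terminal
#'   (default 10).
#' @return A list with `case` (one of `no_vector`, `trimmed_extremity`,
#'   `joined_circular`, `split_two`, `multi_excised`), `contigs` (tibble of
#'   output contigs, X-free), `join_overlap_len` and `flagged`.
#' @export
reorganize_contig <- function(contig, matches, min_join_overlap = 20,
                              min_join_identity = 0.95, end_slack = 10) {
  stopifnot(nrow(contig) == 1)
  seq <- contig$seq
  L <- nchar(seq)
  cov <- if ("mean_cov" %in% names(contig)) contig$mean_cov else NA_real_
  out_tbl <- function(ids, seqs) {
    keep <- nchar(seqs) > 0
    contig_tbl(tibble(contig_id = ids[keep], seq = seqs[keep],
                      length = nchar(seqs[keep]), mean_cov = cov,
                      is_cycle = FALSE))
  }
  mm <- matches[matches$contig_id == contig$contig_id, , drop = FALSE]
  if (nrow(mm) == 0) {
    return(list(case = "no_vector", contigs = out_tbl(contig$contig_id, seq),
                join_overlap_len = NA_integer_, flagged = FALSE))
  }
  iv <- IRanges::reduce(IRanges::IRanges(start = mm$start + 1, end = mm$end),
                        min.gapwidth = 20)
  s <- IRanges::start(iv) - 1L  # 0-based half-open
  e <- IRanges::end(iv)
  term_l <- s <= end_slack
  term_r <- e >= L - end_slack

  if (length(s) == 1) {
    if (term_l && term_r) {
      return(list(case = "trimmed_extremity",
                  contigs = out_tbl(character(0), character(0)),
                  join_overlap_len = NA_integer_, flagged = FALSE))
    }
    if (term_l || term_r) {
      res <- if (term_l) substring(seq, e + 1, L) else substring(seq, 1, s)
      return(list(case = "trimmed_extremity",
                  contigs = out_tbl(contig$contig_id, res),
                  join_overlap_len = NA_integer_, flagged = FALSE))
    }
    left <- substring(seq, 1, s)
    right <- substring(seq, e + 1, L)
    ov <- detect_terminal_overlap(right, left, min_len = min_join_overlap,
                                  min_identity = min_join_identity)
    if (!is.na(ov)) {
      joined <- paste0(right, substring(left, ov + 1))
      return(list(case = "joined_circular",
                  contigs = out_tbl(contig$contig_id, joined),
                  join_overlap_len = as.integer(ov), flagged = FALSE))
    }
    return(list(
      case = "split_two",
      contigs = out_tbl(paste0(contig$contig_id, c("_part1", "_part2")),
                        c(left, right)),
      join_overlap_len = NA_integer_, flagged = FALSE))
  }

  if (length(s) == 2 && term_l[1] && !term_r[1] && term_r[2] && !term_l[2]) {
    # single occurrence wrapped across the extremities of an opened circle
    middle <- substring(seq, e[1] + 1, s[2])
    return(list(case = "trimmed_extremity",
                contigs = out_tbl(contig$contig_id, middle),
                join_overlap_len = NA_integer_, flagged = FALSE))
  }

  # >= 2 disjoint occurrences: excise all spans, no join (conservative)
  bounds <- c(0L, as.vector(rbind(s, e)), L)
  pieces <- character(0)
  for (i in seq(1, length(bounds) - 1, by = 2)) {
    pieces <- c(pieces, substring(seq, bounds[i] + 1, bounds[i + 1]))
  }
  list(case = "multi_excised",
       contigs = out_tbl(sprintf("%s_part%d", contig$contig_id,
                                 seq_along(pieces)), pieces),
       join_overlap_len = NA_integer_, flagged = TRUE)
}

#' Re-organize every contig of a set
#'
#' @param contigs A contig tibble.
#' @param matches [detect_vector()] output for these contigs.
#' @inheritParams reorganize_contig
#' @return A list with `contigs` (tibble of all output contigs) and
#'   `outcomes` (tibble with `contig_id`, `case`, `join_overlap_len`,
#'   `flagged`, `n_out`).
#' @export
reorganize_contigs <- function(contigs, matches, min_join_overlap = 20,
                               min_join_identity = 0.95, end_slack = 10) {
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    reorganize_contig(contigs[i, ], matches,
                      min_join_overlap = min_join_overlap,
                      min_join_identity = min_join_identity,
                      end_slack = end_slack)
  })
  outcomes <- purrr::map2_dfr(res, seq_along(res), function(r, i) {
    tibble(contig_id = contigs$contig_id[i], case = r$case,
           join_overlap_len = r$join_overlap_len, flagged = r$flagged,
           n_out = nrow(r$contigs))
  })
  list(contigs = dplyr::bind_rows(lapply(res, `[[`, "contigs")),
       outcomes = outcomes)
}
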