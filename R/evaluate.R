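#' Assembly precision and recall against a reference
#'
#' Each contig is aligned to the reference on both strands
#' (seed-chain-extend local alignments; affine scoring as in
#' [align_pair()]). Secondary alignments reusing more than half of an
#' already-aligned contig region are discarded, so a collapsed repeat in the
#' contig credits only one reference copy. Matched bases are identically
#' matching alignment positions; within a contig and in the aggregate each
#' reference base is credited at most once (interval union), which makes the
#' aggregate independent of contig order.
#'
#' Precision is matched bases over contig length; recall is matched bases
#' over reference length. The aggregate uses the union of matched reference
#' positions over all contigs: precision = sum(matched)/sum(contig length),
#' recall = sum(matched)/reference length.
#'
#' @param contigs A contig tibble.
#' @param reference Reference sequence (string or one-row data frame);
#'   typically the vector-free insert of the truth construct.
#' @return An object of class `assembly_metrics`: list with `per_contig`
#'   (tibble: `contig_id`, `matched_bases`, `contig_len`, `reference_len`,
#'   `precision`, `recall`), `aggregate` (one-row tibble) and `empty` flag.
#' @export
assembly_metrics <- function(contigs, reference) {
  if (is.data.frame(reference)) reference <- reference$seq[1]
  ref_len <- nchar(reference)
  stopifnot(ref_len > 0)
  if (nrow(contigs) == 0) {
    agg <- tibble(matched_bases = 0L, total_contig_len = 0L,
                  reference_len = ref_len, precision = 0, recall = 0)
    return(structure(list(per_contig = tibble(
      contig_id = character(), matched_bases = integer(),
      contig_len = integer(), reference_len = integer(),
      precision = numeric(), recall = numeric()),
      aggregate = agg, empty = TRUE), class = "assembly_metrics"))
  }

  contig_ranges <- function(seq) {
    m <- nchar(seq)
    res <- dplyr::bind_rows(
      local_matches(seq, reference, match = 1, mismatch = -2,
                    gap_open = 4, gap_ext = 1),
      {
        r <- local_matches(revcomp(seq), reference, match = 1, mismatch = -2,
                           gap_open = 4, gap_ext = 1)
        if (!is.null(r)) {  # map query coords back to the forward strand
          qs <- m - r$q_end
          r$q_end <- m - r$q_start
          r$q_start <- qs
        }
        r
      })
    if (is.null(res) || nrow(res) == 0) return(IRanges::IRanges())
    # primary selection: best first, drop alignments reusing > 50% of an
    # already-aligned query interval
    res <- res[order(-res$n_match), ]
    used <- IRanges::IRanges()
    kept <- list()
    for (i in seq_len(nrow(res))) {
      qi <- IRanges::IRanges(res$q_start[i] + 1, res$q_end[i])
      ov <- sum(IRanges::width(IRanges::intersect(used, qi)))
      if (ov > 0.5 * IRanges::width(qi)) next
      used <- IRanges::union(used, qi)
      tm <- res$t_match[[i]]
      if (nrow(tm) > 0) {
        kept[[length(kept) + 1L]] <- IRanges::IRanges(tm[, 1] + 1, tm[, 2])
      }
    }
    if (length(kept) == 0) return(IRanges::IRanges())
    IRanges::reduce(do.call(c, kept))
  }

  ranges <- lapply(contigs$seq, contig_ranges)
  matched <- vapply(ranges, function(r) sum(IRanges::width(r)), 0L)
  per <- tibble(
    contig_id = contigs$contig_id,
    matched_bases = as.integer(matched),
    contig_len = nchar(contigs$seq),
    reference_len = ref_len,
    precision = ifelse(nchar(contigs$seq) > 0, matched / nchar(contigs$seq), 0),
    recall = matched / ref_len
  )
  all_ranges <- IRanges::reduce(do.call(c, ranges))
  tot_matched <- sum(IRanges::width(all_ranges))
  tot_len <- sum(per$contig_len)
  agg <- tibble(matched_bases = as.integer(tot_matched),
                total_contig_len = as.integer(tot_len),
                reference_len = ref_len,
                precision = ifelse(tot_len > 0, tot_matched / tot_len, 0),
                recall = tot_matched / ref_len)
  structure(list(per_contig = per, aggregate = agg, empty = FALSE),
            class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat("<assembly_metrics> ", nrow(x$per_contig), " contig(s), aggregate ",
      sprintf("precision %.4f, recall %.4f\n", x$aggregate$precision,
              x$aggregate$recall), sep = "")
  print(x$per_contig)
  invisible(x)
}

#' Annotation precision and recall
#'
#' A detected CDS is a true positive when its nucleotide sequence aligns to
#' a reference CDS covering that reference from its start to its end
#' position (full-length), with identity at least `min_identity`; each
#' reference CDS is consumed at most once, assigned greedily by identity.
#'
#' The default ratios follow the source convention of this pipeline family:
#' precision = TP / number of reference CDS and recall = TP / number of
#' detected CDS — note these are swapped relative to the usual definitions;
#' set `conventional = TRUE` for precision = TP/detected, recall = TP/reference.
#'
#' @param detected Tibble of detected CDS with columns `cds_id`, `seq`
#'   (nucleotide, coding strand); see [cds_sequences()].
#' @param reference_cds Tibble of reference CDS with `cds_id`, `seq`.
#' @param min_identity Identity floor for a full-length match (default 0.95).
#' @param conventional Swap the ratios to the standard definitions.
#' @return An object of class `annotation_metrics`: list with `n_ref_cds`,
#'   `n_detected`, `n_true_positive`, `precision`, `recall`, `conventional`
#'   and a `pairs` tibble of the TP assignments.
#' @export
annotation_metrics <- function(detected, reference_cds, min_identity = 0.95,
                               conventional = FALSE) {
  n_det <- nrow(detected)
  n_ref <- nrow(reference_cds)
  flagged <- n_det == 0 || n_ref == 0
  pairs <- tibble(detected_id = character(), reference_id = character(),
                  identity = numeric())
  if (!flagged) {
    drc_all <- revcomp(detected$seq)
    # shared 15-mer screen over all pairs at once: only seed-sharing pairs
    # are aligned (pairs at the identity floor always share exact 15-mers)
    sep <- strrep("N", 20)
    concat_ref <- paste(reference_cds$seq, collapse = sep)
    ref_starts <- cumsum(c(0, utils::head(nchar(reference_cds$seq) + 20L, -1)))
    det_starts <- cumsum(c(0, utils::head(nchar(detected$seq) + 20L, -1)))
    pair_hits <- function(det_concat) {
      h <- cpp_seed_hits(concat_ref, det_concat, 15L, 200L)
      if (length(h$qpos) == 0) return(NULL)
      unique(cbind(i = findInterval(h$tpos, det_starts),
                   j = findInterval(h$qpos, ref_starts)))
    }
    shared_ij <- rbind(pair_hits(paste(detected$seq, collapse = sep)),
                       pair_hits(paste(drc_all, collapse = sep)))
    shared_by_i <- if (is.null(shared_ij)) list() else {
      split(shared_ij[, "j"], shared_ij[, "i"])
    }
    ref_by_seq <- split(seq_len(n_ref), reference_cds$seq)
    cand <- list()
    for (i in seq_len(n_det)) {
      dseq <- detected$seq[i]
      drc <- drc_all[i]
      exact <- unique(c(ref_by_seq[[dseq]], ref_by_seq[[drc]]))
      for (j in exact) {
        cand[[length(cand) + 1L]] <- tibble(i = i, j = j, identity = 1)
      }
      shared <- unique(shared_by_i[[as.character(i)]])
      for (j in setdiff(shared, exact)) {
        rseq <- reference_cds$seq[j]
        rl <- nchar(rseq)
        # cheap pre-filter: too short to cover the reference at the identity
        # floor, or so long the pair is clearly unrelated
        if (nchar(dseq) < rl * min_identity || nchar(dseq) > rl * 3) next
        ident <- full_length_identity(dseq, rseq, rl)
        if (is.na(ident)) ident <- full_length_identity(drc, rseq, rl)
        if (!is.na(ident) && ident >= min_identity) {
          cand[[length(cand) + 1L]] <- tibble(i = i, j = j, identity = ident)
        }
      }
    }
    if (length(cand) > 0) {
      cand <- dplyr::bind_rows(cand)
      cand <- cand[order(-cand$identity), ]
      used_i <- logical(n_det); used_j <- logical(n_ref)
      take <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        take[r] <- TRUE
      }
      sel <- cand[take, ]
      pairs <- tibble(detected_id = detected$cds_id[sel$i],
                      reference_id = reference_cds$cds_id[sel$j],
                      identity = sel$identity)
    }
  }
  tp <- nrow(pairs)
  if (flagged) {
    precision <- 0; recall <- 0
  } else if (conventional) {
    precision <- tp / n_det; recall <- tp / n_ref
  } else {
    precision <- tp / n_ref; recall <- tp / n_det
  }
  structure(list(n_ref_cds = n_ref, n_detected = n_det,
                 n_true_positive = tp, precision = precision, recall = recall,
                 conventional = conventional, flagged = flagged,
                 pairs = pairs),
            class = "annotation_metrics")
}

# identity of the best local alignment of det vs ref, required to cover the
# reference end to end; NA when it does not. Seed chains are required: CDS
# pairs near the identity floor always share exact 15-mers, while unrelated
# pairs are dismissed without a dynamic program.
full_length_identity <- function(det, ref, ref_len) {
  res <- local_matches(det, ref, match = 1, mismatch = -2,
                       gap_open = 4, gap_ext = 1, seedless_fallback = FALSE)
  if (is.null(res)) return(NA_real_)
  full <- res[res$t_start == 0 & res$t_end == ref_len, , drop = FALSE]
  if (nrow(full) == 0) return(NA_real_)
  max(full$identity)
}

#' @export
print.annotation_metrics <- function(x, ...) {
  cat("<annotation_metrics> TP ", x$n_true_positive, " of ", x$n_detected,
      " detected vs ", x$n_ref_cds, " reference CDS\n",
      sprintf("  precision %.4f, recall %.4f%s\n", x$precision, x$recall,
              if (x$conventional) " (conventional)" else ""), sep = "")
  invisible(x)
}
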