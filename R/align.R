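# Alignment layer: a full affine-gap DP for small problems and a
# seed (exact k-mer) - chain (co-linear diagonal clusters) - extend
# (banded DP) path for fosmid-scale sequences.

# run one DP and attach identity + absolute offsets
run_affine <- function(query, target, mode, match, mismatch, gap_open,
                       gap_ext, band_lo = NULL, band_hi = NULL) {
  m <- nchar(query); n <- nchar(target)
  if (is.null(band_lo)) band_lo <- -m
  if (is.null(band_hi)) band_hi <- n
  r <- cpp_affine_align(query, target, as.integer(match), as.integer(mismatch),
                        as.integer(gap_open), as.integer(gap_ext), mode,
                        as.integer(band_lo), as.integer(band_hi))
  r$identity <- if (r$n_cols > 0) r$n_match / r$n_cols else 0
  r
}

# cluster seed hits into co-linear chains: split on diagonal jumps, then on
# large positional gaps within a diagonal group
chain_seed_hits <- function(query, target, seed_k = 15, max_occ = 20,
                            diag_tol = 75, max_gap = 2000) {
  h <- cpp_seed_hits(query, target, as.integer(seed_k), as.integer(max_occ))
  if (length(h$qpos) == 0) return(NULL)
  d <- h$tpos - h$qpos
  ord <- order(d, h$qpos)
  q <- h$qpos[ord]; t <- h$tpos[ord]; d <- d[ord]
  grp <- cumsum(c(1L, diff(d) > diag_tol))
  out <- list()
  for (g in split(seq_along(grp), grp)) {
    qs <- q[g]; ts <- t[g]
    o2 <- order(qs)
    qs <- qs[o2]; ts <- ts[o2]
    sub <- cumsum(c(1L, diff(qs) > max_gap))
    for (s in split(seq_along(sub), sub)) {
      out[[length(out) + 1L]] <- tibble(
        qlo = min(qs[s]), qhi = max(qs[s]),
        tlo = min(ts[s]), thi = max(ts[s]),
        dlo = min(ts[s] - qs[s]), dhi = max(ts[s] - qs[s]),
        n_hits = length(s))
    }
  }
  dplyr::bind_rows(out)
}

# local alignments of query against target on the forward strands, possibly
# at several loci: exact-seed chains delimit candidate windows, each aligned
# by a (banded) local DP. Small seedless problems fall back to one full DP.
local_matches <- function(query, target, match = 1, mismatch = -2,
                          gap_open = 0, gap_ext = 3, seed_k = 15,
                          max_occ = 20, min_chain_hits = 2,
                          full_dp_cells = 4e6, pad = 100,
                          seedless_fallback = TRUE) {
  m <- nchar(query); n <- nchar(target)
  if (m == 0 || n == 0) return(NULL)
  as_row <- function(r, toff = 0L) {
    tibble(q_start = r$q_start, q_end = r$q_end,
           t_start = r$t_start + toff, t_end = r$t_end + toff,
           n_match = r$n_match, n_cols = r$n_cols, score = r$score,
           identity = r$identity,
           t_match = list(cbind(r$t_match_start + toff, r$t_match_end + toff)),
           q_match = list(cbind(r$q_match_start, r$q_match_end)))
  }
  chains <- chain_seed_hits(query, target, seed_k = seed_k, max_occ = max_occ)
  if (!is.null(chains)) {
    chains <- chains[chains$n_hits >= min_chain_hits, , drop = FALSE]
  }
  if (is.null(chains) || nrow(chains) == 0) {
    if (seedless_fallback && as.numeric(m) * n <= full_dp_cells) {
      r <- run_affine(query, target, "local", match, mismatch, gap_open,
                      gap_ext)
      if (r$n_match == 0) return(NULL)
      return(as_row(r))
    }
    return(NULL)
  }
  res <- list()
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    tlo <- max(0L, ch$tlo - ch$qlo - pad)
    thi <- min(n, ch$thi + seed_k + (m - ch$qhi - seed_k) + pad)
    twin <- substring(target, tlo + 1, thi)
    band_lo <- ch$dlo - tlo - pad
    band_hi <- ch$dhi - tlo + pad
    if (as.numeric(m) * nchar(twin) <= full_dp_cells) {
      band_lo <- -m; band_hi <- nchar(twin)
    }
    r <- run_affine(query, twin, "local", match, mismatch, gap_open, gap_ext,
                    band_lo, band_hi)
    if (r$n_match == 0) next
    res[[length(res) + 1L]] <- as_row(r, toff = tlo)
  }
  if (length(res) == 0) return(NULL)
  out <- dplyr::bind_rows(res)
  # drop duplicate/contained alignments found from different chains
  out <- out[order(-out$n_match), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in seq(i + 1, nrow(out))) {
        if (!keep[j]) next
        qo <- min(out$q_end[i], out$q_end[j]) - max(out$q_start[i], out$q_start[j])
        to <- min(out$t_end[i], out$t_end[j]) - max(out$t_start[i], out$t_start[j])
        jq <- out$q_end[j] - out$q_start[j]
        jt <- out$t_end[j] - out$t_start[j]
        if (qo > 0.5 * jq && to > 0.5 * jt) keep[j] <- FALSE
      }
    }
  }
  out[keep, ]
}

#' Align two sequences and count matching bases
#'
#' Affine-gap alignment (match +1, mismatch -2, gap open -4, gap extend -1
#' by default; a gap of length g costs open + g * extend). The query strand
#' is chosen as the better of forward and reverse complement. Small problems
#' run a full dynamic program; larger ones are banded around exact-seed
#' chains. Global mode aligns end to end; local mode reports the single best
#' local alignment.
#'
#' @param query,target Character DNA sequences (fosmid scale, <= 100 kb).
#' @param mode `"global"` or `"local"`.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @param both_strands Also try the reverse complement of `query`.
#' @return A list of class `pairwise_alignment` with `score`, `strand`,
#'   `n_match` (identically matching bases), `n_cols` (alignment columns),
#'   `identity`, `q_start`/`q_end`/`t_start`/`t_end` (0-based half-open,
#'   query coordinates on its forward strand) and `blocks`, a tibble of
#'   exact-match runs with target and query intervals.
#' @export
align_pair <- function(query, target, mode = c("global", "local"),
                       match = 1, mismatch = -2, gap_open = 4, gap_ext = 1,
                       both_strands = TRUE) {
  mode <- match.arg(mode)
  if (!nzchar(query) || !nzchar(target)) stop("cannot align an empty sequence")
  m <- nchar(query); n <- nchar(target)

  one <- function(q) {
    if (as.numeric(m) * n <= 2.5e7) {
      return(run_affine(q, target, mode, match, mismatch, gap_open, gap_ext))
    }
    ch <- chain_seed_hits(q, target)
    if (is.null(ch)) {
      stop("sequences too large for a full alignment and no seed chain found")
    }
    run_affine(q, target, mode, match, mismatch, gap_open, gap_ext,
               band_lo = min(ch$dlo) - 200, band_hi = max(ch$dhi) + 200)
  }

  fw <- one(query)
  res <- fw; strand <- "+"
  if (both_strands) {
    rv <- one(revcomp(query))
    if (rv$score > fw$score) { res <- rv; strand <- "-" }
  }
  blocks <- tibble(
    t_start = res$t_match_start, t_end = res$t_match_end,
    q_start = res$q_match_start, q_end = res$q_match_end
  )
  qs <- res$q_start; qe <- res$q_end
  if (strand == "-") {  # report query coords on the forward strand
    blocks$q_start2 <- m - blocks$q_end
    blocks$q_end <- m - blocks$q_start
    blocks$q_start <- blocks$q_start2
    blocks$q_start2 <- NULL
    qs <- m - res$q_end; qe <- m - res$q_start
  }
  structure(list(
    score = res$score, strand = strand, n_match = res$n_match,
    n_cols = res$n_cols,
    identity = if (res$n_cols > 0) res$n_match / res$n_cols else 0,
    q_start = qs, q_end = qe, t_start = res$t_start, t_end = res$t_end,
    blocks = blocks
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", x$score, ", strand ", x$strand,
      ", matched ", x$n_match, "/", x$n_cols,
      sprintf(" (identity %.4f)\n", x$identity),
      "  query [", x$q_start, ", ", x$q_end, ") x target [",
      x$t_start, ", ", x$t_end, ")\n", sep = "")
  invisible(x)
}
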