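#' Estimate read-set coverage
#'
#' Coverage is the summed read length (both mates counted) divided by the
#' expected insert length. The default expected length is 40 kb, the nominal
#' fosmid insert size.
#'
#' @param reads A [read_set()] tibble.
#' @param expected_len Expected sequence length in bp.
#' @return Coverage as a single numeric (X). An empty read set returns 0
#'   with a warning.
#' @export
estimate_coverage <- function(reads, expected_len = 40000) {
  stopifnot(expected_len > 0)
  if (nrow(reads) == 0) {
    warning("empty read set: coverage is 0")
    return(0)
  }
  sum(nchar(reads$seq)) / expected_len
}

#' Filter poor-quality reads
#'
#' Removes reads with mean phred below `min_mean_q`, an N fraction above
#' `max_n_frac`, or length below `min_len`. In a paired layout the pair is
#' dropped if either mate fails, preserving pair integrity. Input order is
#' preserved.
#'
#' @param reads A [read_set()] tibble.
#' @param min_mean_q Minimum mean phred quality (default 20).
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.1).
#' @param min_len Minimum read length in bp (default 50).
#' @return The filtered [read_set()].
#' @export
filter_reads <- function(reads, min_mean_q = 20, max_n_frac = 0.1,
                         min_len = 50) {
  stopifnot(min_mean_q >= 0, max_n_frac >= 0, min_len >= 0)
  if (nrow(reads) == 0) return(reads)
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0) {
    stop("malformed read record at index ", bad[1],
         ": sequence and quality lengths differ")
  }
  len <- nchar(reads$seq)
  meanq <- cpp_mean_phred(reads$qual)
  nfrac <- ifelse(len > 0, stringr::str_count(reads$seq, "N") / len, 1)
  pass <- !is.na(meanq) & meanq >= min_mean_q & nfrac <= max_n_frac &
    len >= min_len
  paired <- !is.na(reads$pair_id)
  if (any(paired)) {
    ok_pairs <- tapply(pass[paired], reads$pair_id[paired], all)
    pass[paired] <- as.logical(ok_pairs[as.character(reads$pair_id[paired])])
  }
  reads[pass, ]
}

#' Randomly subsample a read set to a target coverage
#'
#' If the estimated coverage is already at or below the target the set is
#' returned unchanged. Otherwise sampling units (pairs stay together) are
#' drawn uniformly without replacement until their summed length reaches
#' `target_cov * expected_len`; the selection keeps the original read order.
#'
#' @param reads A [read_set()] tibble.
#' @param target_cov Target coverage in X (default 300).
#' @param expected_len Expected sequence length in bp (default 40000).
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @return The subsampled [read_set()].
#' @export
subsample_reads <- function(reads, target_cov = 300, expected_len = 40000,
                            seed = 1) {
  stopifnot(target_cov > 0)
  est <- suppressWarnings(estimate_coverage(reads, expected_len))
  if (est <= target_cov) return(reads)

  unit <- ifelse(is.na(reads$pair_id), paste0("s", seq_len(nrow(reads))),
                 paste0("p", reads$pair_id))
  units <- unique(unit)
  unit_len <- tapply(nchar(reads$seq), unit, sum)[units]
  need <- target_cov * expected_len

  keep_units <- withr::with_seed(seed, {
    perm <- sample(seq_along(units))
    cum <- cumsum(unit_len[perm])
    take <- perm[seq_len(which(cum >= need)[1])]
    units[take]
  })
  reads[unit %in% keep_units, ]
}
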