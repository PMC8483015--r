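#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases; a stand-in for a real host genome when simulating
#' fosmid constructs at desk scale.
#'
#' @param length Genome length in bp.
#' @param id Sequence id.
#' @param gc GC content in \[0, 1\].
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with columns `id`, `seq`.
#' @export
random_genome <- function(length, id = "genome", gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  draw <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }
  seq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(id = id, seq = seq)
}

#' Extract random genomic chunks
#'
#' Samples fixed-length windows uniformly (with replacement) over all valid
#' start positions; chunks may overlap each other. Source coordinates are
#' 0-based half-open.
#'
#' @param genome A one-row data frame with columns `id`, `seq`, or a list
#'   with those elements.
#' @param n_chunks Number of chunks to draw.
#' @param chunk_len Chunk length in bp (default 40000, the nominal fosmid
#'   insert size).
#' @param seed Integer seed; extraction is deterministic given the seed.
#' @return A tibble with columns `chunk_id`, `seq`, `genome_id`, `start`,
#'   `end`.
#' @export
extract_chunks <- function(genome, n_chunks, chunk_len = 40000, seed = 1) {
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1)
    genome <- as.list(genome[1, ])
  }
  gl <- nchar(genome$seq)
  if (gl < chunk_len) {
    stop("genome '", genome$id, "' is ", gl, " bp, shorter than chunk_len = ",
         chunk_len, " bp")
  }
  stopifnot(n_chunks >= 1)
  check_dna(genome$seq, paste0("genome '", genome$id, "'"))
  starts <- withr::with_seed(seed, {
    sample.int(gl - chunk_len + 1L, n_chunks, replace = TRUE) - 1L
  })
  tibble(
    chunk_id = sprintf("%s_chunk%02d", genome$id, seq_len(n_chunks)),
    seq = substring(genome$seq, starts + 1L, starts + chunk_len),
    genome_id = genome$id,
    start = starts,
    end = starts + chunk_len
  )
}

#' Build a linear reference fosmid construct
#'
#' Inserts the cloning vector into a genomic chunk, either at one of the
#' extremities or internally. Internal insertions additionally append a copy
#' of the first `overlap_len` bases to the end of the sequence, mimicking the
#' circularity of the clone (reads can then span the join). All coordinates
#' are 0-based half-open on `full_seq`.
#'
#' @param chunk Either a chunk character string or a one-row tibble from
#'   [extract_chunks()].
#' @param vector_seq Cloning-vector sequence (character string, or a one-row
#'   data frame with a `seq` column).
#' @param mode One of `"random"`, `"extremity_left"`, `"extremity_right"`,
#'   `"internal"`.
#' @param insertion_pos Internal insertion offset into the chunk
#'   (0 < pos < chunk length); drawn at random when `NULL`.
#' @param overlap_len Terminal overlap for internal mode (default 500 bp);
#'   forced to 0 for extremity modes.
#' @param construct_id Id recorded on the construct.
#' @param seed Integer seed used when mode or position is random.
#' @return An object of class `fosmid_construct`: a list with fields
#'   `construct_id`, `insert_seq`, `vector_seq`, `insertion_mode`,
#'   `insertion_pos`, `overlap_len`, `full_seq`, `source` and
#'   `vector_interval` (0-based half-open on `full_seq`).
#' @export
build_construct <- function(chunk, vector_seq, mode = "random",
                            insertion_pos = NULL, overlap_len = 500,
                            construct_id = NULL, seed = 1) {
  source <- list(genome_id = NA_character_, start = NA_integer_,
                 end = NA_integer_)
  if (is.data.frame(chunk)) {
    stopifnot(nrow(chunk) == 1)
    source <- list(genome_id = chunk$genome_id, start = chunk$start,
                   end = chunk$end)
    if (is.null(construct_id)) construct_id <- chunk$chunk_id
    chunk <- chunk$seq
  }
  if (is.data.frame(vector_seq)) vector_seq <- vector_seq$seq[1]
  if (is.null(construct_id)) construct_id <- "construct"
  cl <- nchar(chunk); vl <- nchar(vector_seq)
  stopifnot(cl > 0, vl > 0, overlap_len >= 0, overlap_len <= cl)

  mode <- match.arg(mode, c("random", "extremity_left", "extremity_right",
                            "internal"))
  pick <- withr::with_seed(seed, {
    m <- if (mode == "random") {
      sample(c("extremity_left", "extremity_right", "internal"), 1)
    } else mode
    p <- insertion_pos
    if (m == "internal" && is.null(p)) p <- sample.int(cl - 1L, 1)
    list(mode = m, pos = p)
  })
  mode <- pick$mode

  if (mode == "extremity_left") {
    full <- paste0(vector_seq, chunk)
    vint <- c(0L, vl)
    overlap_len <- 0L
    pos <- NA_integer_
  } else if (mode == "extremity_right") {
    full <- paste0(chunk, vector_seq)
    vint <- c(cl, cl + vl)
    overlap_len <- 0L
    pos <- NA_integer_
  } else {
    pos <- as.integer(pick$pos)
    if (is.na(pos) || pos <= 0L || pos >= cl) {
      stop("internal insertion_pos must satisfy 0 < pos < ", cl,
           " (an extremity insertion is a separate mode)")
    }
    linear <- paste0(substring(chunk, 1, pos), vector_seq,
                     substring(chunk, pos + 1, cl))
    if (overlap_len > nchar(linear)) {
      stop("overlap_len (", overlap_len, ") exceeds the linear construct (",
           nchar(linear), " bp)")
    }
    full <- paste0(linear, substring(linear, 1, overlap_len))
    vint <- c(pos, pos + vl)
  }

  structure(
    list(construct_id = construct_id, insert_seq = chunk,
         vector_seq = vector_seq, insertion_mode = mode,
         insertion_pos = pos, overlap_len = as.integer(overlap_len),
         full_seq = full, source = source,
         vector_interval = as.integer(vint)),
    class = "fosmid_construct"
  )
}

#' @export
print.fosmid_construct <- function(x, ...) {
  cat("<fosmid_construct> ", x$construct_id, "\n",
      "  mode: ", x$insertion_mode,
      if (!is.na(x$insertion_pos)) paste0(" @ ", x$insertion_pos), "\n",
      "  insert ", nchar(x$insert_seq), " bp + vector ",
      nchar(x$vector_seq), " bp",
      if (x$overlap_len > 0) paste0(" + ", x$overlap_len, " bp overlap"),
      " = ", nchar(x$full_seq), " bp\n",
      "  vector at [", x$vector_interval[1], ", ", x$vector_interval[2],
      ")\n", sep = "")
  invisible(x)
}

#' Describe a read-simulation profile
#'
#' @param layout `"paired"` or `"single"`.
#' @param read_len Read length in bp (default 150).
#' @param fragment_mean,fragment_sd Paired-end fragment length distribution
#'   (Normal, truncated to \[read_len, construct length\]).
#' @param coverage Target fold coverage (default 1000 paired / 500 single,
#'   matching common high-coverage fosmid designs).
#' @param subst_error_rate Per-base substitution error rate in \[0, 1).
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A list of class `read_profile`.
#' @export
read_profile <- function(layout = c("paired", "single"), read_len = 150,
                         fragment_mean = 200, fragment_sd = 10,
                         coverage = NULL, subst_error_rate = 0, seed = 1) {
  layout <- match.arg(layout)
  if (is.null(coverage)) coverage <- if (layout == "paired") 1000 else 500
  stopifnot(read_len > 0, coverage > 0, fragment_mean > 0, fragment_sd >= 0,
            subst_error_rate >= 0, subst_error_rate < 1)
  structure(list(layout = layout, read_len = as.integer(read_len),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 coverage = coverage, subst_error_rate = subst_error_rate,
                 seed = as.integer(seed)),
            class = "read_profile")
}

#' Simulate sequencing reads from a fosmid construct
#'
#' A simple uniform-shotgun simulator with a substitution-only error model
#' and fixed quality strings. Paired fragments are drawn with
#' Normal(fragment_mean, fragment_sd) lengths clamped to
#' \[read_len, construct length\]; mate 2 is the reverse complement of the
#' fragment end, and fragment strand is sampled so mates appear on both
#' strands. Read count n satisfies n * read_len >= coverage * length.
#'
#' @param construct A [build_construct()] object (or a character sequence).
#' @param profile A [read_profile()].
#' @return A [read_set()] tibble; the profile and construct id are attached
#'   as attributes `profile` and `construct_id`.
#' @export
simulate_reads <- function(construct, profile = read_profile()) {
  if (is.character(construct)) {
    construct <- list(construct_id = "seq", full_seq = construct)
  }
  full <- construct$full_seq
  L <- nchar(full)
  rl <- profile$read_len
  if (L < rl) stop("construct (", L, " bp) shorter than read length ", rl)
  qual_char <- "F"  # phred 37

  withr::with_seed(profile$seed, {
    if (profile$layout == "paired") {
      n_pairs <- ceiling(profile$coverage * L / (2 * rl))
      if (n_pairs < 1) stop("coverage too low: no read pairs to simulate")
      frag <- round(rnorm(n_pairs, profile$fragment_mean, profile$fragment_sd))
      frag <- pmin(pmax(frag, rl), L)
      starts <- floor(runif(n_pairs) * (L - frag + 1))
      m1 <- substring(full, starts + 1, starts + rl)
      m2 <- revcomp(substring(full, starts + frag - rl + 1, starts + frag))
      # a minus-strand fragment swaps the mate roles exactly
      flip <- runif(n_pairs) < 0.5
      if (any(flip)) {
        tmp <- m1[flip]
        m1[flip] <- m2[flip]
        m2[flip] <- tmp
      }
      m1 <- cpp_add_substitutions(m1, profile$subst_error_rate)
      m2 <- cpp_add_substitutions(m2, profile$subst_error_rate)
      ids <- sprintf("%s_p%06d", construct$construct_id, seq_len(n_pairs))
      reads <- read_set(
        id = c(rbind(ids, ids)),
        seq = c(rbind(m1, m2)),
        qual = strrep(qual_char, rl),
        mate = rep(c(1L, 2L), n_pairs),
        pair_id = rep(seq_len(n_pairs), each = 2L)
      )
    } else {
      n <- ceiling(profile$coverage * L / rl)
      if (n < 1) stop("coverage too low: no reads to simulate")
      starts <- floor(runif(n) * (L - rl + 1))
      sq <- substring(full, starts + 1, starts + rl)
      rev <- runif(n) < 0.5
      if (any(rev)) sq[rev] <- revcomp(sq[rev])
      sq <- cpp_add_substitutions(sq, profile$subst_error_rate)
      reads <- read_set(
        id = sprintf("%s_s%06d", construct$construct_id, seq_len(n)),
        seq = sq,
        qual = strrep(qual_char, rl),
        mate = 0L
      )
    }
    attr(reads, "profile") <- profile
    attr(reads, "construct_id") <- construct$construct_id
    reads
  })
}

#' Write a truth manifest for simulated constructs
#'
#' Records, per construct, the insertion mode and position, overlap length,
#' vector interval on the full sequence, genomic source coordinates, and both
#' the full and insert sequences, so that downstream evaluation can pick
#' either reference.
#'
#' @param constructs A list of [build_construct()] objects.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_manifest <- function(constructs, path) {
  recs <- lapply(constructs, function(cs) {
    list(construct_id = cs$construct_id,
         insertion_mode = cs$insertion_mode,
         insertion_pos = cs$insertion_pos,
         overlap_len = cs$overlap_len,
         vector_interval = cs$vector_interval,
         source = cs$source,
         insert_len = nchar(cs$insert_seq),
         full_len = nchar(cs$full_seq),
         insert_seq = cs$insert_seq,
         full_seq = cs$full_seq)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth manifest written by [write_truth_manifest()]
#'
#' @param path JSON path.
#' @return A list of construct truth records.
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Simulate a batch of fosmid constructs with reads and truth
#'
#' High-level generator emulating a simulated fosmid study: chunks are
#' extracted from the supplied genomes (round-robin), the vector is inserted
#' at a random position (extremity or internal with a terminal overlap), and
#' reads are simulated per construct.
#'
#' @param genomes Tibble of genomes (columns `id`, `seq`).
#' @param vector_seq Cloning-vector sequence (string or one-row data frame).
#' @param n_constructs Total constructs to simulate.
#' @param chunk_len Chunk length (default 40000 bp).
#' @param mode Insertion mode passed to [build_construct()].
#' @param overlap_len Internal-mode terminal overlap (default 500 bp).
#' @param profile A [read_profile()]; its seed is re-derived per construct.
#' @param seed Master seed.
#' @param out_dir Optional directory: writes per-construct FASTQ files,
#'   `constructs.fasta` and `truth.json`.
#' @return A list with `constructs` (list), `read_sets` (named list of
#'   [read_set()]), and `truth` (tibble summary).
#' @export
simulate_fosmid_set <- function(genomes, vector_seq, n_constructs = 15,
                                chunk_len = 40000, mode = "random",
                                overlap_len = 500,
                                profile = read_profile("paired", coverage = 300),
                                seed = 1, out_dir = NULL) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1)
  sub_seeds <- withr::with_seed(seed, sample.int(2^30, n_constructs * 2))
  gi <- rep(seq_len(nrow(genomes)), length.out = n_constructs)

  constructs <- vector("list", n_constructs)
  read_sets <- vector("list", n_constructs)
  for (i in seq_len(n_constructs)) {
    g <- genomes[gi[i], ]
    chunk <- extract_chunks(g, 1, chunk_len, seed = sub_seeds[2 * i - 1])
    chunk$chunk_id <- sprintf("fosmid%02d_%s", i, g$id)
    cs <- build_construct(chunk, vector_seq, mode = mode,
                          overlap_len = overlap_len,
                          seed = sub_seeds[2 * i])
    prof <- profile
    prof$seed <- sub_seeds[2 * i] %% 2^30 + i
    constructs[[i]] <- cs
    read_sets[[i]] <- simulate_reads(cs, prof)
  }
  names(read_sets) <- vapply(constructs, `[[`, "", "construct_id")

  truth <- purrr::map_dfr(constructs, function(cs) {
    tibble(construct_id = cs$construct_id, mode = cs$insertion_mode,
           insertion_pos = cs$insertion_pos, overlap_len = cs$overlap_len,
           vector_start = cs$vector_interval[1],
           vector_end = cs$vector_interval[2],
           genome_id = cs$source$genome_id, source_start = cs$source$start,
           source_end = cs$source$end,
           insert_len = nchar(cs$insert_seq), full_len = nchar(cs$full_seq))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(tibble(id = names(read_sets),
                       seq = vapply(constructs, `[[`, "", "full_seq")),
                file.path(out_dir, "constructs.fasta"))
    write_truth_manifest(constructs, file.path(out_dir, "truth.json"))
    for (nm in names(read_sets)) {
      rs <- read_sets[[nm]]
      if (read_set_layout(rs) == "paired") {
        write_fastq(rs, file.path(out_dir, paste0(nm, "_R1.fastq.gz")),
                    file.path(out_dir, paste0(nm, "_R2.fastq.gz")))
      } else {
        write_fastq(rs, file.path(out_dir, paste0(nm, "_single.fastq.gz")))
      }
    }
  }
  list(constructs = constructs, read_sets = read_sets, truth = truth)
}
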