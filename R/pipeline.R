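#' Pipeline configuration
#'
#' Central defaults for the assembly pipeline. Every value can be overridden
#' by argument, or loaded from a YAML key/value file with [read_config()].
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `fosmid_config`.
#' @details Defaults: `coverage = 300` (subsampling target, X),
#'   `expected_len = 40000` (nominal insert, bp), read filters
#'   `min_mean_q = 20`, `max_n_frac = 0.1`, `min_read_len = 50`;
#'   `assembler = "builtin"` with `k = 31`, `min_count = 10`
#'   (`external_cmd` used when `assembler = "external"`); vector detection
#'   `min_identity = 0.9`, `min_match_len = 50`; contig filter
#'   `min_contig_len = 1000`, `min_contig_cov = 8` (both strict);
#'   circular join `min_join_overlap = 20`, `min_join_identity = 0.95`,
#'   `end_slack = 10`; `seed = 1`.
#' @export
fosmid_config <- function(...) {
  cfg <- list(
    coverage = 300, expected_len = 40000,
    min_mean_q = 20, max_n_frac = 0.1, min_read_len = 50,
    assembler = "builtin", external_cmd = NULL, k = 31, min_count = 10,
    min_identity = 0.9, min_match_len = 50,
    min_contig_len = 1000, min_contig_cov = 8,
    min_join_overlap = 20, min_join_identity = 0.95, end_slack = 10,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "fosmid_config")
}

#' Read a YAML configuration file
#'
#' @param path YAML file of key/value overrides.
#' @param ... Further overrides applied after the file.
#' @return A [fosmid_config()] object.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(fosmid_config, vals)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Collect FASTQ samples from a directory
#'
#' Scans for `SAMPLE_R1.fastq[.gz]` / `SAMPLE_R2.fastq[.gz]` pairs and
#' `SAMPLE_single.fastq[.gz]` files.
#'
#' @param dir Directory to scan.
#' @return A tibble with columns `sample`, `r1`, `r2`, `single`.
#' @export
collect_samples <- function(dir) {
  fq <- list.files(dir, pattern = "\\.(fastq|fq)(\\.gz)?$", full.names = TRUE)
  base <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fq))
  sample <- sub("_(R1|R2|single)$", "", base)
  kind <- stringr::str_match(base, "_(R1|R2|single)$")[, 2]
  kind[is.na(kind)] <- "single"
  tb <- tibble(sample = sample, kind = kind, path = fq)
  out <- tidyr::pivot_wider(tb, names_from = "kind", values_from = "path")
  for (col in c("r1", "r2", "single")) {
    src <- c(r1 = "R1", r2 = "R2", single = "single")[[col]]
    out[[col]] <- if (src %in% names(out)) out[[src]] else NA_character_
  }
  out[, c("sample", "r1", "r2", "single")]
}

# 0-based half-open <-> 1-based inclusive (GFF/report) conversion: the single
# crossing point between internal and external coordinate conventions
to_gff_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}
from_gff_coords <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

#' Run the assembly pipeline on a batch of samples
#'
#' Per sample: quality filtering, subsampling to the target coverage,
#' assembly (built-in or external), vector detection and masking, contig
#' filtering, vector removal with circularity-aware re-organization. A
#' failing sample is recorded and skipped, never fatal to the batch.
#' Outputs (per-sample cleaned FASTA, masked FASTA, vector GFF3, pooled
#' `assembled.fasta`, `manifest.json`, `report.html`) are written under
#' `out_dir`.
#'
#' @param samples Tibble with columns `sample`, `r1`, `r2`, `single`
#'   (see [collect_samples()]), or a directory path to scan.
#' @param vector_fasta Path to the cloning-vector FASTA.
#' @param out_dir Output directory.
#' @param config A [fosmid_config()].
#' @return An object of class `fosmid_run` (the run manifest).
#' @export
run_assemble <- function(samples, vector_fasta, out_dir,
                         config = fosmid_config()) {
  if (is.character(samples) && length(samples) == 1) {
    samples <- collect_samples(samples)
  }
  stopifnot(nrow(samples) >= 1)
  vec <- read_fasta(vector_fasta)
  stopifnot(nrow(vec) >= 1, nzchar(vec$seq[1]))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- vector("list", nrow(samples))
  pooled <- list()
  for (i in seq_len(nrow(samples))) {
    sm <- samples$sample[i]
    rec <- list(sample = sm, status = "ok", error = NULL)
    res <- tryCatch({
      has_r1 <- "r1" %in% names(samples) && !is.na(samples$r1[i])
      has_single <- "single" %in% names(samples) && !is.na(samples$single[i])
      reads <- if (has_r1) {
        r2 <- if ("r2" %in% names(samples) && !is.na(samples$r2[i]))
          samples$r2[i] else NULL
        rd <- read_fastq(samples$r1[i], r2)
        if (has_single) {
          rd <- dplyr::bind_rows(rd, read_fastq(samples$single[i]))
        }
        rd
      } else if (has_single) {
        read_fastq(samples$single[i])
      } else {
        stop("sample ", sm, " has no FASTQ files")
      }
      rec$reads_in <- nrow(reads)
      rec$coverage_in <- estimate_coverage(reads, config$expected_len)

      reads <- filter_reads(reads, config$min_mean_q, config$max_n_frac,
                            config$min_read_len)
      if (nrow(reads) == 0) stop("all reads removed by quality filtering")
      reads <- subsample_reads(reads, config$coverage, config$expected_len,
                               seed = config$seed + i)
      rec$reads_used <- nrow(reads)
      rec$coverage_used <- estimate_coverage(reads, config$expected_len)

      contigs <- if (identical(config$assembler, "external")) {
        run_external_assembler(config$external_cmd,
                               r1 = samples$r1[i],
                               r2 = if ("r2" %in% names(samples)) samples$r2[i] else NULL,
                               single = samples$single[i])
      } else {
        assemble_reads(reads, k = config$k, min_count = config$min_count)
      }
      rec$contigs_raw <- nrow(contigs)
      if (nrow(contigs) == 0) stop("assembly produced no contigs")

      matches <- detect_vector(contigs, vec$seq[1],
                               min_identity = config$min_identity,
                               min_match_len = config$min_match_len)
      masked <- mask_vector(contigs, matches)
      kept <- filter_contigs(contigs, config$min_contig_len,
                             config$min_contig_cov)
      rec$contigs_kept <- nrow(kept)
      reorg <- reorganize_contigs(kept, matches,
                                  min_join_overlap = config$min_join_overlap,
                                  min_join_identity = config$min_join_identity,
                                  end_slack = config$end_slack)
      final <- reorg$contigs
      if (nrow(final) > 0) {
        final$contig_id <- paste0(sm, "_", final$contig_id)
      }
      rec$contigs_final <- nrow(final)
      rec$vector_cases <- as.list(setNames(reorg$outcomes$case,
                                           reorg$outcomes$contig_id))

      masked_path <- file.path(out_dir, paste0(sm, "_masked.fasta"))
      write_fasta(masked, masked_path)
      gff_path <- file.path(out_dir, paste0(sm, "_vector.gff3"))
      gl <- c("##gff-version 3")
      if (nrow(matches) > 0) {
        g <- to_gff_coords(matches$start, matches$end)
        gl <- c(gl, sprintf(
          "%s\tfosmidr\tvector_region\t%d\t%d\t.\t%s\t.\tNote=%s;identity=%.4f",
          matches$contig_id, g$start, g$end, matches$strand,
          gff3_escape(vec$id[1]), matches$identity))
      }
      writeLines(gl, gff_path)
      final_path <- file.path(out_dir, paste0(sm, "_assembled.fasta"))
      write_fasta(final, final_path)

      rec$files <- list(masked = masked_path, vector_gff = gff_path,
                        assembled = final_path)
      rec$contig_table <- final[, c("contig_id", "length", "mean_cov")]
      pooled[[sm]] <- final
      rec
    }, error = function(e) {
      rec$status <- "failed"
      rec$error <- conditionMessage(e)
      rec
    })
    records[[i]] <- res
  }

  pooled_tbl <- dplyr::bind_rows(pooled)
  pooled_path <- file.path(out_dir, "assembled.fasta")
  write_fasta(pooled_tbl, pooled_path)

  run <- structure(list(
    run_id = sprintf("fosmidr_%s", format(Sys.time(), "%Y%m%d_%H%M%S")),
    parameters = unclass(config),
    vector = list(id = vec$id[1], length = nchar(vec$seq[1]),
                  path = vector_fasta),
    samples = records,
    pooled_fasta = pooled_path,
    out_dir = out_dir,
    version = as.character(utils::packageVersion("fosmidr"))
  ), class = "fosmid_run")

  # file checksums for reproducibility checks (manifest written last)
  files <- unlist(lapply(records, function(r) unlist(r$files)))
  files <- c(files, pooled_path)
  run$checksums <- as.list(tools::md5sum(files[file.exists(files)]))

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass_deep(run), manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  run$manifest_path <- manifest_path
  build_report(run, file.path(out_dir, "report.html"))
  run
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' @export
print.fosmid_run <- function(x, ...) {
  ok <- vapply(x$samples, function(s) identical(s$status, "ok"), TRUE)
  cat("<fosmid_run> ", x$run_id, ": ", sum(ok), "/", length(ok),
      " samples assembled -> ", x$out_dir, "\n", sep = "")
  invisible(x)
}

#' Annotate assembled contigs
#'
#' Runs the ORF caller on cleaned contigs and writes GFF3 and protein FASTA
#' (plus an annotation report when `report = TRUE`). An external homology
#' hit table (tab-separated: query, subject, identity, evalue, bitscore,
#' description) may be attached.
#'
#' @param contigs A contig tibble or path to a FASTA of cleaned contigs.
#' @param out_dir Output directory.
#' @param min_aa_len Minimum ORF length in codons (default 100).
#' @param genetic_code NCBI genetic code id (default `"11"`).
#' @param hits_tsv Optional path to an external hit table.
#' @param report Write `annotation_report.html`.
#' @return A list with `features`, `gff`, `faa` paths.
#' @export
run_annotate <- function(contigs, out_dir, min_aa_len = 100,
                         genetic_code = "11", hits_tsv = NULL,
                         report = TRUE) {
  if (is.character(contigs)) {
    fa <- read_fasta(contigs)
    contigs <- contig_tbl(tibble(contig_id = fa$id, seq = fa$seq,
                                 length = nchar(fa$seq), mean_cov = NaN,
                                 is_cycle = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- NULL
  if (!is.null(hits_tsv)) {
    hits <- utils::read.delim(hits_tsv, header = TRUE,
                              stringsAsFactors = FALSE)
  }
  features <- find_orfs(contigs, min_aa_len = min_aa_len,
                        genetic_code = genetic_code)
  gff <- file.path(out_dir, "annotation.gff3")
  faa <- file.path(out_dir, "proteins.faa")
  write_annotation(contigs, features, gff, faa, hits = hits)
  if (report) {
    build_annotation_report(contigs, features,
                            file.path(out_dir, "annotation_report.html"))
  }
  list(features = features, gff = gff, faa = faa)
}
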