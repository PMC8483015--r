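#' Tidy a fosmid run manifest into a per-sample tibble
#'
#' @param x A `fosmid_run` from [run_assemble()].
#' @param ... Unused.
#' @return One row per sample: status, read and contig counts, coverage
#'   before/after subsampling, and the vector re-organization cases.
#' @importFrom generics tidy
#' @export
#' @export tidy
tidy.fosmid_run <- function(x, ...) {
  purrr::map_dfr(x$samples, function(s) {
    tibble(sample = s$sample, status = s$status,
           reads_in = s$reads_in %||% NA_integer_,
           reads_used = s$reads_used %||% NA_integer_,
           coverage_in = s$coverage_in %||% NA_real_,
           coverage_used = s$coverage_used %||% NA_real_,
           contigs_raw = s$contigs_raw %||% NA_integer_,
           contigs_kept = s$contigs_kept %||% NA_integer_,
           contigs_final = s$contigs_final %||% NA_integer_,
           vector_case = paste(unlist(s$vector_cases %||% list(NA_character_)),
                               collapse = ","))
  })
}

#' Summarise a fosmid run in one row
#'
#' @param x A `fosmid_run`.
#' @param ... Unused.
#' @return A one-row tibble: sample counts, failure count, single-contig
#'   count and total final contigs.
#' @importFrom generics glance
#' @export
#' @export glance
glance.fosmid_run <- function(x, ...) {
  tb <- tidy(x)
  tibble(n_samples = nrow(tb),
         n_failed = sum(tb$status != "ok"),
         n_single_contig = sum(tb$contigs_final == 1, na.rm = TRUE),
         n_contigs_total = sum(tb$contigs_final, na.rm = TRUE))
}

#' Tidy assembly metrics
#'
#' @param x An `assembly_metrics` object.
#' @param ... Unused.
#' @return The per-contig metric tibble.
#' @export
tidy.assembly_metrics <- function(x, ...) x$per_contig

#' One-row summary of assembly metrics
#'
#' @param x An `assembly_metrics` object.
#' @param ... Unused.
#' @return The aggregate tibble (matched bases, precision, recall).
#' @export
glance.assembly_metrics <- function(x, ...) x$aggregate

#' Tidy annotation metrics
#'
#' @param x An `annotation_metrics` object.
#' @param ... Unused.
#' @return The true-positive assignment pairs.
#' @export
tidy.annotation_metrics <- function(x, ...) x$pairs

#' One-row summary of annotation metrics
#'
#' @param x An `annotation_metrics` object.
#' @param ... Unused.
#' @return Counts and the precision/recall ratios.
#' @export
glance.annotation_metrics <- function(x, ...) {
  tibble(n_ref_cds = x$n_ref_cds, n_detected = x$n_detected,
         n_true_positive = x$n_true_positive, precision = x$precision,
         recall = x$recall, conventional = x$conventional)
}

#' Coverage-versus-length scatter for a contig set
#'
#' @param object A contig tibble (class `contig_tbl`).
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
#' @export autoplot
autoplot.contig_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$mean_cov)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::labs(x = "contig length (bp)", y = "mean coverage (X)") +
    ggplot2::theme_minimal()
}

#' Per-sample final contig counts for a fosmid run
#'
#' @param object A `fosmid_run`.
#' @param ... Unused.
#' @return A ggplot bar chart of final contig counts per sample.
#' @export
autoplot.fosmid_run <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$sample,
                                   y = .data$contigs_final)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "final contigs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
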