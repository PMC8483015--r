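# Self-contained HTML reports: all styling and graphics (inline SVG) are
# embedded, so the files render offline and can be mailed around as-is.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0) return("<p><em>empty</em></p>")
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(abs(v - round(v)) < 1e-9, format(round(v)),
                              sprintf("%.2f", v))
    else html_escape(as.character(v))
  }
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  cells <- lapply(df, fmt)
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", vapply(cells, `[`, "", i), "</td>",
                          collapse = ""), "</tr>")
  }, "")
  paste0("<table>", head, paste(rows, collapse = "\n"), "</table>")
}

# minimal scatter plot as inline SVG (x = length, y = coverage by default)
svg_scatter <- function(x, y, xlab, ylab, width = 560, height = 360,
                        pad = 55) {
  if (length(x) == 0) return("<p><em>no points</em></p>")
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0) rx <- rx + c(-1, 1)
  if (diff(ry) == 0) ry <- ry + c(-1, 1)
  sx <- function(v) pad + (v - rx[1]) / diff(rx) * (width - 2 * pad)
  sy <- function(v) height - pad - (v - ry[1]) / diff(ry) * (height - 2 * pad)
  ticks <- function(r) pretty(r, 5)
  tx <- ticks(rx); tx <- tx[tx >= rx[1] & tx <= rx[2]]
  ty <- ticks(ry); ty <- ty[ty >= ry[1] & ty <= ry[2]]
  el <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width, height),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            pad, height - pad, width - pad, height - pad),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            pad, pad, pad, height - pad),
    sprintf('<text x="%f" y="%f" font-size="11" text-anchor="middle">%s</text>',
            sx(tx), height - pad + 16, format(tx)),
    sprintf('<text x="%f" y="%f" font-size="11" text-anchor="end">%s</text>',
            pad - 4, sy(ty) + 4, format(ty)),
    sprintf('<text x="%f" y="%f" font-size="12" text-anchor="middle">%s</text>',
            width / 2, height - 12, html_escape(xlab)),
    sprintf(paste0('<text x="14" y="%f" font-size="12" text-anchor="middle" ',
                   'transform="rotate(-90 14 %f)">%s</text>'),
            height / 2, height / 2, html_escape(ylab)),
    sprintf('<circle cx="%f" cy="%f" r="4" fill="#2c7fb8" fill-opacity="0.7"/>',
            sx(x), sy(y))
  )
  paste(c(el, "</svg>"), collapse = "\n")
}

report_css <- paste(
  "body{font-family:sans-serif;margin:2em;max-width:70em}",
  "table{border-collapse:collapse;margin:1em 0}",
  "th,td{border:1px solid #999;padding:4px 8px;font-size:0.9em}",
  "th{background:#eee}",
  "h1{color:#234}h2{color:#345;border-bottom:1px solid #ccc}",
  sep = "\n")

#' Build the assembly HTML report
#'
#' Single self-contained file: parameters, per-sample assembly and vector
#' detection table, contig coverage-vs-length scatter (inline SVG) and a
#' download table linking the generated FASTA/GFF files.
#'
#' @param run A `fosmid_run` from [run_assemble()].
#' @param path Output HTML path.
#' @return The path, invisibly.
#' @export
build_report <- function(run, path) {
  secs <- c(sprintf("<html><head><meta charset='utf-8'><title>%s</title>",
                    run$run_id),
            sprintf("<style>%s</style></head><body>", report_css),
            sprintf("<h1>Fosmid assembly report &mdash; %s</h1>", run$run_id))

  pars <- tibble(parameter = names(run$parameters),
                 value = vapply(run$parameters, function(v)
                   paste(format(v), collapse = " "), ""))
  secs <- c(secs, "<h2>Inputs and parameters</h2>",
            sprintf("<p>Cloning vector: <b>%s</b> (%d bp)</p>",
                    html_escape(run$vector$id), run$vector$length),
            html_table(pars))

  ok <- vapply(run$samples, function(s) identical(s$status, "ok"), TRUE)
  if (length(run$samples) == 0) {
    secs <- c(secs, "<h2>Assembly and vector detection</h2>",
              "<p><b>No samples.</b></p>")
  } else {
    smtab <- purrr::map_dfr(run$samples, function(s) {
      tibble(sample = s$sample, status = s$status,
             reads_in = s$reads_in %||% NA_integer_,
             reads_used = s$reads_used %||% NA_integer_,
             coverage_used = s$coverage_used %||% NA_real_,
             contigs_raw = s$contigs_raw %||% NA_integer_,
             contigs_final = s$contigs_final %||% NA_integer_,
             vector_case = paste(unlist(s$vector_cases %||% list("-")),
                                 collapse = ","),
             error = s$error %||% "")
    })
    secs <- c(secs, "<h2>Assembly and vector detection</h2>",
              html_table(smtab))
  }

  contigs <- purrr::map_dfr(run$samples[ok], function(s) {
    as_tibble(s$contig_table)
  })
  secs <- c(secs, "<h2>Contig coverage vs length</h2>",
            if (nrow(contigs) > 0) {
              svg_scatter(contigs$length, contigs$mean_cov,
                          "contig length (bp)", "mean coverage (X)")
            } else "<p><em>no contigs</em></p>")

  files <- purrr::map_dfr(run$samples[ok], function(s) {
    tibble(sample = s$sample, file = unlist(s$files),
           kind = names(unlist(s$files)))
  })
  files <- dplyr::bind_rows(files, tibble(sample = "(all)",
                                          file = run$pooled_fasta,
                                          kind = "pooled"))
  links <- sprintf('<a href="%s">%s</a>', basename(files$file),
                   basename(files$file))
  ftab <- tibble(sample = html_escape(files$sample),
                 kind = html_escape(files$kind), file = links)
  secs <- c(secs, "<h2>Download files</h2>", html_table_raw(ftab),
            "</body></html>")
  writeLines(paste(secs, collapse = "\n"), path)
  invisible(path)
}

# like html_table but trusting cell content (used for link cells)
html_table_raw <- function(df) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", vapply(df, function(c) as.character(c[i]),
                                         ""), "</td>", collapse = ""),
           "</tr>")
  }, "")
  paste0("<table>", head, paste(rows, collapse = "\n"), "</table>")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the annotation HTML report
#'
#' Per-contig CDS tables with coordinates (1-based inclusive), strand and
#' protein lengths; self-contained HTML.
#'
#' @param contigs Contig tibble.
#' @param features CDS tibble from [find_orfs()].
#' @param path Output HTML path.
#' @return The path, invisibly.
#' @export
build_annotation_report <- function(contigs, features, path) {
  secs <- c("<html><head><meta charset='utf-8'><title>annotation</title>",
            sprintf("<style>%s</style></head><body>", report_css),
            "<h1>Fosmid annotation report</h1>")
  if (nrow(contigs) == 0) {
    secs <- c(secs, "<p><b>No contigs.</b></p>")
  }
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    ft <- features[features$contig_id == cid, , drop = FALSE]
    secs <- c(secs, sprintf("<h2>%s (%d bp, %d CDS)</h2>", html_escape(cid),
                            nchar(contigs$seq[i]), nrow(ft)))
    if (nrow(ft) > 0) {
      g <- to_gff_coords(ft$start, ft$end)
      secs <- c(secs, html_table(tibble(
        cds = ft$cds_id, start = g$start, end = g$end, strand = ft$strand,
        frame = ft$frame, protein_aa = nchar(ft$translation))))
    }
  }
  secs <- c(secs, "</body></html>")
  writeLines(paste(secs, collapse = "\n"), path)
  invisible(path)
}
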