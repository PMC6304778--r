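#' Demultiplex paired ddSEQ FASTQ files
#'
#' The end-to-end pipeline: streams read pairs from R1/R2 FASTQ, runs
#' [extract_tags()] on every Read 1, and optionally writes the tagged
#' unmapped BAM ([write_tagged_bam()]) and the QC summary TSVs
#' (`<prefix>_barcode_counts.tsv`, `<prefix>_error_distribution.tsv`,
#' `<prefix>_cumulative.tsv`). Every input pair yields exactly one result
#' row (and one BAM record unless `drop_invalid`). With `cores > 1` the
#' pairs are processed in chunks on a fork cluster; results are reassembled
#' in input order, so the output is identical for any worker count.
#'
#' @param r1_path,r2_path Input FASTQ paths (plain or gzipped).
#' @param whitelist A [barcode_whitelist()].
#' @param cfg A [read_structure()] (default SureCell).
#' @param out_bam Optional output BAM path.
#' @param summary_prefix Optional path prefix for the three summary TSVs.
#' @param scheme A [tag_scheme()].
#' @param drop_invalid Exclude error-tagged reads from the BAM.
#' @param cores Number of worker processes (default 1).
#' @return An object of class `ddseq_demux`: a list with `results` (the
#'   per-read tibble), `summary` (the [error_distribution()] table),
#'   `counts` (the [count_valid_reads()] table), `n_pairs`, and the output
#'   paths used.
#' @seealso [tidy()], [glance()] and [autoplot()] methods; [demux_report()].
#' @export
demux <- function(r1_path, r2_path, whitelist, cfg = read_structure(),
                  out_bam = NULL, summary_prefix = NULL,
                  scheme = tag_scheme(), drop_invalid = FALSE, cores = 1L) {
  pairs <- read_fastq_pairs(r1_path, r2_path)
  if (cores > 1L && nrow(pairs) > 1L) {
    chunk <- sort(rep_len(seq_len(cores), nrow(pairs)))
    parts <- split(pairs, chunk)
    res <- parallel::mclapply(parts, extract_tags, cfg = cfg,
                              whitelist = whitelist, mc.cores = cores)
    results <- bind_rows(res)  # chunks are contiguous: input order preserved
  } else {
    results <- extract_tags(pairs, cfg, whitelist)
  }
  counts <- count_valid_reads(results)
  summary <- error_distribution(results)

  if (!is.null(out_bam)) {
    cmd <- paste("ddseqr::demux", r1_path, r2_path, out_bam)
    write_tagged_bam(results, out_bam, scheme = scheme,
                     drop_invalid = drop_invalid, command = cmd)
  }
  files <- c(bam = if (is.null(out_bam)) NA_character_ else out_bam)
  if (!is.null(summary_prefix)) {
    f_counts <- paste0(summary_prefix, "_barcode_counts.tsv")
    f_err <- paste0(summary_prefix, "_error_distribution.tsv")
    f_cum <- paste0(summary_prefix, "_cumulative.tsv")
    write_barcode_counts(counts, f_counts)
    utils::write.table(summary, f_err, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cumulative_curve(counts), f_cum, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, counts = f_counts, errors = f_err, cumulative = f_cum)
  }
  structure(
    list(results = results, summary = summary, counts = counts,
         n_pairs = nrow(pairs), files = files, scheme = scheme),
    class = "ddseq_demux"
  )
}

#' @export
print.ddseq_demux <- function(x, ...) {
  cat("<ddseq_demux> ", x$n_pairs, " read pairs\n", sep = "")
  pass <- x$summary$fraction[x$summary$code == "PASS"]
  cat(sprintf("  PASS: %d (%.2f%%)\n",
              x$summary$count[x$summary$code == "PASS"], 100 * pass))
  err <- x$summary[x$summary$code != "PASS" & x$summary$count > 0, ]
  if (nrow(err)) {
    cat("  errors:",
        paste0(err$code, "=", sprintf("%.2f%%", 100 * err$fraction),
               collapse = " "), "\n")
  }
  cat("  cells with >=1 valid read:", nrow(x$counts), "\n")
  invisible(x)
}

#' @rdname demux
#' @param x A `ddseq_demux` object.
#' @param ... Unused.
#' @export
tidy.ddseq_demux <- function(x, ...) x$results

#' @rdname demux
#' @export
glance.ddseq_demux <- function(x, ...) {
  pass <- sum(x$results$status == "valid")
  tibble(
    n_pairs = x$n_pairs,
    n_valid = pass,
    pass_fraction = if (x$n_pairs) pass / x$n_pairs else 0,
    n_barcodes = nrow(x$counts),
    estimated_cells = if (nrow(x$counts) >= 3) knee_estimate(x$counts)
                      else NA_integer_
  )
}

#' One-screen run report for a demultiplexing result
#'
#' Returns (and optionally prints) the run report as a list convertible to
#' JSON: totals, PASS percentage and per-code percentages.
#'
#' @param x A `ddseq_demux` object.
#' @return A named list with `n_pairs`, `n_valid`, `pass_pct` and
#'   `error_pct` (named per-code percentages).
#' @export
demux_report <- function(x) {
  stopifnot(inherits(x, "ddseq_demux"))
  s <- x$summary
  list(
    n_pairs = x$n_pairs,
    n_valid = s$count[s$code == "PASS"],
    pass_pct = 100 * s$fraction[s$code == "PASS"],
    error_pct = setNames(as.list(100 * s$fraction[s$code != "PASS"]),
                         as.character(s$code[s$code != "PASS"]))
  )
}
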