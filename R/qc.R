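#' Distribution of extraction outcomes
#'
#' Tabulates valid reads (`PASS`) and every error code over a set of tag
#' results. Zero-count codes are included so the table shape is stable;
#' fractions are of the total read count and sum to one.
#'
#' @param tags A tibble from [extract_tags()] (needs `status` and
#'   `error_code`).
#' @return A tibble with columns `code` (`PASS` first, then the codes in
#'   precedence order), `count` and `fraction` (all zero for empty input).
#' @export
error_distribution <- function(tags) {
  codes <- c("PASS", DDSEQ_ERROR_CODES)
  obs <- ifelse(tags$status == "valid", "PASS", tags$error_code)
  cnt <- table(factor(obs, levels = codes))
  total <- sum(cnt)
  tibble(
    code = factor(codes, levels = codes),
    count = as.integer(cnt),
    fraction = if (total == 0) rep(0, length(codes)) else as.integer(cnt) / total
  )
}

#' Valid reads per cell barcode
#'
#' Counts valid reads keyed by the 18-nt corrected cell barcode, sorted by
#' count descending with ties broken lexicographically. This is the table
#' behind the reads-per-cell QC curves and the knee-based cell-number
#' estimate, and what [write_barcode_counts()] serialises.
#'
#' @param tags A tibble from [extract_tags()].
#' @return A tibble with columns `cell_barcode` and `reads`.
#' @export
count_valid_reads <- function(tags) {
  v <- tags[tags$status == "valid", , drop = FALSE]
  out <- count(v, .data$cell_barcode, name = "reads")
  arrange(out, desc(.data$reads), .data$cell_barcode)
}

#' Cumulative fraction of reads over ranked barcodes
#'
#' For the `top_n` most-read barcodes, the cumulative fraction of all valid
#' reads (the denominator is the total over the whole table, not the top-n
#' subset). The curve is monotone nondecreasing and reaches 1 exactly when
#' `top_n` covers every barcode.
#'
#' @param counts A tibble from [count_valid_reads()].
#' @param top_n Number of top barcodes to report (default 5000).
#' @return A tibble with columns `rank` and `cumulative_fraction`; zero rows
#'   for an empty table.
#' @export
cumulative_curve <- function(counts, top_n = 5000L) {
  stopifnot(top_n >= 1)
  counts <- arrange(counts, desc(.data$reads), .data$cell_barcode)
  if (!nrow(counts)) {
    return(tibble(rank = integer(0), cumulative_fraction = numeric(0)))
  }
  r <- min(as.integer(top_n), nrow(counts))
  tibble(
    rank = seq_len(r),
    cumulative_fraction = cumsum(counts$reads[seq_len(r)]) / sum(counts$reads)
  )
}

#' Knee-based estimate of the number of cells
#'
#' Estimates how many barcodes correspond to real cells from the ranked
#' reads-per-barcode table, as the knee of the cumulative-fraction curve:
#' with ranks and cumulative fractions rescaled to the unit square and the
#' curve anchored at the origin, the returned rank maximises the
#' perpendicular distance to the chord joining the curve's endpoints. Ties
#' are broken towards the smaller rank (so a degenerate straight-line curve
#' returns rank 1), and the estimate is invariant to uniform rescaling of
#' the counts.
#'
#' @param counts A tibble from [count_valid_reads()] with at least 3
#'   distinct barcodes.
#' @param top_n Restrict the analysis to the `top_n` most-read barcodes
#'   (default 5000).
#' @return The estimated cell count (integer rank).
#' @export
knee_estimate <- function(counts, top_n = 5000L) {
  if (nrow(counts) < 3) {
    stop("knee estimation needs at least 3 distinct barcodes", call. = FALSE)
  }
  curve <- cumulative_curve(counts, top_n)
  r <- nrow(curve)
  # unit-square normalization; chord runs (0,0) -> (1,1), so the distance to
  # it is |y - x| / sqrt(2) and only |y - x| matters for the argmax
  x <- curve$rank / r
  y <- curve$cumulative_fraction / curve$cumulative_fraction[r]
  which.max(abs(y - x))
}
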