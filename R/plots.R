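#' QC plots for demultiplexing results
#'
#' ggplot2 views of the three standard QC surfaces: the distribution of
#' valid (`PASS`) and error-tagged reads, the number of reads per ranked
#' cell barcode, and the cumulative fraction of reads over ranked barcodes
#' with the knee-based cell estimate marked.
#'
#' @param dist An [error_distribution()] tibble.
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$code, y = 100 * .data$fraction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "outcome", y = "% of reads") +
    ggplot2::theme_bw()
}

#' @rdname plot_error_distribution
#' @param counts A [count_valid_reads()] tibble.
#' @param top_n Number of top barcodes to show (default 5000).
#' @export
plot_reads_per_barcode <- function(counts, top_n = 5000L) {
  counts <- arrange(counts, desc(.data$reads), .data$cell_barcode)
  df <- tibble(rank = seq_len(min(top_n, nrow(counts))),
               reads = counts$reads[seq_len(min(top_n, nrow(counts)))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$reads)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "valid reads") +
    ggplot2::theme_bw()
}

#' @rdname plot_error_distribution
#' @param knee Mark this rank with a vertical line; `TRUE` (default)
#'   computes it with [knee_estimate()], `NULL`/`FALSE` omits it.
#' @export
plot_cumulative_curve <- function(counts, top_n = 5000L, knee = TRUE) {
  curve <- cumulative_curve(counts, top_n)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$rank,
                                           y = .data$cumulative_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "barcode rank", y = "cumulative fraction of reads") +
    ggplot2::theme_bw()
  if (isTRUE(knee) && nrow(counts) >= 3) knee <- knee_estimate(counts, top_n)
  if (is.numeric(knee)) {
    p <- p + ggplot2::geom_vline(xintercept = knee, linetype = "dashed")
  }
  p
}

#' @rdname plot_error_distribution
#' @param object A `ddseq_demux` object.
#' @param type One of `"errors"`, `"cumulative"`, `"barcodes"`.
#' @param ... Unused.
#' @export
autoplot.ddseq_demux <- function(object, type = c("errors", "cumulative",
                                                  "barcodes"), ...) {
  type <- match.arg(type)
  switch(type,
    errors = plot_error_distribution(object$summary),
    cumulative = plot_cumulative_curve(object$counts),
    barcodes = plot_reads_per_barcode(object$counts)
  )
}
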