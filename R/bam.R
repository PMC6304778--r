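#' BAM tag scheme for demultiplexed reads
#'
#' Names of the BAM auxiliary tags carrying the cell barcode, the UMI and
#' the error code. The default mirrors the Drop-seq tools convention
#' (`XC`/`XM`) plus the custom `XE` error tag; alternative schemes (e.g.
#' `CB`/`UB` for 10x-style downstream tools) can be chosen freely as long as
#' the three names are distinct, match `[A-Za-z][A-Za-z0-9]` and avoid
#' predefined standard tags.
#'
#' @param cell,umi,error Two-character tag names.
#' @return An object of class `tag_scheme`.
#' @export
#' @examples
#' tag_scheme()
#' tag_scheme(cell = "CB", umi = "UB")
tag_scheme <- function(cell = "XC", umi = "XM", error = "XE") {
  tags <- c(cell = cell, umi = umi, error = error)
  ok <- grepl("^[A-Za-z][A-Za-z0-9]$", tags)
  if (!all(ok)) {
    stop("invalid tag name(s): ", paste(tags[!ok], collapse = ", "),
         " (must match [A-Za-z][A-Za-z0-9])", call. = FALSE)
  }
  if (anyDuplicated(tags)) {
    stop("cell, umi and error tags must be distinct", call. = FALSE)
  }
  reserved <- c("AS", "BC", "CC", "CG", "CP", "FI", "FS", "HI", "H0", "H1",
                "H2", "LB", "MC", "MD", "MI", "MQ", "NH", "NM", "OA", "OC",
                "OP", "OQ", "PG", "PQ", "PT", "PU", "Q2", "QT", "QX", "R2",
                "RG", "RX", "SA", "SM", "SQ", "S2", "TC", "TS", "U2", "UQ")
  if (any(tags %in% reserved)) {
    stop("tag(s) collide with predefined SAM tags: ",
         paste(intersect(tags, reserved), collapse = ", "), call. = FALSE)
  }
  structure(as.list(tags), class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("<tag_scheme> cell:", x$cell, " umi:", x$umi, " error:", x$error, "\n")
  invisible(x)
}

#' Write demultiplexed reads as a tagged unmapped BAM
#'
#' Emits one unmapped BAM record (flag 4, no reference or mate information)
#' per read pair. The record carries the Read 2 sequence and qualities
#' verbatim; a valid read additionally carries the cell-barcode and UMI
#' tags, an invalid read the error tag with its error code. The header
#' records the program name, version and command line. By default every
#' read is written so that record count equals input pair count;
#' `drop_invalid = TRUE` restricts the output to valid reads for pipelines
#' that cannot skip error-tagged records.
#'
#' @param tags A tibble as returned by [extract_tags()], additionally
#'   carrying `r2_seq` and `r2_qual` columns (as produced by
#'   [read_fastq_pairs()] + [extract_tags()], or by [demux()]).
#' @param out_path Output BAM path (`.bam` appended if missing).
#' @param scheme A [tag_scheme()].
#' @param drop_invalid Write only valid reads (default `FALSE`).
#' @param command Command line recorded in the `@PG` header line.
#' @return The number of records written, invisibly; the output path is
#'   attached as attribute `path`.
#' @export
write_tagged_bam <- function(tags, out_path, scheme = tag_scheme(),
                             drop_invalid = FALSE,
                             command = "ddseqr::write_tagged_bam") {
  stopifnot(inherits(scheme, "tag_scheme"),
            all(c("read_id", "status", "cell_barcode", "umi", "error_code",
                  "r2_seq", "r2_qual") %in% names(tags)))
  if (drop_invalid) tags <- tags[tags$status == "valid", , drop = FALSE]
  valid <- tags$status == "valid"
  tag_field <- ifelse(
    valid,
    paste0(scheme$cell, ":Z:", tags$cell_barcode, "\t",
           scheme$umi, ":Z:", tags$umi),
    paste0(scheme$error, ":Z:", tags$error_code)
  )
  version <- as.character(utils::packageVersion("ddseqr"))
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@PG\tID:ddseqr\tPN:ddseqr\tVN:", version, "\tCL:", command)
  )
  records <- paste(tags$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   tags$r2_seq, tags$r2_qual, tag_field, sep = "\t")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, records), sam)
  out_path <- ifelse(grepl("\\.bam$", out_path), out_path,
                     paste0(out_path, ".bam"))
  dest <- sub("\\.bam$", "", out_path)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  n <- length(records)
  invisible(structure(n, path = bam))
}

#' Read a tagged unmapped BAM back into a tibble
#'
#' Counterpart of [write_tagged_bam()], mainly for round-trip verification
#' and for feeding downstream summaries from an existing BAM.
#'
#' @param path BAM path.
#' @param scheme The [tag_scheme()] the file was written with.
#' @return A tibble with `read_id`, `flag`, `r2_seq`, `r2_qual`, `status`,
#'   `cell_barcode`, `umi`, `error_code`.
#' @export
read_tagged_bam <- function(path, scheme = tag_scheme()) {
  stopifnot(inherits(scheme, "tag_scheme"))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    tag = c(scheme$cell, scheme$umi, scheme$error)
  )
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  cell <- res$tag[[scheme$cell]]
  umi <- res$tag[[scheme$umi]]
  err <- res$tag[[scheme$error]]
  n <- length(res$qname)
  if (is.null(cell)) cell <- rep(NA_character_, n)
  if (is.null(umi)) umi <- rep(NA_character_, n)
  if (is.null(err)) err <- rep(NA_character_, n)
  tibble(
    read_id = res$qname,
    flag = res$flag,
    r2_seq = as.character(res$seq),
    r2_qual = as.character(res$qual),
    status = ifelse(is.na(err), "valid", "invalid"),
    cell_barcode = cell,
    umi = umi,
    error_code = err
  )
}

#' Write per-cell valid-read counts to a TSV file
#'
#' Two tab-separated columns (cell barcode, valid-read count), sorted by
#' count descending with ties broken lexicographically by barcode; no header
#' unless requested.
#'
#' @param counts A tibble as returned by [count_valid_reads()].
#' @param path Output path.
#' @param header Write a `barcode<TAB>reads` header line (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_barcode_counts <- function(counts, path, header = FALSE) {
  stopifnot(all(c("cell_barcode", "reads") %in% names(counts)))
  counts <- arrange(counts, desc(.data$reads), .data$cell_barcode)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (header) writeLines("barcode\treads", con)
  if (nrow(counts)) {
    writeLines(paste(counts$cell_barcode, counts$reads, sep = "\t"), con)
  }
  invisible(path)
}
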