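#' Read paired FASTQ files into a tibble
#'
#' Loads R1 (molecular tags) and R2 (cDNA) FASTQ files, plain or
#' gzip-compressed, and pairs them record by record. Sequences are
#' uppercased; quality strings are preserved verbatim. Read identifiers are
#' taken up to the first whitespace with a trailing `/1` or `/2` mate suffix
#' stripped, and the two files must agree on every identifier in order.
#'
#' @param r1_path,r2_path Paths to the R1 and R2 FASTQ files.
#' @return A tibble with columns `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`, in file order.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- .read_fastq(r1_path)
  r2 <- .read_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) {
    stop("R1 and R2 record counts differ (", nrow(r1), " vs ", nrow(r2),
         "): first unmatched pair at index ", min(nrow(r1), nrow(r2)) + 1L,
         call. = FALSE)
  }
  bad <- which(r1$read_id != r2$read_id)
  if (length(bad)) {
    stop("R1/R2 identifiers disagree at pair ", bad[1], ": '",
         r1$read_id[bad[1]], "' vs '", r2$read_id[bad[1]], "'", call. = FALSE)
  }
  tibble(read_id = r1$read_id,
         r1_seq = r1$seq, r1_qual = r1$qual,
         r2_seq = r2$seq, r2_qual = r2$qual)
}

.read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(x))
  ids <- sub("/[12]$", "", ids)
  tibble(read_id = unname(ids),
         seq = unname(toupper(as.character(x))),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

# write a set of reads as (optionally gzipped) FASTQ
.write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
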