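# Shared fixtures and independent brute-force oracles.
#
# The toy configuration uses short recognisable linkers and a three-entry
# whitelist so expected outcomes can be worked out by hand; the shipped
# synthetic 96-entry whitelist exercises realistic ambiguity rates.

toy_cfg <- function(...) {
  read_structure(linker1 = "AAAAATTTTTGGGGG", linker2 = "CCCCCGGGGGAAAAA", ...)
}

toy_wl <- function() barcode_whitelist(c("ACGTAC", "TGCATG", "GATCGA"))

wl96 <- function() {
  read_barcode_whitelist(
    system.file("extdata", "synthetic_barcode_blocks_96.txt", package = "ddseqr")
  )
}

# canonical clean toy read: PB "GT", BC1 ACGTAC, L1, BC2 TGCATG, L2,
# BC3 GATCGA, ACG, UMI AACCGGTT, GAC, tail
toy_read <- function(pb = "GT", bc1 = "ACGTAC", bc2 = "TGCATG",
                     bc3 = "GATCGA", umi = "AACCGGTT", tail = "TTTT",
                     cfg = toy_cfg()) {
  paste0(pb, bc1, cfg$linker1, bc2, cfg$linker2, bc3,
         cfg$pre_umi_flanker, umi, cfg$post_umi_flanker, tail)
}

toy_barcode <- "ACGTACTGCATGGATCGA"

del_at <- function(s, p) paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
ins_at <- function(s, p, b) paste0(substr(s, 1, p - 1), b, substr(s, p, nchar(s)))
sub_at <- function(s, p, b) { substr(s, p, p) <- b; s }

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force linker oracle: every (start, span) window within Levenshtein
# distance max_edits of the linker, via utils::adist
oracle_scan <- function(seq, linker, max_edits = 1L) {
  L <- nchar(linker)
  n <- nchar(seq)
  res <- NULL
  spans <- if (max_edits == 0L) L else c(L - 1L, L, L + 1L)
  for (w in spans) {
    if (n < w) next
    st <- seq_len(n - w + 1L)
    d <- as.vector(utils::adist(substring(seq, st, st + w - 1L), linker))
    keep <- d <= max_edits
    if (any(keep)) {
      res <- rbind(res, cbind(start = st[keep], width = w, dist = d[keep]))
    }
  }
  res
}

# brute-force whitelist oracle: exact membership, else the unique entry
# within Levenshtein distance 1 over an exhaustive distance matrix
oracle_match <- function(blocks, entries) {
  out <- entries[match(blocks, entries)]
  todo <- which(is.na(out))
  if (length(todo)) {
    d <- utils::adist(blocks[todo], entries)
    nn <- rowSums(d <= 1L)
    uniq <- nn == 1L
    out[todo[uniq]] <- entries[apply(d[uniq, , drop = FALSE], 1, which.min)]
  }
  out
}

expect_tag <- function(tag, status, barcode = NULL, umi = NULL, code = NULL) {
  expect_equal(tag$status, status)
  if (!is.null(barcode)) expect_equal(tag$cell_barcode, barcode)
  if (!is.null(umi)) expect_equal(tag$umi, umi)
  if (!is.null(code)) expect_equal(tag$error_code, code)
}
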