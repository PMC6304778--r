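#' Validate the linker geometry of a Read 1
#'
#' Applies the structural checks that follow linker localization: the
#' distance between the two linker start positions must fall in the accepted
#' gap set (21 nt on a clean read; 20/22 absorb a single indel in BC2 or
#' linker 1, and the implied BC2 block must be within one base of
#' `barcode_len`); at least `min_l1_start` bases must precede the linker-1
#' match (phase block + BC1); and the read must be long enough to contain
#' BC3, both UMI flankers and the UMI downstream of linker 2. Checks are
#' applied in the order D, P, S and the first failure is returned.
#'
#' @param hit1,hit2 Linker hits as returned by [find_linker()] (one row
#'   each, or any list with `start` and `width`).
#' @param read_len Length of the Read 1 sequence.
#' @param cfg A [read_structure()] configuration.
#' @return `"ok"`, or one of the error codes `"D"`, `"P"`, `"S"`.
#' @export
#' @examples
#' cfg <- read_structure()
#' h1 <- list(start = 9, width = 15)  # 8 bases precede the linker
#' h2 <- list(start = 30, width = 15)
#' validate_structure(h1, h2, read_len = 60, cfg = cfg)
validate_structure <- function(hit1, hit2, read_len, cfg) {
  gap <- hit2$start - hit1$start
  bc2_len <- gap - hit1$width
  if (!(gap %in% cfg$accepted_gaps) ||
      abs(bc2_len - cfg$barcode_len) > 1L) {
    return("D")
  }
  if (hit1$start - 1L < cfg$min_l1_start) return("P")
  end2 <- hit2$start + hit2$width - 1L
  need <- end2 + cfg$barcode_len + 3L + cfg$umi_len + 3L
  if (read_len < need) return("S")
  "ok"
}

#' Check the trinucleotides flanking the UMI
#'
#' Counts mismatches of the three bases following BC3 against the pre-UMI
#' flanker (`ACG`) plus the three bases following the UMI against the
#' post-UMI flanker (`GAC`). The total must not exceed
#' `cfg$max_flanker_mismatches` (default 1). No shifting or indel search is
#' performed: the flankers are too short for reliable indel placement.
#' `N` counts as a mismatch.
#'
#' @param read1_seq Read 1 sequence.
#' @param bc3_end 1-based inclusive position of the last BC3 base.
#' @param cfg A [read_structure()] configuration.
#' @return `"ok"` or the error code `"T"`.
#' @export
#' @examples
#' cfg <- read_structure()
#' # BC3 ends at base 6; "ACG" + 8-nt UMI + "GAC" follow
#' check_flankers("ACGTACACGAACCGGTTGAC", bc3_end = 6, cfg = cfg)
check_flankers <- function(read1_seq, bc3_end, cfg) {
  seq <- toupper(read1_seq)
  pre <- substr(seq, bc3_end + 1L, bc3_end + 3L)
  post <- substr(seq, bc3_end + 3L + cfg$umi_len + 1L,
                 bc3_end + 3L + cfg$umi_len + 3L)
  mm <- .flanker_mismatches(pre, post, cfg)
  ifelse(mm <= cfg$max_flanker_mismatches, "ok", "T")
}

# vectorized positionwise mismatch count of the two observed trinucleotides
# against the configured flankers; short/missing bases count as mismatches
.flanker_mismatches <- function(pre, post, cfg) {
  mm <- integer(length(pre))
  for (i in 1:3) {
    mm <- mm +
      (substr(pre, i, i) != substr(cfg$pre_umi_flanker, i, i)) +
      (substr(post, i, i) != substr(cfg$post_umi_flanker, i, i))
  }
  mm
}

# scan one linker over all reads and keep, per read, only the hits at the
# minimal edit distance (the scanner returns hits ordered by distance then
# start, so the first row per read carries the minimum)
.minimal_hits <- function(seqs, linker, max_edits) {
  raw <- .scan_linker_batch(seqs, linker, max_edits)
  n <- length(seqs)
  first <- !duplicated(raw$seq)
  min_d <- rep(NA_integer_, n)
  min_d[raw$seq[first]] <- raw$edit_distance[first]
  keep <- raw$edit_distance == min_d[raw$seq]
  idx <- unname(split(which(keep), factor(raw$seq[keep], levels = seq_len(n))))
  list(start = raw$start, width = raw$width, idx = idx)
}

# ordered candidate (L1, L2) interpretation pairs per read: every minimal
# L1 hit combined with every minimal L2 hit starting after it, in
# (L1 start, L2 start) order.  Most reads have exactly one pair; returned
# as one flat matrix with columns read, rank, s1, w1, s2, w2.
.candidate_pairs <- function(h1, h2, n) {
  n1 <- lengths(h1$idx); n2 <- lengths(h2$idx)
  simple <- which(n1 == 1L & n2 == 1L)
  out <- list()
  if (length(simple)) {
    i1 <- unlist(h1$idx[simple]); i2 <- unlist(h2$idx[simple])
    s1 <- h1$start[i1]; w1 <- h1$width[i1]
    s2 <- h2$start[i2]; w2 <- h2$width[i2]
    ok <- s2 > s1 + w1 - 1L
    out[[1]] <- cbind(read = simple[ok], rank = 1L, s1 = s1[ok],
                      w1 = w1[ok], s2 = s2[ok], w2 = w2[ok])
  }
  for (r in which(n1 * n2 > 1L)) {
    i1 <- h1$idx[[r]]; i2 <- h2$idx[[r]]
    s1 <- h1$start[i1]; w1 <- h1$width[i1]
    s2 <- h2$start[i2]; w2 <- h2$width[i2]
    comb <- which(outer(s1 + w1 - 1L, s2, "<"), arr.ind = TRUE)
    if (!nrow(comb)) next
    comb <- comb[order(comb[, 1], comb[, 2]), , drop = FALSE]
    out[[length(out) + 1L]] <- cbind(
      read = r, rank = seq_len(nrow(comb)),
      s1 = s1[comb[, 1]], w1 = w1[comb[, 1]],
      s2 = s2[comb[, 2]], w2 = w2[comb[, 2]]
    )
  }
  if (!length(out)) {
    return(matrix(integer(0), 0, 6,
                  dimnames = list(NULL, c("read", "rank", "s1", "w1",
                                          "s2", "w2"))))
  }
  do.call(rbind, out)
}

# evaluate one candidate interpretation per read (vectorized): geometry
# checks in order D, P, S, then flankers (T), then whitelist matching (B);
# NA code means valid
.evaluate_pair <- function(seqs, read_len, s1, w1, s2, w2, cfg, whitelist) {
  bl <- cfg$barcode_len; ul <- cfg$umi_len
  gap <- s2 - s1
  bc2_len <- gap - w1
  end2 <- s2 + w2 - 1L
  code <- rep(NA_character_, length(seqs))
  code[!(gap %in% cfg$accepted_gaps) | abs(bc2_len - bl) > 1L] <- "D"
  code[is.na(code) & (s1 - 1L < cfg$min_l1_start)] <- "P"
  code[is.na(code) & (read_len < end2 + bl + 3L + ul + 3L)] <- "S"

  open <- is.na(code)
  pre <- substr(seqs, end2 + bl + 1L, end2 + bl + 3L)
  post <- substr(seqs, end2 + bl + 3L + ul + 1L, end2 + bl + 3L + ul + 3L)
  mm <- .flanker_mismatches(pre, post, cfg)
  code[open & mm > cfg$max_flanker_mismatches] <- "T"

  open <- is.na(code)
  cell <- rep(NA_character_, length(seqs))
  umi <- rep(NA_character_, length(seqs))
  if (any(open)) {
    b1 <- substr(seqs[open], s1[open] - bl, s1[open] - 1L)
    b2 <- substr(seqs[open], s1[open] + w1[open], s2[open] - 1L)
    b3 <- substr(seqs[open], end2[open] + 1L, end2[open] + bl)
    m1 <- match_barcode(b1, whitelist, cfg$max_barcode_edits)$barcode
    m2 <- match_barcode(b2, whitelist, cfg$max_barcode_edits)$barcode
    m3 <- match_barcode(b3, whitelist, cfg$max_barcode_edits)$barcode
    cc <- ifelse(is.na(m1) | is.na(m2) | is.na(m3), NA_character_,
                 paste0(m1, m2, m3))
    cell[open] <- cc
    umi[open] <- substr(seqs[open], end2[open] + bl + 4L,
                        end2[open] + bl + 3L + ul)
    code[open][is.na(cc)] <- "B"
  }
  list(code = code, cell = cell, umi = umi)
}

#' Extract cell barcodes and UMIs from Read 1 sequences
#'
#' The core demultiplexing operation. For each read it (1) locates both
#' linkers with single-edit tolerance ([find_linker()] semantics; codes
#' `LX`/`L1`/`L2` when localization fails), (2) validates the geometry
#' ([validate_structure()]; codes `D`/`P`/`S`), (3) extracts BC1 (the
#' `barcode_len` bases left of the linker-1 hit), BC2 (the bases between the
#' two linker hits, 5-7 nt when an indel is implied), BC3 (the bases right
#' of the linker-2 hit) and the UMI, (4) checks the UMI flankers
#' ([check_flankers()]; code `T`), and (5) resolves each barcode block
#' against the whitelist within edit distance 1 ([match_barcode()]; code `B`
#' when any block has no unique match). The cell barcode of a valid read is
#' the concatenation of the three corrected blocks; the UMI is reported
#' verbatim and never corrected.
#'
#' A single linker edit can admit several overlapping minimal-distance
#' interpretations (for instance, a deletion inside a homopolymer run also
#' reads as a substitution one base to the left). Candidate interpretation
#' pairs are therefore tried in (edit distance, start) order and the first
#' one that yields a fully valid read wins; if none does, the primary
#' (leftmost minimal) interpretation's error code is reported. Exactly one
#' row is returned per input read, and an invalid read carries the single
#' highest-precedence error code (`LX > L1 > L2 > D > P > S > T > B`).
#'
#' @param reads A data frame with columns `read_id` and `r1_seq` (extra
#'   columns are preserved), or a bare character vector of Read 1 sequences.
#' @param cfg A [read_structure()] configuration.
#' @param whitelist A [barcode_whitelist()].
#' @return A tibble with one row per read: the input columns plus `status`
#'   (`"valid"`/`"invalid"`), `cell_barcode`, `umi` and `error_code`
#'   (`NA` where not applicable).
#' @export
#' @examples
#' cfg <- read_structure(linker1 = "AAAAATTTTTGGGGG", linker2 = "CCCCCGGGGGAAAAA")
#' wl <- barcode_whitelist(c("ACGTAC", "TGCATG", "GATCGA"))
#' r1 <- paste0("GT", "ACGTAC", cfg$linker1, "TGCATG", cfg$linker2,
#'              "GATCGA", "ACG", "AACCGGTT", "GAC", "TTTT")
#' extract_tags(r1, cfg, wl)
extract_tags <- function(reads, cfg, whitelist) {
  stopifnot(inherits(cfg, "read_structure"),
            inherits(whitelist, "barcode_whitelist"))
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)), r1_seq = reads)
  }
  stopifnot(all(c("read_id", "r1_seq") %in% names(reads)))
  seqs <- toupper(reads$r1_seq)
  n <- length(seqs)
  read_len <- nchar(seqs)

  h1 <- .minimal_hits(seqs, cfg$linker1, cfg$max_linker_edits)
  h2 <- .minimal_hits(seqs, cfg$linker2, cfg$max_linker_edits)
  M <- .candidate_pairs(h1, h2, n)

  has1 <- lengths(h1$idx) > 0L
  has2 <- lengths(h2$idx) > 0L
  npair <- tabulate(M[, "read"], n)
  code <- rep(NA_character_, n)
  code[!has1 & !has2] <- "LX"
  code[!has1 & has2] <- "L1"
  code[has1 & npair == 0L] <- "L2"

  cell <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(max(0L, npair))) {
    sel <- M[, "rank"] == k & !valid[M[, "read"]]
    if (!any(sel)) next
    p <- M[sel, , drop = FALSE]
    active <- p[, "read"]
    ev <- .evaluate_pair(seqs[active], read_len[active],
                         p[, "s1"], p[, "w1"], p[, "s2"], p[, "w2"],
                         cfg, whitelist)
    if (k == 1L) code[active] <- ev$code  # primary interpretation's verdict
    ok <- is.na(ev$code)
    adopt <- active[ok]
    valid[adopt] <- TRUE
    code[adopt] <- NA_character_
    cell[adopt] <- ev$cell[ok]
    umi[adopt] <- ev$umi[ok]
  }

  out <- as_tibble(reads)
  out$status <- ifelse(valid, "valid", "invalid")
  out$cell_barcode <- ifelse(valid, cell, NA_character_)
  out$umi <- ifelse(valid, umi, NA_character_)
  out$error_code <- code
  out
}
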