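SIM_TARGETS <- c("linker1", "linker2", "bc1", "bc2", "bc3",
                 "flanker_pre", "flanker_post", "umi", "phase")
SIM_KINDS <- c("substitution", "insertion", "deletion")

#' Build an error model for the synthetic-read generator
#'
#' Each entry describes one class of injected errors as a string
#' `target:kind:prob[:count[:position]]` — e.g. `"linker1:substitution:0.05"`
#' injects one random substitution into linker 1 in 5% of reads, and
#' `"linker2:substitution:0.02:2"` injects two substitutions (at distinct
#' positions) in 2% of reads. Targets: `linker1`, `linker2`, `bc1`, `bc2`,
#' `bc3`, `flanker_pre`, `flanker_post`, `umi`, `phase`; kinds:
#' `substitution`, `insertion`, `deletion`. `position` is a 1-based offset
#' within the target or `random` (default). Entries are applied
#' independently per read.
#'
#' @param ... Error-class strings.
#' @return A tibble with columns `target`, `kind`, `prob`, `count`,
#'   `position`.
#' @export
#' @examples
#' error_model("linker1:substitution:0.05", "bc2:substitution:0.02")
error_model <- function(...) {
  specs <- c(...)
  if (!length(specs)) {
    return(tibble(target = character(0), kind = character(0),
                  prob = numeric(0), count = integer(0),
                  position = character(0)))
  }
  parts <- strsplit(specs, ":", fixed = TRUE)
  parse1 <- function(p, raw) {
    if (length(p) < 3 || length(p) > 5) {
      stop("malformed error spec '", raw,
           "' (want target:kind:prob[:count[:position]])", call. = FALSE)
    }
    target <- p[1]; kind <- p[2]; prob <- suppressWarnings(as.numeric(p[3]))
    count <- if (length(p) >= 4) as.integer(p[4]) else 1L
    position <- if (length(p) >= 5) p[5] else "random"
    if (!target %in% SIM_TARGETS) stop("unknown error target: ", target, call. = FALSE)
    if (!kind %in% SIM_KINDS) stop("unknown error kind: ", kind, call. = FALSE)
    if (is.na(prob) || prob < 0 || prob > 1) stop("bad probability in '", raw, "'", call. = FALSE)
    if (is.na(count) || count < 1) stop("bad count in '", raw, "'", call. = FALSE)
    tibble(target = target, kind = kind, prob = prob,
           count = count, position = position)
  }
  bind_rows(Map(parse1, parts, specs))
}

DNA_BASES <- c("A", "C", "G", "T")

.random_seq <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                collapse = ""), character(1))
}

# apply `count` edits of one kind to a segment string; substitutions always
# change the base (and use distinct positions), so the Hamming/Levenshtein
# distance moved equals `count`
.mutate_segment <- function(s, kind, count, position = "random") {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (kind == "substitution") {
    if (identical(position, "random")) {
      pos <- sample(length(ch), min(count, length(ch)))
    } else {
      pos <- rep(as.integer(position), count)[seq_len(min(count, length(ch)))]
      pos <- unique(pos)
    }
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  } else if (kind == "deletion") {
    for (j in seq_len(count)) {
      if (!length(ch)) break
      p <- if (identical(position, "random")) sample(length(ch), 1)
           else min(as.integer(position), length(ch))
      ch <- ch[-p]
    }
  } else {  # insertion
    for (j in seq_len(count)) {
      p <- if (identical(position, "random")) sample(length(ch) + 1L, 1)
           else min(as.integer(position), length(ch) + 1L)
      ch <- append(ch, sample(DNA_BASES, 1), after = p - 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Generate synthetic ddSEQ read pairs with ground truth
#'
#' Emulates the Read 1 anatomy — phase block, BC1, linker 1, BC2, linker 2,
#' BC3, `ACG`, UMI, `GAC`, poly-T tail — with a variable-length phase block,
#' cell barcodes drawn as distinct whitelist triples, random UMIs and a
#' random-sequence Read 2 (alignment is out of scope, so no transcriptome is
#' modelled). Errors are injected per an [error_model()] and recorded per
#' read; the status the extraction contract mandates for each read is
#' computed analytically by [predict_status()] and stored alongside, which
#' makes the output a self-contained test oracle. Identical seeds give
#' identical output.
#'
#' @param n_cells Number of cells (distinct BC1/BC2/BC3 triples).
#' @param reads_per_cell Reads per cell: a scalar, a vector of length
#'   `n_cells`, or a function of `n_cells` returning such a vector.
#' @param whitelist A [barcode_whitelist()].
#' @param seed Integer seed; all randomness flows from it.
#' @param model An [error_model()] (default: no errors).
#' @param cfg A [read_structure()] (default SureCell).
#' @param pb_range Phase-block length range, inclusive (default `c(1, 5)`).
#' @param r2_len Read 2 length in nt (default 60).
#' @param tail_len Poly-T tail appended after the post-UMI flanker
#'   (default 8), so single deletions never truncate the structure.
#' @param out_dir If non-`NULL`, write `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz` and `<prefix>_truth.tsv` there.
#' @param prefix File prefix used with `out_dir` (default `"sim"`).
#' @return An object of class `ddseq_sim`: a list with `reads` (tibble:
#'   `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`), `truth` (tibble:
#'   `read_id`, `cell_barcode`, `umi`, `pb_len`, `errors`,
#'   `expected_status`, `expected_barcode`, `expected_umi`), `segments`
#'   (per-read mutated segment strings, the generator's bookkeeping),
#'   `seed`, and `files` (paths, when written).
#' @export
#' @examples
#' wl <- barcode_whitelist(c("ACGTAC", "TGCATG", "GATCGA", "CCAATT"))
#' sim <- simulate_reads(3, 10, wl, seed = 1)
#' table(sim$truth$expected_status)
simulate_reads <- function(n_cells, reads_per_cell, whitelist, seed,
                           model = error_model(), cfg = read_structure(),
                           pb_range = c(1L, 5L), r2_len = 60L, tail_len = 8L,
                           out_dir = NULL, prefix = "sim") {
  stopifnot(inherits(whitelist, "barcode_whitelist"),
            inherits(cfg, "read_structure"),
            n_cells >= 1, length(pb_range) == 2, pb_range[1] >= 1,
            pb_range[2] >= pb_range[1])
  n_entries <- length(whitelist$entries)
  if (n_cells > n_entries^3) {
    stop("n_cells exceeds the number of distinct barcode triples (",
         n_entries^3, ")", call. = FALSE)
  }
  set.seed(as.integer(seed))

  # distinct (BC1, BC2, BC3) triples
  triples <- matrix(sample(whitelist$entries, 3 * n_cells, replace = TRUE),
                    ncol = 3)
  key <- apply(triples, 1, paste, collapse = "")
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    triples[dup, ] <- sample(whitelist$entries, 3 * length(dup), replace = TRUE)
    key <- apply(triples, 1, paste, collapse = "")
  }

  if (is.function(reads_per_cell)) reads_per_cell <- reads_per_cell(n_cells)
  if (length(reads_per_cell) == 1L) {
    reads_per_cell <- rep(as.integer(reads_per_cell), n_cells)
  }
  stopifnot(length(reads_per_cell) == n_cells, all(reads_per_cell >= 0))
  n <- sum(reads_per_cell)
  cell_of <- rep(seq_len(n_cells), reads_per_cell)

  pb_len <- sample(seq(pb_range[1], pb_range[2]), n, replace = TRUE)
  seg <- tibble(
    pb = .random_seq(n, pb_len),
    bc1 = triples[cell_of, 1],
    l1 = rep(cfg$linker1, n),
    bc2 = triples[cell_of, 2],
    l2 = rep(cfg$linker2, n),
    bc3 = triples[cell_of, 3],
    fpre = rep(cfg$pre_umi_flanker, n),
    umi = .random_seq(n, cfg$umi_len),
    fpost = rep(cfg$post_umi_flanker, n),
    tail = rep(strrep("T", tail_len), n)
  )
  true_barcode <- paste0(seg$bc1, seg$bc2, seg$bc3)
  true_umi <- seg$umi

  # error injection, independent per model row
  errors <- rep("", n)
  seg_map <- c(linker1 = "l1", linker2 = "l2", bc1 = "bc1", bc2 = "bc2",
               bc3 = "bc3", flanker_pre = "fpre", flanker_post = "fpost",
               umi = "umi", phase = "pb")
  for (i in seq_len(nrow(model))) {
    hit <- which(runif(n) < model$prob[i])
    if (!length(hit)) next
    col <- seg_map[[model$target[i]]]
    seg[[col]][hit] <- vapply(
      seg[[col]][hit], .mutate_segment, character(1),
      kind = model$kind[i], count = model$count[i],
      position = model$position[i], USE.NAMES = FALSE
    )
    lab <- paste(model$target[i], model$kind[i], model$count[i], sep = ":")
    errors[hit] <- ifelse(errors[hit] == "", lab, paste(errors[hit], lab, sep = ";"))
  }

  r1 <- paste0(seg$pb, seg$bc1, seg$l1, seg$bc2, seg$l2, seg$bc3,
               seg$fpre, seg$umi, seg$fpost, seg$tail)
  read_id <- sprintf("%s%06d", prefix, seq_len(n))
  reads <- tibble(
    read_id = read_id,
    r1_seq = r1,
    r1_qual = strrep("I", nchar(r1)),
    r2_seq = .random_seq(n, r2_len),
    r2_qual = strrep("I", r2_len)
  )

  pred <- predict_status(seg, cfg, whitelist)
  truth <- tibble(
    read_id = read_id,
    cell_barcode = true_barcode,
    umi = true_umi,
    pb_len = pb_len,
    errors = errors,
    expected_status = pred$expected_status,
    expected_barcode = pred$expected_barcode,
    expected_umi = pred$expected_umi
  )

  out <- structure(
    list(reads = reads, truth = truth, segments = seg, seed = as.integer(seed),
         files = NULL),
    class = "ddseq_sim"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    f <- file.path(out_dir, paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz",
                                             "_truth.tsv")))
    .write_fastq(reads$read_id, reads$r1_seq, reads$r1_qual, f[1])
    .write_fastq(reads$read_id, reads$r2_seq, reads$r2_qual, f[2])
    utils::write.table(truth, f[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- setNames(f, c("r1", "r2", "truth"))
  }
  out
}

#' @export
print.ddseq_sim <- function(x, ...) {
  cat("<ddseq_sim> ", nrow(x$reads), " read pairs, ",
      length(unique(x$truth$cell_barcode)), " cells, seed ", x$seed, "\n",
      sep = "")
  tab <- table(x$truth$expected_status)
  cat("  expected: ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Analytically predict the extraction outcome of simulated reads
#'
#' The generator-side oracle: computes, for every simulated read, the status
#' that the extraction contract mandates, without running the extraction
#' scanner. Linker hits are predicted by a localized brute-force window scan
#' around the known (bookkept) linker position using Levenshtein distances
#' from [utils::adist()], applying the documented interpretation priority
#' (exact > substitution > deletion > insertion) and leftmost-minimal
#' tie-break; geometry budgets, flanker mismatch counting and whitelist
#' neighbourhood uniqueness (again via `adist`, not the package's variant
#' table) then follow the contract arithmetic. The one assumption is that
#' no spurious linker match arises far from the true position, which for
#' 15-nt linkers has negligible probability.
#'
#' @param segments Per-read mutated segment strings (the `segments` element
#'   of a [simulate_reads()] result, or a compatible tibble with columns
#'   `pb`, `bc1`, `l1`, `bc2`, `l2`, `bc3`, `fpre`, `umi`, `fpost`, `tail`).
#' @param cfg The [read_structure()] the reads were generated under.
#' @param whitelist The [barcode_whitelist()] used.
#' @return A tibble with `expected_status` (`"valid"` or an error code),
#'   `expected_barcode` and `expected_umi` (`NA` for invalid reads).
#' @export
predict_status <- function(segments, cfg, whitelist) {
  if (inherits(segments, "ddseq_sim")) segments <- segments$segments
  seg <- segments
  n <- nrow(seg)
  reads <- paste0(seg$pb, seg$bc1, seg$l1, seg$bc2, seg$l2, seg$bc3,
                  seg$fpre, seg$umi, seg$fpost, seg$tail)
  read_len <- nchar(reads)
  bl <- cfg$barcode_len; ul <- cfg$umi_len

  s1_true <- nchar(seg$pb) + nchar(seg$bc1) + 1L
  s2_true <- s1_true + nchar(seg$l1) + nchar(seg$bc2)
  h1 <- .local_candidates(reads, s1_true, cfg$linker1, cfg$max_linker_edits)
  h2 <- .local_candidates(reads, s2_true, cfg$linker2, cfg$max_linker_edits)
  M <- .candidate_pairs(h1, h2, n)

  has1 <- lengths(h1$idx) > 0L
  has2 <- lengths(h2$idx) > 0L
  npair <- tabulate(M[, "read"], n)
  status <- rep(NA_character_, n)
  status[!has1 & !has2] <- "LX"
  status[!has1 & has2] <- "L1"
  status[has1 & npair == 0L] <- "L2"

  bc <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(max(0L, npair))) {
    sel <- M[, "rank"] == k & !valid[M[, "read"]]
    if (!any(sel)) next
    p <- M[sel, , drop = FALSE]
    act <- p[, "read"]
    s1 <- p[, "s1"]; w1 <- p[, "w1"]; s2 <- p[, "s2"]; w2 <- p[, "w2"]
    gap <- s2 - s1
    end2 <- s2 + w2 - 1L
    code <- rep(NA_character_, length(act))
    code[!(gap %in% cfg$accepted_gaps) | abs(gap - w1 - bl) > 1L] <- "D"
    code[is.na(code) & (s1 - 1L < cfg$min_l1_start)] <- "P"
    code[is.na(code) & (read_len[act] < end2 + bl + 3L + ul + 3L)] <- "S"
    open <- is.na(code)
    pre <- substr(reads[act], end2 + bl + 1L, end2 + bl + 3L)
    post <- substr(reads[act], end2 + bl + 3L + ul + 1L,
                   end2 + bl + 3L + ul + 3L)
    mm <- .flanker_mismatches(pre, post, cfg)
    code[open & mm > cfg$max_flanker_mismatches] <- "T"
    open <- is.na(code)
    cellk <- rep(NA_character_, length(act))
    umik <- rep(NA_character_, length(act))
    if (any(open)) {
      m1 <- .adist_match(substr(reads[act], s1 - bl, s1 - 1L)[open],
                         whitelist, cfg$max_barcode_edits)
      m2 <- .adist_match(substr(reads[act], s1 + w1, s2 - 1L)[open],
                         whitelist, cfg$max_barcode_edits)
      m3 <- .adist_match(substr(reads[act], end2 + 1L, end2 + bl)[open],
                         whitelist, cfg$max_barcode_edits)
      cc <- ifelse(is.na(m1) | is.na(m2) | is.na(m3), NA_character_,
                   paste0(m1, m2, m3))
      cellk[open] <- cc
      umik[open] <- substr(reads[act], end2 + bl + 4L,
                           end2 + bl + 3L + ul)[open]
      code[open][is.na(cc)] <- "B"
    }
    if (k == 1L) status[act] <- code
    okv <- is.na(code)
    adopt <- act[okv]
    valid[adopt] <- TRUE
    status[adopt] <- NA_character_
    bc[adopt] <- cellk[okv]
    umi[adopt] <- umik[okv]
  }

  status[valid] <- "valid"
  tibble(
    expected_status = status,
    expected_barcode = ifelse(valid, bc, NA_character_),
    expected_umi = ifelse(valid, umi, NA_character_)
  )
}

# localized brute-force window classification around the bookkept linker
# position: every (start, span) window with starts S-2..S+2 and spans
# {L, L-1, L+1}, Levenshtein distances via utils::adist.  Only
# minimal-distance candidates are kept, ordered by (start, then
# exact/substitution > deletion > insertion), mirroring the scanner's hit
# ordering.  Returns the same (start, width, idx) shape as .minimal_hits.
.local_candidates <- function(reads, S, linker, max_edits) {
  n <- length(reads)
  L <- nchar(linker)
  read_len <- nchar(reads)
  offs <- -2:2
  spans <- c(L, L - 1L, L + 1L)  # per-start priority order
  nc <- length(offs) * length(spans)
  D <- matrix(Inf, n, nc)
  W <- matrix(NA_integer_, n, nc)
  St <- matrix(NA_integer_, n, nc)
  Pr <- matrix(NA_integer_, n, nc)
  col <- 0L
  for (o in offs) {
    st <- S + o
    for (si in seq_along(spans)) {
      col <- col + 1L
      w <- spans[si]
      en <- st + w - 1L
      St[, col] <- st
      W[, col] <- w
      Pr[, col] <- si
      need <- st >= 1L & en <= read_len
      if (!any(need)) next
      d <- as.vector(adist(substr(reads, st, en)[need], linker))
      hit <- d <= max_edits
      D[which(need)[hit], col] <- d[hit]
    }
  }
  rmin <- D[, 1]
  for (j in 2:nc) rmin <- pmin(rmin, D[, j])
  cand <- is.finite(D) & D == rmin
  rows <- row(D)[cand]
  starts <- St[cand]
  widths <- W[cand]
  prio <- Pr[cand]
  ord <- order(rows, starts, prio)
  rows <- rows[ord]
  list(start = starts[ord], width = widths[ord],
       idx = unname(split(seq_along(rows), factor(rows, levels = seq_len(n)))))
}

# exhaustive whitelist resolution via Levenshtein distances (oracle route,
# independent of the variant-table lookup used by match_barcode)
.adist_match <- function(blocks, whitelist, max_edits) {
  out <- whitelist$entries[match(blocks, whitelist$entries)]
  todo <- which(is.na(out))
  if (length(todo) && max_edits >= 1) {
    d <- adist(blocks[todo], whitelist$entries)
    nn <- rowSums(d <= max_edits)
    uniq <- nn == 1L
    out[todo[uniq]] <- whitelist$entries[apply(
      d[uniq, , drop = FALSE], 1, which.min)]
  }
  out
}
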