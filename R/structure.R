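#' Read 1 structure configuration
#'
#' Declarative description of the anatomy of Read 1 in a ddSEQ/SureCell
#' library: a phase block of variable length, three barcode blocks (BC1,
#' BC2, BC3) separated by two fixed 15-nt linkers, then the UMI bracketed by
#' the `ACG` and `GAC` trinucleotides. All tolerances used by the extraction
#' checks live here.
#'
#' The default linkers are the SureCell WTA 3' linker sequences. With the
#' defaults, the distance between the two linker start positions on a clean
#' read is exactly `barcode_len + nchar(linker1)` = 21 nt; the accepted gap
#' set is `{20, 21, 22}` because a single insertion or deletion in BC2 (or in
#' linker 1 itself) shifts the gap by one while remaining correctable.
#' `strict_gap = TRUE` restricts the gap to exactly 21 nt.
#'
#' @param linker1,linker2 Linker nucleotide sequences (A/C/G/T, equal
#'   purpose-built length, default 15 nt each; must differ).
#' @param barcode_len Length of each barcode block in nt (default 6).
#' @param umi_len UMI length in nt (default 8, per SureCell chemistry).
#' @param pre_umi_flanker,post_umi_flanker Trinucleotides bracketing the UMI.
#' @param min_l1_start Minimum number of read bases that must precede the
#'   linker-1 match (default 7 = one phase-block base + BC1).
#' @param max_linker_edits Levenshtein budget per linker, 0 or 1 (default 1:
#'   one substitution OR one indel, not both).
#' @param max_flanker_mismatches Total mismatch budget across both UMI
#'   flankers (default 1; no indels are considered for the flankers).
#' @param max_barcode_edits Levenshtein budget per barcode block for
#'   whitelist correction, 0 or 1 (default 1).
#' @param strict_gap If `TRUE` only the canonical 21-nt linker gap is
#'   accepted (disables indel absorption in BC2/linker 1).
#'
#' @return An object of class `read_structure` (a named list).
#' @seealso [read_structure_file()] to load a `key=value` structure file.
#' @export
#' @examples
#' cfg <- read_structure()
#' cfg
#' toy <- read_structure(linker1 = "AAAAATTTTTGGGGG", linker2 = "CCCCCGGGGGAAAAA")
read_structure <- function(linker1 = "TAGCCATCGCATTGC",
                           linker2 = "TACCTCTGAGCTGAA",
                           barcode_len = 6L,
                           umi_len = 8L,
                           pre_umi_flanker = "ACG",
                           post_umi_flanker = "GAC",
                           min_l1_start = 7L,
                           max_linker_edits = 1L,
                           max_flanker_mismatches = 1L,
                           max_barcode_edits = 1L,
                           strict_gap = FALSE) {
  linker1 <- toupper(linker1); linker2 <- toupper(linker2)
  stopifnot(
    grepl("^[ACGT]+$", linker1), grepl("^[ACGT]+$", linker2),
    barcode_len >= 1, umi_len >= 1,
    nchar(pre_umi_flanker) == 3, nchar(post_umi_flanker) == 3,
    max_linker_edits %in% 0:1, max_barcode_edits %in% 0:1,
    max_flanker_mismatches >= 0
  )
  if (linker1 == linker2) {
    stop("linker1 and linker2 must differ", call. = FALSE)
  }
  if (min_l1_start < barcode_len + 1) {
    stop("min_l1_start must be at least barcode_len + 1 ",
         "(a phase block of at least 1 nt precedes BC1)", call. = FALSE)
  }
  gap <- barcode_len + nchar(linker1)
  cfg <- list(
    linker1 = linker1,
    linker2 = linker2,
    barcode_len = as.integer(barcode_len),
    umi_len = as.integer(umi_len),
    pre_umi_flanker = toupper(pre_umi_flanker),
    post_umi_flanker = toupper(post_umi_flanker),
    expected_linker_gap = as.integer(gap),
    accepted_gaps = if (strict_gap) as.integer(gap) else as.integer(gap + (-1:1)),
    min_l1_start = as.integer(min_l1_start),
    max_linker_edits = as.integer(max_linker_edits),
    max_flanker_mismatches = as.integer(max_flanker_mismatches),
    max_barcode_edits = as.integer(max_barcode_edits),
    strict_gap = isTRUE(strict_gap)
  )
  structure(cfg, class = "read_structure")
}

#' @export
print.read_structure <- function(x, ...) {
  cat("<read_structure>\n")
  cat("  linker1:", x$linker1, " linker2:", x$linker2, "\n")
  cat("  barcode_len:", x$barcode_len, " umi_len:", x$umi_len, "\n")
  cat("  UMI flankers:", x$pre_umi_flanker, "/", x$post_umi_flanker, "\n")
  cat("  linker gap:", paste(x$accepted_gaps, collapse = "/"),
      " min bases before L1:", x$min_l1_start, "\n")
  cat("  budgets: linker", x$max_linker_edits, "edit(s), flankers",
      x$max_flanker_mismatches, "mismatch(es), barcode",
      x$max_barcode_edits, "edit(s)\n")
  invisible(x)
}

#' Load a Read 1 structure configuration from a key=value file
#'
#' Plain-text configuration with one `key=value` pair per line; `#` starts a
#' comment. Recognised keys match the arguments of [read_structure()]
#' (`linker1`, `linker2`, `barcode_len`, `umi_len`, `pre_umi_flanker`,
#' `post_umi_flanker`, `min_l1_start`, `max_linker_edits`,
#' `max_flanker_mismatches`, `max_barcode_edits`, `strict_gap`). All keys are
#' optional; missing keys take the defaults. An editable copy of the default
#' configuration ships as
#' `system.file("extdata", "surecell_structure.txt", package = "ddseqr")`.
#'
#' @param path Path to the structure file.
#' @return A `read_structure` object.
#' @export
#' @examples
#' cfg <- read_structure_file(
#'   system.file("extdata", "surecell_structure.txt", package = "ddseqr")
#' )
read_structure_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("malformed structure line (expected key=value): ", lines[bad][1],
         call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(read_structure))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown structure key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- as.list(vals)
  names(args) <- keys
  int_keys <- c("barcode_len", "umi_len", "min_l1_start", "max_linker_edits",
                "max_flanker_mismatches", "max_barcode_edits")
  for (k in intersect(names(args), int_keys)) args[[k]] <- as.integer(args[[k]])
  if ("strict_gap" %in% names(args)) {
    args$strict_gap <- toupper(args$strict_gap) %in% c("TRUE", "T", "YES", "1")
  }
  do.call(read_structure, args)
}
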