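LINKER_EDIT_TYPES <- c("exact", "substitution", "deletion", "insertion")

#' Locate a linker inside Read 1 sequences with single-edit tolerance
#'
#' Scans each sequence for windows within Levenshtein distance `max_edits`
#' of the linker. At every candidate start the best interpretation is kept,
#' with priority exact > substitution > deletion > insertion; a deletion hit
#' spans `nchar(linker) - 1` read bases, an insertion hit
#' `nchar(linker) + 1`. Hits are ordered by (edit distance, start), so the
#' first hit per sequence is the leftmost minimal-distance match. `N` bases
#' never match. Coordinates are 1-based with inclusive ends.
#'
#' @param seqs Character vector of read sequences (uppercased internally).
#' @param linker Linker sequence (A/C/G/T).
#' @param max_edits Levenshtein budget, 0 or 1 (default 1).
#' @return A tibble with columns `seq` (index into `seqs`), `start`, `end`,
#'   `width`, `edit_distance` and `edit_type`; zero rows where nothing
#'   matches.
#' @export
#' @examples
#' find_linker("GTACGTACAAAAATTTTTGGGGGTGCATG", "AAAAATTTTTGGGGG")
find_linker <- function(seqs, linker, max_edits = 1L) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, max_edits %in% 0:1)
  linker <- toupper(linker)
  stopifnot(grepl("^[ACGT]+$", linker))
  raw <- .scan_linker_batch(toupper(seqs), linker, as.integer(max_edits))
  tibble(
    seq = raw$seq,
    start = raw$start,
    end = raw$start + raw$width - 1L,
    width = raw$width,
    edit_distance = raw$edit_distance,
    edit_type = LINKER_EDIT_TYPES[raw$type_code + 1L]
  )
}
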