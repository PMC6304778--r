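#' Barcode-block whitelist with 1-edit lookup
#'
#' Builds the lookup structure used to validate and correct individual
#' barcode blocks. Besides exact membership, the whitelist supports
#' unique-within-edit-distance-1 lookup: every string reachable from an
#' entry by one substitution, one deletion or one insertion is precomputed
#' into a variant table, so a query resolves in a single hashed `match()`.
#' Variants shared by two or more entries are marked ambiguous and never
#' resolved to either entry (this avoids silently merging distinct cells).
#' An `N` in a query matches no base and therefore costs one edit.
#'
#' @param entries Character vector of distinct barcode blocks, all the same
#'   length, over A/C/G/T.
#' @return An object of class `barcode_whitelist`.
#' @seealso [read_barcode_whitelist()], [match_barcode()]
#' @export
#' @examples
#' wl <- barcode_whitelist(c("ACGTAC", "TGCATG", "GATCGA"))
#' wl
barcode_whitelist <- function(entries) {
  entries <- toupper(as.character(entries))
  if (!length(entries)) stop("whitelist is empty", call. = FALSE)
  if (!all(grepl("^[ACGT]+$", entries))) {
    stop("whitelist entries must contain only A/C/G/T", call. = FALSE)
  }
  if (length(unique(nchar(entries))) != 1L) {
    stop("whitelist entries must all have the same length", call. = FALSE)
  }
  if (anyDuplicated(entries)) {
    stop("whitelist contains duplicate entries", call. = FALSE)
  }
  vt <- .variant_table(entries)
  structure(
    list(entries = entries, barcode_len = nchar(entries[1]),
         variant_key = vt$key, variant_entry = vt$entry),
    class = "barcode_whitelist"
  )
}

# All strings at Levenshtein distance exactly 1 from each entry:
# substitutions (including to N, so single-N queries resolve), deletions,
# and insertions (including of N).  Variants reachable from >1 entry, or
# colliding with an exact entry, get NA (= ambiguous / shadowed).
.variant_table <- function(entries) {
  bases <- c("A", "C", "G", "T")
  sub_bases <- c(bases, "N")
  L <- nchar(entries[1])
  keys <- character(0); owners <- character(0)
  for (e in entries) {
    ch <- strsplit(e, "", fixed = TRUE)[[1]]
    v <- character(0)
    for (i in seq_len(L)) {
      for (b in setdiff(sub_bases, ch[i])) {
        x <- ch; x[i] <- b
        v <- c(v, paste(x, collapse = ""))
      }
      v <- c(v, paste(ch[-i], collapse = ""))
    }
    for (i in 0:L) {
      for (b in sub_bases) {
        v <- c(v, paste(c(head(ch, i), b, ch[seq_len(L - i) + i]), collapse = ""))
      }
    }
    v <- setdiff(unique(v), e)
    keys <- c(keys, v)
    owners <- c(owners, rep(e, length(v)))
  }
  first <- !duplicated(keys)
  owner_of <- owners[first]
  key_of <- keys[first]
  amb <- tapply(owners, keys, function(o) length(unique(o)) > 1L)
  owner_of[amb[key_of]] <- NA_character_
  owner_of[key_of %in% entries] <- NA_character_  # exact entries shadow variants
  list(key = key_of, entry = owner_of)
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat("<barcode_whitelist> ", length(x$entries), " entries of ",
      x$barcode_len, " nt (", sum(is.na(x$variant_entry)),
      " ambiguous 1-edit variants)\n", sep = "")
  invisible(x)
}

#' Read a barcode-block whitelist from a text file
#'
#' One barcode per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the whitelist file.
#' @return A `barcode_whitelist` object.
#' @export
#' @examples
#' wl <- read_barcode_whitelist(
#'   system.file("extdata", "synthetic_barcode_blocks_96.txt", package = "ddseqr")
#' )
read_barcode_whitelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  barcode_whitelist(lines[nzchar(lines)])
}

#' Match barcode blocks against a whitelist within edit distance one
#'
#' Resolves raw barcode blocks to whitelist entries. An exact member is
#' returned as-is; otherwise the unique entry within Levenshtein distance
#' `max_edits` is returned in corrected form. Blocks one base shorter or
#' longer than the entry length (as arise from a single indel implied by the
#' linker geometry) are matched through deletion/insertion variants. A block
#' with no neighbour, or with neighbours in two or more entries, is not
#' resolved; both cases surface as error code `B` during extraction.
#'
#' @param blocks Character vector of raw barcode blocks.
#' @param whitelist A [barcode_whitelist()].
#' @param max_edits Edit budget, 0 or 1 (default 1).
#' @return A tibble with one row per block: `block`, `barcode` (the resolved
#'   whitelist entry or `NA`), and `match` (one of `"exact"`, `"corrected"`,
#'   `"ambiguous"`, `"none"`).
#' @export
#' @examples
#' wl <- barcode_whitelist(c("ACGTAC", "TGCATG"))
#' match_barcode(c("ACGTAC", "ACGTAT", "ACGTA", "TTTTTT"), wl)
match_barcode <- function(blocks, whitelist, max_edits = 1L) {
  stopifnot(inherits(whitelist, "barcode_whitelist"), max_edits %in% 0:1)
  blocks <- toupper(as.character(blocks))
  barcode <- whitelist$entries[match(blocks, whitelist$entries)]
  kind <- ifelse(is.na(barcode), "none", "exact")
  if (max_edits >= 1L) {
    todo <- is.na(barcode)
    if (any(todo)) {
      i <- match(blocks[todo], whitelist$variant_key)
      hit <- !is.na(i)
      ent <- whitelist$variant_entry[i[hit]]
      b2 <- barcode[todo]; k2 <- kind[todo]
      b2[hit] <- ent
      k2[hit] <- ifelse(is.na(ent), "ambiguous", "corrected")
      barcode[todo] <- b2; kind[todo] <- k2
    }
  }
  tibble(block = blocks, barcode = barcode, match = kind)
}
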