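#' Scan a sequence for SL units
#'
#' Leftmost-greedy non-overlapping unit calling. The sequence is scanned
#' left to right; at each position the scanner tests, in priority order,
#' a FULL canonical SL (up to `maxMismatches` substitutions), then an exact
#' VARIANT (TCG-opened first unit), then an exact RELICT. On a hit the unit
#' is emitted and scanning resumes immediately after it, so positions inside
#' an emitted unit are never reused; in particular the relict embedded in
#' every canonical SL (the relict is a suffix of the SL) is not
#' double-counted. `N` bases never match any motif base.
#'
#' @param seq a single DNA sequence (character or [Biostrings::DNAString]).
#' @param motifs an [SLMotifSet-class] (default [slMotifs()]).
#' @return An [IRanges::IRanges] of unit spans (1-based inclusive) with
#'   metadata columns `kind` (`FULL`/`VARIANT`/`RELICT`) and `mismatches`.
#'   Zero-length when no unit is found.
#' @examples
#' sl <- slMotifs()
#' scanSequence(paste0("AAAA", sl@sl, "AAAA"))
#' @export
scanSequence <- function(seq, motifs = slMotifs()) {
  s <- toupper(as.character(seq))
  stopifnot(length(s) == 1L, nzchar(s))
  L <- nchar(s)
  kinds <- c("FULL", "VARIANT", "RELICT")
  pats <- c(FULL = motifs@sl, VARIANT = motifs@variant,
            RELICT = motifs@relict)
  lens <- nchar(pats)
  maxMM <- motifs@maxMismatches
  outStart <- integer(0); outKind <- character(0); outMM <- integer(0)
  i <- 1L
  while (i <= L) {
    hit <- NA_character_; hmm <- 0L
    for (k in kinds) {
      if (i + lens[[k]] - 1L > L) next
      if (k == "FULL" && maxMM > 0L) {
        mm <- cpp_mismatches_at(s, pats[[k]], i)
        if (mm <= maxMM) { hit <- k; hmm <- mm; break }
      } else if (substr(s, i, i + lens[[k]] - 1L) == pats[[k]]) {
        hit <- k; hmm <- 0L; break
      }
    }
    if (!is.na(hit)) {
      outStart <- c(outStart, i); outKind <- c(outKind, hit)
      outMM <- c(outMM, hmm)
      i <- i + lens[[hit]]
    } else i <- i + 1L
  }
  res <- IRanges::IRanges(start = outStart, width = unname(lens[outKind]))
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    kind = outKind, mismatches = outMM)
  res
}

#' @describeIn scanSequence scan a set of sequences; returns a named list
#'   of `IRanges`, one per input sequence.
#' @param seqs a named [Biostrings::DNAStringSet] or character vector.
#' @export
scanSequences <- function(seqs, motifs = slMotifs()) {
  out <- lapply(as.character(seqs), scanSequence, motifs = motifs)
  names(out) <- names(seqs)
  out
}

.unitCounts <- function(match) {
  k <- as.character(S4Vectors::mcols(match)$kind)
  c(FULL = sum(k == "FULL"), VARIANT = sum(k == "VARIANT"),
    RELICT = sum(k == "RELICT"))
}

#' Select SL-containing reads and SL-like candidates
#'
#' A read is SL-containing iff it carries at least one FULL canonical SL
#' unit. Reads with no FULL unit but at least two RELICT/VARIANT units are
#' routed to a separate SL-like candidate pool (the published filter:
#' candidates with only one SL or relict are removed as likely random
#' occurrences). All other reads are discarded.
#'
#' @param reads named [Biostrings::DNAStringSet] of deduplicated
#'   sense-strand reads.
#' @param motifs an [SLMotifSet-class].
#' @return A list:
#' \describe{
#'   \item{slReads, slMatches}{SL-containing reads and their unit calls.}
#'   \item{histogram}{named integer vector: number of reads per FULL-unit
#'     count.}
#'   \item{slLikeReads, slLikeMatches}{the SL-like candidate pool.}
#' }
#' @export
selectSLReads <- function(reads, motifs = slMotifs()) {
  if (length(reads) == 0L) {
    empty <- if (is.character(reads)) character(0) else
      Biostrings::DNAStringSet()
    return(list(slReads = empty, slMatches = list(),
                histogram = stats::setNames(integer(0), character(0)),
                slLikeReads = empty, slLikeMatches = list()))
  }
  matches <- scanSequences(reads, motifs)
  cnt <- t(vapply(matches, .unitCounts, integer(3)))
  isSL <- cnt[, "FULL"] >= 1L
  isLike <- !isSL & (cnt[, "VARIANT"] + cnt[, "RELICT"]) >= 2L
  hist <- table(factor(cnt[isSL, "FULL"]))
  histogram <- stats::setNames(as.integer(hist), names(hist))
  list(slReads = reads[isSL], slMatches = matches[isSL],
       histogram = histogram,
       slLikeReads = reads[isLike], slLikeMatches = matches[isLike])
}

#' Count (possibly overlapping) exact motif occurrences
#'
#' Shared counting kernel for unit scanning and motif enrichment. `N` in
#' the subject never matches a motif base.
#'
#' @param seq a DNA sequence (character or [Biostrings::DNAString]).
#' @param motif a DNA motif (character). A motif longer than `seq` yields 0.
#' @return Integer count of exact, possibly overlapping occurrences.
#' @examples
#' countMotifOccurrences("AAAA", "AA")  # 3
#' @export
countMotifOccurrences <- function(seq, motif) {
  stopifnot(nzchar(motif))
  s <- toupper(as.character(seq))
  if (nchar(motif) > nchar(s)) return(0L)
  Biostrings::countPattern(toupper(motif), Biostrings::DNAString(s),
                           fixed = TRUE)
}
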