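#' Classify one consensus sequence into an SL gene class
#'
#' Class rules: at least one FULL canonical unit gives `SINGLE_SL` (exactly
#' one FULL) or `TANDEM_SL` (two or more FULL); no FULL unit but at least
#' two RELICT/VARIANT units gives `SL_LIKE`; anything else is discarded
#' (`NULL`), mirroring the published filter that removes candidates with a
#' single SL or relict as probable random occurrences. Tandem class keys on
#' FULL units only: a consensus with one FULL SL followed by relicts is a
#' `SINGLE_SL` call (raw unit counts are always reported so loci can be
#' re-binned).
#'
#' The upstream extension is everything 5' of the first unit; `core_len`
#' (total minus upstream) is the length measure comparable to SL genes
#' cloned with SL-anchored primers.
#'
#' @param sequence consensus DNA sequence (character or
#'   [Biostrings::DNAString]).
#' @param motifs an [SLMotifSet-class].
#' @param consensusId id recorded in the call.
#' @return A one-row data.frame
#'   (`consensus_id`, `gene_class`, `n_full`, `n_relict`, `n_variant`,
#'   `upstream_len`, `total_len`, `core_len`, `downstream_seq`), or `NULL`
#'   for discarded consensi.
#' @export
classifyConsensus <- function(sequence, motifs = slMotifs(),
                              consensusId = "consensus1") {
  s <- toupper(as.character(sequence))
  m <- scanSequence(s, motifs)
  cnt <- .unitCounts(m)
  if (cnt[["FULL"]] >= 1L) {
    cls <- if (cnt[["FULL"]] >= 2L) "TANDEM_SL" else "SINGLE_SL"
  } else if (cnt[["VARIANT"]] + cnt[["RELICT"]] >= 2L) {
    cls <- "SL_LIKE"
  } else return(NULL)
  first <- IRanges::start(m)[1]
  last <- IRanges::end(m)[length(m)]
  data.frame(
    consensus_id = consensusId, gene_class = cls,
    n_full = unname(cnt[["FULL"]]), n_relict = unname(cnt[["RELICT"]]),
    n_variant = unname(cnt[["VARIANT"]]),
    upstream_len = first - 1L, total_len = nchar(s),
    core_len = nchar(s) - (first - 1L),
    downstream_seq = substr(s, last + 1L, nchar(s)),
    stringsAsFactors = FALSE)
}

#' Classify an assembled consensus set
#'
#' Applies [classifyConsensus()] to every consensus and appends cluster
#' read counts and, when a library size is supplied, expression in reads
#' per million.
#'
#' @param consensi an [SLConsensusSet-class].
#' @param motifs an [SLMotifSet-class].
#' @param libraryTotalReads total deduplicated reads in the library
#'   (the rpm denominator, counted before SL filtering); `NA` skips rpm.
#' @return A data.frame of locus calls (zero rows if every consensus is
#'   discarded), with columns as in [classifyConsensus()] plus `n_reads`,
#'   `donor`, `donor_ok`, and `expression_rpm`.
#' @export
classifyConsensusSet <- function(consensi, motifs = slMotifs(),
                                 libraryTotalReads = NA_integer_) {
  ids <- names(consensi)
  rows <- lapply(seq_along(ids), function(i)
    classifyConsensus(as.character(consensusSequences(consensi)[[i]]),
                      motifs, consensusId = ids[i]))
  keep <- !vapply(rows, is.null, logical(1))
  nReads <- vapply(clusterMembers(consensi), nrow, integer(1))
  calls <- do.call(rbind, rows[keep])
  if (is.null(calls))
    calls <- data.frame(consensus_id = character(0),
                        gene_class = character(0), n_full = integer(0),
                        n_relict = integer(0), n_variant = integer(0),
                        upstream_len = integer(0), total_len = integer(0),
                        core_len = integer(0),
                        downstream_seq = character(0),
                        stringsAsFactors = FALSE)
  calls$n_reads <- unname(nReads[calls$consensus_id])
  donor <- substr(calls$downstream_seq, 1L, 2L)
  calls$donor <- donor
  calls$donor_ok <- nchar(calls$downstream_seq) >= 2L &
    donor %in% c("GT", "GC")
  calls$expression_rpm <- if (nrow(calls) == 0L) numeric(0) else
    if (!is.na(libraryTotalReads))
      expressionRPM(calls$n_reads, libraryTotalReads) else NA_real_
  calls
}

#' Length summary of classified SL loci
#'
#' Arithmetic summaries over the `SINGLE_SL` and `TANDEM_SL` calls only
#' (SL-like loci are reported separately): minimum, maximum and mean of the
#' total locus length, and the mean of the core length (total minus the
#' upstream extension, the measure comparable to SL-anchored cloning).
#' Full precision is retained; round in reports as needed.
#'
#' @param calls a data.frame of locus calls.
#' @return list with `min`, `max`, `meanTotal`, `meanCore`, `n`.
#' @export
lengthSummary <- function(calls) {
  sl <- calls[calls$gene_class %in% c("SINGLE_SL", "TANDEM_SL"), ,
              drop = FALSE]
  if (nrow(sl) == 0L) stop("no SINGLE_SL/TANDEM_SL calls to summarise")
  list(min = min(sl$total_len), max = max(sl$total_len),
       meanTotal = mean(sl$total_len), meanCore = mean(sl$core_len),
       n = nrow(sl))
}

#' Expression in reads per million
#'
#' `rpm = 1e6 * count / libraryTotalReads`. The denominator is the total
#' deduplicated read count of the library (before SL filtering), summed
#' across libraries for pooled estimates.
#'
#' @param counts per-locus read counts.
#' @param libraryTotalReads total deduplicated reads (> 0).
#' @return Numeric vector of rpm values.
#' @examples
#' expressionRPM(17, 1e6)  # 17
#' @export
expressionRPM <- function(counts, libraryTotalReads) {
  if (length(libraryTotalReads) != 1L || is.na(libraryTotalReads) ||
      libraryTotalReads <= 0)
    stop("'libraryTotalReads' must be a single positive count")
  stopifnot(all(counts >= 0))
  1e6 * counts / libraryTotalReads
}
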