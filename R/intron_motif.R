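#' Default U-rich motif panel
#'
#' The union of the U-rich motifs reported for dinoflagellate SL gene
#' introns and examined as candidate Sm-protein binding sites:
#' CUUUG, CUUUUG, GUUUA, GUUUUC, GUUUUA, UUUAA (RNA alphabet).
#'
#' @return Character vector of RNA-alphabet motifs.
#' @export
uRichMotifs <- function() {
  c("CUUUG", "CUUUUG", "GUUUA", "GUUUUC", "GUUUUA", "UUUAA")
}

.rna2dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Extract candidate intron sequences downstream of the SL
#'
#' For every call with at least one FULL unit, the candidate intron is the
#' consensus suffix starting immediately after the end of the LAST full SL
#' unit (the SL terminates in AAG, the exon/intron boundary). No acceptor
#' site is modelled: the candidate runs to the consensus end. Calls whose
#' consensus ends exactly at the SL yield no candidate.
#'
#' @param calls data.frame of locus calls from [classifyConsensusSet()]
#'   (needs `consensus_id`, `gene_class`, `n_full`, `downstream_seq`).
#' @return data.frame with columns `consensus_id`, `sequence`, `donor`
#'   (first two bases) and `donor_ok` (donor is GT or GC); zero rows if no
#'   call qualifies.
#' @export
extractIntrons <- function(calls) {
  keep <- calls$n_full >= 1L & nchar(calls$downstream_seq) > 0L
  x <- calls[keep, , drop = FALSE]
  donor <- substr(x$downstream_seq, 1L, 2L)
  data.frame(consensus_id = x$consensus_id, sequence = x$downstream_seq,
             donor = donor,
             donor_ok = nchar(x$downstream_seq) >= 2L &
               donor %in% c("GT", "GC"),
             stringsAsFactors = FALSE)
}

#' Splice-donor dinucleotide check
#'
#' TRUE iff the sequence downstream of the last unit (full SL for SL genes;
#' relict/variant for SL-like loci) is at least 2 bp long and starts with
#' GT or GC, the 5' dinucleotides characteristic of dinoflagellate introns.
#' SL-like loci are expected to fail this check.
#'
#' @param calls data.frame of locus calls (needs `downstream_seq`).
#' @return Named logical vector (names = `consensus_id`).
#' @export
donorCheck <- function(calls) {
  donor <- substr(calls$downstream_seq, 1L, 2L)
  stats::setNames(nchar(calls$downstream_seq) >= 2L &
                    donor %in% c("GT", "GC"), calls$consensus_id)
}

#' U-rich motif enrichment over an intron set
#'
#' Counts the overlapping occurrences of each motif across the intron set
#' and normalises by the expected count under a uniform 25%-per-base
#' background: `expected = positionsScanned * 4^-n`, where
#' `positionsScanned = sum over introns of max(0, L - n + 1)` and `n` is
#' the motif length. The per-position Bernoulli expectation ignores overlap
#' dependence, which is adequate for the large ratios of interest. The
#' original report printed the normalisation as `1/n^4`; that literal form
#' has no probabilistic meaning (it is independent of the sequence
#' composition space) but is available via `expected = "literal"` for
#' replication.
#'
#' @param introns character vector of intron sequences (DNA alphabet), or
#'   the data.frame from [extractIntrons()].
#' @param motifs RNA-alphabet motifs (default [uRichMotifs()]); scanned as
#'   DNA with U mapped to T.
#' @param expected `"uniform"` (default, `4^-n` per position) or
#'   `"literal"` (`1/n^4` per position).
#' @return data.frame with columns `motif`, `n`, `observed`,
#'   `positions_scanned`, `expected`, `ratio` (`observed/expected`;
#'   `NaN`-free: 0 when nothing was scanned).
#' @examples
#' motifEnrichment("GTTTTC", "GUUUUC")$ratio  # 4096
#' @export
motifEnrichment <- function(introns, motifs = uRichMotifs(),
                            expected = c("uniform", "literal")) {
  expected <- match.arg(expected)
  if (is.data.frame(introns)) introns <- introns$sequence
  introns <- toupper(as.character(introns))
  if (length(introns) == 0L) stop("empty intron set")
  out <- lapply(motifs, function(mo) {
    pat <- .rna2dna(mo)
    n <- nchar(pat)
    ps <- sum(pmax(0L, nchar(introns) - n + 1L))
    obs <- sum(vapply(introns, countMotifOccurrences, integer(1),
                      motif = pat))
    exp_ <- ps * (if (expected == "uniform") 4^(-n) else 1 / n^4)
    data.frame(motif = mo, n = n, observed = obs, positions_scanned = ps,
               expected = exp_,
               ratio = if (exp_ > 0) obs / exp_ else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Locate a motif within a consensus, relative to the SL 3' end
#'
#' Reports every overlapping occurrence of the motif in the consensus,
#' annotated with its signed distance from the 3' end of the last FULL SL
#' unit: 0 means immediately adjacent downstream, negative values lie
#' upstream of (or within) the SL block. Used to situate candidate
#' Sm-binding motifs relative to the exon/intron boundary; secondary
#' structure itself is not predicted here.
#'
#' @param sequence consensus DNA sequence.
#' @param motif RNA- or DNA-alphabet motif.
#' @param motifs an [SLMotifSet-class] used to find the last FULL unit.
#' @return data.frame with columns `start` (1-based) and `distance`,
#'   ascending; zero rows when the motif is absent. Errors if the
#'   consensus has no FULL unit.
#' @export
locateMotif <- function(sequence, motif, motifs = slMotifs()) {
  s <- toupper(as.character(sequence))
  m <- scanSequence(s, motifs)
  kinds <- as.character(S4Vectors::mcols(m)$kind)
  if (!any(kinds == "FULL"))
    stop("consensus contains no FULL SL unit")
  lastEnd <- max(IRanges::end(m)[kinds == "FULL"])
  hits <- Biostrings::matchPattern(.rna2dna(motif), Biostrings::DNAString(s),
                                   fixed = TRUE)
  st <- IRanges::start(hits)
  data.frame(start = st, distance = st - lastEnd - 1L)
}
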