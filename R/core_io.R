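#' Read a paired (or single-end) stranded FASTQ library
#'
#' Reads one or both mates of a stranded library. Read ids are stripped of
#' comments (everything after the first whitespace) and of trailing `/1`,
#' `/2` mate suffixes. In paired mode the two files must contain the same
#' records in the same order; a count or id mismatch is a hard error naming
#' the first offending record.
#'
#' Qualities are not retained: the pipeline is motif- and overlap-driven and
#' performs no quality-aware step.
#'
#' @param pathR1,pathR2 FASTQ file paths; either may be `NULL` for
#'   single-end input.
#' @param libraryId label recorded as the library of origin.
#' @return A [StrandedReadPairs-class] object.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
#' readFastqPairs(pathR2 = fq)
#' @export
readFastqPairs <- function(pathR1 = NULL, pathR2 = NULL,
                           libraryId = "library1") {
  if (is.null(pathR1) && is.null(pathR2))
    stop("at least one of 'pathR1', 'pathR2' must be given")
  readOne <- function(path, mate) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path))
      stop(sprintf("%s file not found: %s", mate, path))
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq"),
      error = function(e) stop(sprintf(
        "malformed FASTQ in %s file '%s': %s", mate, path,
        conditionMessage(e)), call. = FALSE))
    names(x) <- sub("/[12]$", "", sub("\\s.*$", "", names(x)))
    x
  }
  r1 <- readOne(pathR1, "R1")
  r2 <- readOne(pathR2, "R2")
  mates <- c("R1", "R2")[c(!is.null(r1), !is.null(r2))]
  if (!is.null(r1) && !is.null(r2)) {
    if (length(r1) != length(r2))
      stop(sprintf(paste0("FASTQ pair mismatch: R1 has %d records, R2 has ",
                          "%d (first unpaired record index %d)"),
                   length(r1), length(r2), min(length(r1), length(r2)) + 1L))
    bad <- which(names(r1) != names(r2))
    if (length(bad))
      stop(sprintf("FASTQ pair mismatch: read ids differ at record %d ('%s' vs '%s')",
                   bad[1], names(r1)[bad[1]], names(r2)[bad[1]]))
  }
  if (is.null(r1)) r1 <- Biostrings::DNAStringSet()
  if (is.null(r2)) r2 <- Biostrings::DNAStringSet()
  new("StrandedReadPairs", r1 = r1, r2 = r2, mates = mates,
      libraryId = libraryId)
}

#' Extract the sense-strand reads of a stranded library
#'
#' Under the TruSeq stranded protocol the reverse read (R2) carries the
#' transcript sense strand, so SL searches operate on R2 verbatim; the
#' antisense mate is neither reverse-complemented nor merged. Other kits
#' invert the convention, hence `senseMate` is configurable.
#'
#' @param pairs a [StrandedReadPairs-class] object.
#' @param senseMate which mate carries the transcript sense strand
#'   (default `"R2"`).
#' @return A named [Biostrings::DNAStringSet] of sense-strand reads.
#' @export
senseReads <- function(pairs, senseMate = c("R2", "R1")) {
  senseMate <- match.arg(senseMate)
  stopifnot(is(pairs, "StrandedReadPairs"))
  if (!senseMate %in% pairs@mates)
    stop(sprintf("sense mate missing: library '%s' has no %s reads",
                 pairs@libraryId, senseMate))
  if (senseMate == "R2") pairs@r2 else pairs@r1
}

#' Remove exact-sequence duplicate reads
#'
#' Drops reads whose sequence string is an exact duplicate of an earlier
#' read, keeping the first occurrence and preserving order. The key is the
#' sequence alone (not the read id and not the mate pair), the minimal
#' reproducible reading of the study's statement that duplicates were
#' removed; substitute a UMI- or pair-aware dedup upstream if needed.
#'
#' @param reads a named [Biostrings::DNAStringSet] (or character vector).
#' @return A list with elements `reads` (the survivors, same class as
#'   input), `nInput`, and `nRemoved`.
#' @examples
#' d <- dedupReads(Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGT")))
#' d$nRemoved
#' @export
dedupReads <- function(reads) {
  keep <- !duplicated(as.character(reads))
  list(reads = reads[keep], nInput = length(reads),
       nRemoved = sum(!keep))
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

.LOCUS_TABLE_COLS <- c("consensus_id", "gene_class", "n_full", "n_relict",
                       "n_variant", "upstream_len", "total_len", "core_len",
                       "n_reads", "expression_rpm", "donor", "donor_ok")

#' Write the classified locus table as TSV
#'
#' Columns are fixed: `consensus_id`, `gene_class`, `n_full`, `n_relict`,
#' `n_variant`, `upstream_len`, `total_len`, `core_len`, `n_reads`,
#' `expression_rpm`, `donor`, `donor_ok`. An empty call set yields a
#' header-only file.
#'
#' @param calls a data.frame of locus calls, as produced by
#'   [classifyConsensusSet()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLocusTable <- function(calls, path) {
  calls <- as.data.frame(calls)
  for (col in setdiff(.LOCUS_TABLE_COLS, names(calls)))
    calls[[col]] <- rep(NA, nrow(calls))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(calls[, .LOCUS_TABLE_COLS, drop = FALSE], file = path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SL unit annotations as GFF3
#'
#' Emits one feature per SL unit, on the consensus sequence it was called
#' in. Coordinates follow the package-wide 1-based inclusive convention,
#' which is also the GFF3 convention, so no conversion is applied.
#'
#' @param matches named list of unit [IRanges::IRanges] (one element per
#'   consensus, as returned by [scanSequences()]), each carrying a `kind`
#'   metadata column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGff <- function(matches, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  keep <- vapply(matches, length, integer(1)) > 0L
  matches <- matches[keep]
  if (length(matches) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(matches), vapply(matches, length, integer(1))),
    ranges = unlist(IRanges::IRangesList(matches), use.names = FALSE),
    strand = "+")
  kind <- unlist(lapply(matches, function(m) as.character(S4Vectors::mcols(m)$kind)))
  S4Vectors::mcols(gr)$source <- "SLscout"
  S4Vectors::mcols(gr)$type <- c(FULL = "SL_unit", RELICT = "SL_relict",
                                 VARIANT = "SL_variant")[kind]
  S4Vectors::mcols(gr)$ID <- sprintf("%s.unit%d", as.character(GenomicRanges::seqnames(gr)),
                                     unlist(lapply(matches, seq_along)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
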