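#' Run the full SL gene discovery pipeline
#'
#' Fixed stage order: read FASTQ, deduplicate sense reads, scan for SL
#' units, assemble the SL-containing pool and the SL-like candidate pool
#' separately, classify consensi, extract introns with donor checks, and
#' compute U-rich motif enrichment over SL-gene introns. Every intermediate
#' is written to `outDir` along with a run manifest (config snapshot, input
#' checksums, per-stage counts). An empty library runs through with zero
#' counts rather than failing.
#'
#' @param pathR1,pathR2 FASTQ paths (either may be `NULL`; the sense mate
#'   must be present).
#' @param outDir output directory.
#' @param libraryId library label.
#' @param senseMate which mate carries the transcript sense strand
#'   (default `"R2"`, the TruSeq stranded convention).
#' @param motifs an [SLMotifSet-class].
#' @param params an [OverlapParams-class].
#' @param motifPanel RNA-alphabet motifs for enrichment (default
#'   [uRichMotifs()]).
#' @param writeOutputs write result files (default TRUE).
#' @return A list: `senseReads`, `selection` (from [selectSLReads()]),
#'   `slConsensi`, `slLikeConsensi` ([SLConsensusSet-class]), `calls`
#'   (locus table), `introns`, `enrichment`, `lengths` (or `NULL` when no
#'   SL locus was called), `manifest`, `paths`.
#' @export
runPipeline <- function(pathR1 = NULL, pathR2 = NULL, outDir = tempfile("slrun"),
                        libraryId = "library1", senseMate = c("R2", "R1"),
                        motifs = slMotifs(), params = overlapParams(),
                        motifPanel = uRichMotifs(), writeOutputs = TRUE) {
  senseMate <- match.arg(senseMate)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pairs <- readFastqPairs(pathR1, pathR2, libraryId = libraryId)
  sense <- senseReads(pairs, senseMate)
  dd <- dedupReads(sense)
  sel <- selectSLReads(dd$reads, motifs)
  slCons <- assembleReads(sel$slReads, params, prefix = "SL")
  likeCons <- assembleReads(sel$slLikeReads, params, prefix = "SLL")
  total <- length(dd$reads)
  callsSL <- classifyConsensusSet(slCons, motifs,
                                  libraryTotalReads = if (total > 0) total else NA)
  callsLike <- classifyConsensusSet(likeCons, motifs,
                                    libraryTotalReads = if (total > 0) total else NA)
  calls <- rbind(callsSL, callsLike)
  introns <- extractIntrons(calls)
  enrichment <- if (nrow(introns) > 0L)
    motifEnrichment(introns, motifPanel)
  else data.frame(motif = character(0), n = integer(0),
                  observed = integer(0), positions_scanned = integer(0),
                  expected = numeric(0), ratio = numeric(0))
  lengths <- if (any(calls$gene_class %in% c("SINGLE_SL", "TANDEM_SL")))
    lengthSummary(calls) else NULL
  manifest <- list(
    tool = "SLscout", version = as.character(utils::packageVersion("SLscout")),
    libraryId = libraryId, senseMate = senseMate,
    inputs = local({
      p <- c(R1 = pathR1, R2 = pathR2)
      if (length(p)) as.list(tools::md5sum(unlist(p))) else list()
    }),
    params = list(minOverlap = params@minOverlap,
                  minIdentity = params@minIdentity,
                  maxMismatches = motifs@maxMismatches),
    counts = list(
      raw = length(pairs), deduplicated = total,
      slContaining = length(sel$slReads),
      slLikeCandidates = length(sel$slLikeReads),
      slClusters = length(slCons), slLikeClusters = length(likeCons),
      classifiedLoci = nrow(calls)),
    unitHistogram = as.list(sel$histogram),
    timestamp = format(Sys.time(), tz = "UTC"))
  paths <- character(0)
  if (writeOutputs) {
    paths <- c(
      slConsensi = file.path(outDir, "sl_consensi.fasta"),
      slLikeConsensi = file.path(outDir, "sl_like_consensi.fasta"),
      locusTable = file.path(outDir, "locus_table.tsv"),
      unitGff = file.path(outDir, "sl_units.gff3"),
      histogram = file.path(outDir, "unit_histogram.tsv"),
      enrichment = file.path(outDir, "motif_enrichment.tsv"),
      summary = file.path(outDir, "summary.json"),
      manifest = file.path(outDir, "manifest.json"))
    writeFasta(consensusSequences(slCons), paths[["slConsensi"]])
    writeFasta(consensusSequences(likeCons), paths[["slLikeConsensi"]])
    writeLocusTable(calls, paths[["locusTable"]])
    allCons <- c(as.character(consensusSequences(slCons)),
                 as.character(consensusSequences(likeCons)))
    writeGff(scanSequences(allCons, motifs), paths[["unitGff"]])
    utils::write.table(
      data.frame(n_full_units = names(sel$histogram),
                 n_reads = as.integer(sel$histogram)),
      paths[["histogram"]], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enrichment, paths[["enrichment"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary <- list(
      counts = manifest$counts, unitHistogram = manifest$unitHistogram,
      lengths = lengths,
      rpmByClass = if (nrow(calls) && total > 0)
        as.list(tapply(calls$expression_rpm, calls$gene_class, mean))
      else list())
    jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(senseReads = dd$reads, selection = sel, slConsensi = slCons,
       slLikeConsensi = likeCons, calls = calls, introns = introns,
       enrichment = enrichment, lengths = lengths, manifest = manifest,
       paths = paths)
}

#' Locate consensus sequences in a genome assembly
#'
#' Searches each consensus against every contig on both strands, allowing
#' up to `maxMismatches` substitutions, and reports the best hit
#' (fewest mismatches; ties broken by contig id, then position, with the
#' forward strand preferred). Matching uses exact/near-exact substring
#' search; loci absent from the assembly return no row.
#'
#' @param consensi named [Biostrings::DNAStringSet] (or character).
#' @param genome named [Biostrings::DNAStringSet] of contigs, or a FASTA
#'   path.
#' @param maxMismatches maximum substitutions (default 0).
#' @return data.frame with columns `consensus_id`, `contig`, `start`
#'   (1-based), `strand`, `mismatches`; one row per consensus with a hit.
#' @export
verifyInGenome <- function(consensi, genome, maxMismatches = 0L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(consensi)) consensi <- Biostrings::DNAStringSet(consensi)
  rows <- lapply(names(consensi), function(cid) {
    pat <- consensi[[cid]]
    best <- NULL
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      for (ctg in names(genome)) {
        hits <- Biostrings::matchPattern(p, genome[[ctg]],
                                         max.mismatch = maxMismatches,
                                         fixed = TRUE)
        if (length(hits) == 0L) next
        mm <- vapply(seq_along(hits), function(i)
          Biostrings::neditAt(p, genome[[ctg]], at = IRanges::start(hits)[i]),
          integer(1))
        for (i in order(mm, IRanges::start(hits))) {
          cand <- list(contig = ctg, start = IRanges::start(hits)[i],
                       strand = strand, mismatches = mm[i])
          if (is.null(best) || cand$mismatches < best$mismatches ||
              (cand$mismatches == best$mismatches &&
               (cand$contig < best$contig ||
                (cand$contig == best$contig && cand$start < best$start))))
            best <- cand
          break
        }
      }
    }
    if (is.null(best)) return(NULL)
    data.frame(consensus_id = cid, contig = best$contig,
               start = best$start, strand = best$strand,
               mismatches = best$mismatches, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(consensus_id = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  out
}
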