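.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.runif_int <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq.int(range[1], range[2]), 1L)
}

# all k-mers of a string (character(0) if too short)
.kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1L), k:L)
}

# Separability screen between two loci: TRUE when no 30-column window at
# any ungapped relative offset has fewer than 3 mismatches, which rules
# out any >=30 bp / >=95% identity overlap window between reads (or
# consensi) drawn from the two loci.
.lociSeparable <- function(a, b)
  !cpp_has_nearmatch_window(a, b, 30L, 2L)

#' Build one planted SL locus
#'
#' Constructs a ground-truth locus of the requested class:
#' \itemize{
#'   \item `SINGLE_SL`: upstream + SL + intron;
#'   \item `TANDEM_SL`: upstream + `nUnits` SL copies separated by short
#'     random spacers + intron;
#'   \item `SL_LIKE`: upstream + VARIANT + (`nUnits`-1) RELICT copies
#'     (spacer-separated) + downstream whose first dinucleotide is neither
#'     GT nor GC (no splice donor) and with no Sm-motif planted.
#' }
#' SL loci receive a GT or GC intron donor and one GUUUUC (DNA: GTTTTC)
#' Sm-candidate motif at a random intron position. All non-unit segments
#' are random uniform sequence, rejection-sampled so that (i) a scan of the
#' finished locus finds exactly the declared units and (ii) against every
#' previously generated locus (recorded in `seqPool`), no 30-column window
#' at any ungapped offset comes within 2 mismatches of identity — the
#' condition that provably prevents the >=30 bp / >=95% overlap rule from
#' joining reads of different loci, even around the unit blocks the loci
#' share by construction.
#'
#' Uses the session RNG; seed control belongs to the caller (see
#' [simulateSLLibrary()]).
#'
#' @param class one of `SINGLE_SL`, `TANDEM_SL`, `SL_LIKE`.
#' @param config a [SimConfig-class].
#' @param motifs an [SLMotifSet-class].
#' @param nUnits number of units (FULL for tandem; variant+relicts for
#'   SL-like).
#' @param locusId id recorded in the truth table.
#' @param seqPool an environment accumulating previously generated locus
#'   sequences, used to enforce cross-locus separability; create with
#'   `new.env()` and share across calls.
#' @param maxTries rejection-sampling attempts before a hard error.
#' @return A one-row data.frame of truth fields, including the full
#'   `sequence`.
#' @export
makeLocus <- function(class = c("SINGLE_SL", "TANDEM_SL", "SL_LIKE"),
                      config = simConfig(), motifs = slMotifs(),
                      nUnits = if (class == "SINGLE_SL") 1L else 2L,
                      locusId = "locus1", seqPool = new.env(),
                      maxTries = 50L) {
  class <- match.arg(class)
  if (class == "SINGLE_SL" && nUnits != 1L)
    stop("SINGLE_SL loci have exactly one unit")
  if (class != "SINGLE_SL" && nUnits < 2L)
    stop("TANDEM_SL and SL_LIKE loci need >= 2 units")
  if (!exists("seqs", envir = seqPool))
    assign("seqs", character(0), envir = seqPool)
  for (try in seq_len(maxTries)) {
    if (class == "SL_LIKE") {
      up <- .runif_int(config@slLikeUpstreamRange)
      intron <- .runif_int(config@slLikeIntronRange)
      units <- c(motifs@variant, rep(motifs@relict, nUnits - 1L))
      nf <- 0L; nr <- nUnits - 1L; nv <- 1L
    } else {
      up <- .runif_int(config@upstreamRange)
      intron <- .runif_int(config@intronRange)
      units <- rep(motifs@sl, nUnits)
      nf <- nUnits; nr <- 0L; nv <- 0L
    }
    spacers <- if (nUnits > 1L)
      vapply(seq_len(nUnits - 1L),
             function(i) .randSeq(.runif_int(config@spacerRange)),
             character(1))
    else character(0)
    upstream <- .randSeq(up)
    if (class == "SL_LIKE") {
      # downstream must not begin with a splice donor (GT/GC)
      first2 <- paste(sample(.BASES, 2L, replace = TRUE), collapse = "")
      while (first2 %in% c("GT", "GC"))
        first2 <- paste(sample(.BASES, 2L, replace = TRUE), collapse = "")
      down <- paste0(first2, .randSeq(intron - 2L))
      donorPlanted <- FALSE; smPlanted <- FALSE
    } else {
      donor <- sample(c("GT", "GC"), 1L)
      sm <- "GTTTTC"
      # place the Sm motif away from the donor, fully inside the intron
      smAt <- .runif_int(c(4L, intron - nchar(sm) - 1L))
      down <- paste0(donor, .randSeq(smAt - 3L), sm,
                     .randSeq(intron - (smAt + nchar(sm) - 1L)))
      stopifnot(nchar(down) == intron)
      donorPlanted <- TRUE; smPlanted <- TRUE
    }
    unitBlock <- paste(as.vector(rbind(units, c(spacers, ""))),
                       collapse = "")
    seqStr <- paste0(upstream, unitBlock, down)
    # declared structure must be exactly what a scan recovers
    cnt <- .unitCounts(scanSequence(seqStr, motifs))
    if (cnt[["FULL"]] != nf || cnt[["RELICT"]] != nr ||
        cnt[["VARIANT"]] != nv) next
    # cross-locus separability under the overlap-clustering thresholds
    pool <- get("seqs", envir = seqPool)
    if (!all(vapply(pool, .lociSeparable, logical(1), b = seqStr))) next
    assign("seqs", c(pool, seqStr), envir = seqPool)
    total <- nchar(seqStr)
    return(data.frame(
      locus_id = locusId, gene_class = class, n_full = nf, n_relict = nr,
      n_variant = nv, upstream_len = up, total_len = total,
      core_len = total - up, intron_len = intron,
      donor_planted = donorPlanted, sm_motif_planted = smPlanted,
      sequence = seqStr, stringsAsFactors = FALSE))
  }
  stop(sprintf("could not generate a unique %s locus in %d tries",
               class, maxTries))
}

#' Plant the full locus census of a configuration
#'
#' @param config a [SimConfig-class].
#' @param motifs an [SLMotifSet-class].
#' @return data.frame of planted loci (one row per locus). SL-like loci
#'   alternate between 2 and 3 units. Uses the session RNG.
#' @export
simulateLoci <- function(config = simConfig(), motifs = slMotifs()) {
  pool <- new.env()
  specs <- rbind(
    if (config@nSingle > 0L)
      data.frame(class = "SINGLE_SL", k = rep(1L, config@nSingle)),
    if (config@nTandem2 > 0L)
      data.frame(class = "TANDEM_SL", k = rep(2L, config@nTandem2)),
    if (config@nTandem3 > 0L)
      data.frame(class = "TANDEM_SL", k = rep(3L, config@nTandem3)),
    if (config@nSLLike > 0L)
      data.frame(class = "SL_LIKE",
                 k = rep_len(c(2L, 3L), config@nSLLike)))
  if (is.null(specs) || nrow(specs) == 0L)
    return(data.frame())
  loci <- lapply(seq_len(nrow(specs)), function(i)
    makeLocus(specs$class[i], config, motifs, nUnits = specs$k[i],
              locusId = sprintf("L%02d_%s", i, tolower(specs$class[i])),
              seqPool = pool))
  do.call(rbind, loci)
}

.addErrors <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
    s <- paste(ch, collapse = "")
  }
  s
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Simulate stranded read pairs from planted loci
#'
#' Emulates a TruSeq-stranded library: for each fragment, R2 is the first
#' `readLen` bases of the fragment on the transcript sense strand and R1 is
#' the reverse complement of the fragment's 3' end. Fragment lengths follow
#' `Normal(insertMean, insertSd)` (floored at `readLen`, clipped at the
#' locus end). Fragment 5' positions are sampled without replacement from
#' the admissible starts `1..L-readLen+1` — at desk-scale depth this
#' emulates the phase saturation of a real multi-million-read library —
#' with surplus depth drawn with replacement, which plants exact duplicate
#' pairs for the dedup stage to remove. Substitution errors are applied
#' i.i.d. per base; background decoys are uniform-random fragments.
#'
#' Uses the session RNG; [simulateSLLibrary()] seeds it from the config.
#'
#' @param loci data.frame from [simulateLoci()].
#' @param config a [SimConfig-class].
#' @return list with `r1`, `r2` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame `read_id`, `locus_id`, `start`).
#' @export
simulateReads <- function(loci, config = simConfig()) {
  rl <- config@readLen
  ids <- character(0); r1 <- character(0); r2 <- character(0)
  src <- character(0); st <- integer(0)
  for (i in seq_len(nrow(loci))) {
    locus <- loci$sequence[i]
    L <- nchar(locus)
    W <- max(1L, L - rl + 1L)
    n <- config@depth
    starts <- if (n <= W) sample.int(W, n) else
      c(seq_len(W), sample.int(W, n - W, replace = TRUE))
    for (j in seq_along(starts)) {
      s <- starts[j]
      ins <- max(rl, round(stats::rnorm(1, config@insertMean,
                                        config@insertSd)))
      e <- min(s + ins - 1L, L)
      sense2 <- substr(locus, s, min(s + rl - 1L, e))
      sense1 <- substr(locus, max(s, e - rl + 1L), e)
      ids <- c(ids, sprintf("%s_f%03d", loci$locus_id[i], j))
      r2 <- c(r2, .addErrors(sense2, config@errorRate))
      r1 <- c(r1, .addErrors(.revcomp(sense1), config@errorRate))
      src <- c(src, loci$locus_id[i]); st <- c(st, s)
    }
  }
  for (j in seq_len(config@backgroundReads)) {
    frag <- .randSeq(max(rl, round(stats::rnorm(1, config@insertMean,
                                                config@insertSd))))
    ids <- c(ids, sprintf("bg_%05d", j))
    r2 <- c(r2, .addErrors(substr(frag, 1L, rl), config@errorRate))
    r1 <- c(r1, .addErrors(.revcomp(substr(frag, nchar(frag) - rl + 1L,
                                           nchar(frag))),
                           config@errorRate))
    src <- c(src, "background"); st <- c(st, 1L)
  }
  r1 <- Biostrings::DNAStringSet(stats::setNames(r1, ids))
  r2 <- Biostrings::DNAStringSet(stats::setNames(r2, ids))
  list(r1 = r1, r2 = r2,
       truth = data.frame(read_id = ids, locus_id = src, start = st,
                          stringsAsFactors = FALSE))
}

#' Simulate a complete ground-truthed library to disk
#'
#' Seeds the RNG from the configuration, plants the locus census, draws
#' reads, and writes `reads_R1.fastq`, `reads_R2.fastq` (constant 'I'
#' qualities), `truth_reads.tsv`, `truth_loci.tsv`, and `truth_loci.fasta`
#' into `dir`. Identical configurations produce byte-identical files.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @param motifs an [SLMotifSet-class].
#' @return list with `loci`, `reads` (as from [simulateReads()]), and
#'   `paths` (named character vector of output files).
#' @export
simulateSLLibrary <- function(config = simConfig(), dir = tempfile("simlib"),
                              motifs = slMotifs()) {
  set.seed(config@seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- simulateLoci(config, motifs)
  reads <- simulateReads(loci, config)
  paths <- c(r1 = file.path(dir, "reads_R1.fastq"),
             r2 = file.path(dir, "reads_R2.fastq"),
             truthReads = file.path(dir, "truth_reads.tsv"),
             truthLoci = file.path(dir, "truth_loci.tsv"),
             lociFasta = file.path(dir, "truth_loci.fasta"))
  qual1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads$r1)))
  qual2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads$r2)))
  Biostrings::writeXStringSet(reads$r1, paths[["r1"]], format = "fastq",
                              qualities = qual1)
  Biostrings::writeXStringSet(reads$r2, paths[["r2"]], format = "fastq",
                              qualities = qual2)
  utils::write.table(reads$truth, paths[["truthReads"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(loci, paths[["truthLoci"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(loci))
    writeFasta(stats::setNames(loci$sequence, loci$locus_id),
               paths[["lociFasta"]])
  list(loci = loci, reads = reads, paths = paths)
}

#' End-to-end truth-vs-pipeline recovery report
#'
#' Simulates a library from `config`, runs the full pipeline on it, maps
#' every recovered consensus back to its planted locus (largest shared
#' 31-mer count), and reports the class confusion matrix, per-locus length
#' error, rpm comparison, and any unrecovered or surplus loci. Robust to
#' partial recovery: missing loci are flagged, not fatal.
#'
#' @param config a [SimConfig-class].
#' @param dir working directory for the simulated library and pipeline
#'   output.
#' @param ... passed to [runPipeline()].
#' @return list with `truth`, `calls`, `mapping` (data.frame planted vs
#'   recovered), `confusion` (table), `lengthError` (mean recovered minus
#'   planted total length over mapped SL loci), `coreLengthError`,
#'   `unrecovered` (planted locus ids), `pipeline` (the full pipeline
#'   result).
#' @export
endToEndRecovery <- function(config = simConfig(), dir = tempfile("e2e"),
                             ...) {
  sim <- simulateSLLibrary(config, dir = file.path(dir, "sim"))
  pipe <- runPipeline(pathR1 = sim$paths[["r1"]],
                      pathR2 = sim$paths[["r2"]],
                      outDir = file.path(dir, "out"), ...)
  calls <- pipe$calls
  truth <- sim$loci
  consensi <- c(
    as.character(consensusSequences(pipe$slConsensi)),
    as.character(consensusSequences(pipe$slLikeConsensi)))
  mapping <- data.frame(consensus_id = character(0),
                        locus_id = character(0), stringsAsFactors = FALSE)
  if (nrow(calls) && nrow(truth)) {
    truthKmers <- lapply(truth$sequence, .kmers, k = 31L)
    mapTo <- vapply(calls$consensus_id, function(cid) {
      km <- .kmers(consensi[[cid]], 31L)
      shared <- vapply(truthKmers, function(tk) sum(km %in% tk), numeric(1))
      if (max(shared) == 0) NA_character_ else truth$locus_id[which.max(shared)]
    }, character(1))
    mapping <- data.frame(consensus_id = calls$consensus_id,
                          locus_id = unname(mapTo),
                          stringsAsFactors = FALSE)
  }
  merged <- merge(mapping, calls, by = "consensus_id")
  merged <- merge(merged, truth, by = "locus_id",
                  suffixes = c("_recovered", "_planted"))
  confusion <- table(planted = merged$gene_class_planted,
                     recovered = merged$gene_class_recovered)
  slRows <- merged$gene_class_planted %in% c("SINGLE_SL", "TANDEM_SL")
  lengthError <- if (any(slRows))
    mean(merged$total_len_recovered[slRows] -
           merged$total_len_planted[slRows]) else NA_real_
  coreError <- if (any(slRows))
    mean(merged$core_len_recovered[slRows] -
           merged$core_len_planted[slRows]) else NA_real_
  list(truth = truth, calls = calls, mapping = mapping, merged = merged,
       confusion = confusion, lengthError = lengthError,
       coreLengthError = coreError,
       unrecovered = setdiff(truth$locus_id, mapping$locus_id),
       pipeline = pipe)
}
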