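#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet
#'   readDNAStringSet matchPattern countPattern mergeIUPACLetters DNAString
#' @importClassesFrom Biostrings DNAStringSet BStringSet
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom Rcpp evalCpp
#' @useDynLib SLscout, .registration = TRUE
NULL

.DINO_SL <- "CCGTAGCCATTTTGGCTCAAG"
.DINO_SL_RELICT <- "AGCCATTTTGGCTCAAG"

.isDNA <- function(x) all(grepl("^[ACGTN]+$", x))

#' Motif set for spliced-leader unit detection
#'
#' Holds the canonical 21-nt dinoflagellate spliced leader (SL), its 17-nt
#' relict (the SL minus its 5' CCGT), and the TCG-variant first unit observed
#' in SL-like genes, in which the TCCG opening the canonical (U/T)CCGUAG...
#' leader is contracted to TCG. The variant is therefore the canonical SL
#' with its first base C replaced by T.
#'
#' @slot sl canonical SL motif (DNA alphabet, uppercase).
#' @slot relict SL relict motif; must be a suffix of `sl`.
#' @slot variant TCG-variant motif recognised as the first unit of SL-like
#'   loci.
#' @slot maxMismatches maximum substitutions tolerated for a FULL (canonical)
#'   match; relict and variant matches are always exact.
#' @name SLMotifSet-class
#' @aliases SLMotifSet-class
#' @exportClass SLMotifSet
setClass("SLMotifSet",
  representation(sl = "character", relict = "character",
                 variant = "character", maxMismatches = "integer"))

setValidity("SLMotifSet", function(object) {
  msg <- character()
  for (s in c("sl", "relict", "variant")) {
    v <- slot(object, s)
    if (length(v) != 1L || !nzchar(v) || !.isDNA(v))
      msg <- c(msg, sprintf("'%s' must be one uppercase ACGTN string", s))
  }
  if (length(msg) == 0L) {
    if (!endsWith(object@sl, object@relict))
      msg <- c(msg, "'relict' must be a suffix of 'sl'")
  }
  if (length(object@maxMismatches) != 1L || is.na(object@maxMismatches) ||
      object@maxMismatches < 0L)
    msg <- c(msg, "'maxMismatches' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct the default dinoflagellate SL motif set
#'
#' @param sl canonical SL motif (default the 21-nt dinoflagellate SL,
#'   `CCGTAGCCATTTTGGCTCAAG`).
#' @param relict relict motif, a suffix of `sl` (default
#'   `AGCCATTTTGGCTCAAG`).
#' @param variant variant first-unit motif; by default derived from `sl` by
#'   the TCCG-to-TCG rule, i.e. `TCG` + `substr(sl, 4, nchar(sl))`.
#' @param maxMismatches substitutions tolerated for FULL matches (default 0,
#'   exact search).
#' @return An [SLMotifSet-class] object.
#' @examples
#' slMotifs()
#' @export
slMotifs <- function(sl = .DINO_SL, relict = .DINO_SL_RELICT,
                     variant = NULL, maxMismatches = 0L) {
  if (is.null(variant))
    variant <- paste0("TCG", substr(sl, 4L, nchar(sl)))
  new("SLMotifSet", sl = toupper(sl), relict = toupper(relict),
      variant = toupper(variant), maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "SLMotifSet", function(object) {
  cat("SLMotifSet\n",
      "  FULL    (", nchar(object@sl), " nt): ", object@sl, "\n",
      "  VARIANT (", nchar(object@variant), " nt): ", object@variant, "\n",
      "  RELICT  (", nchar(object@relict), " nt): ", object@relict, "\n",
      "  maxMismatches (FULL only): ", object@maxMismatches, "\n", sep = "")
})

#' Overlap acceptance thresholds for read clustering
#'
#' @slot minOverlap minimum aligned columns for an acceptable ungapped
#'   overlap (bp).
#' @slot minIdentity minimum fraction of matching columns.
#' @name OverlapParams-class
#' @exportClass OverlapParams
setClass("OverlapParams",
  representation(minOverlap = "integer", minIdentity = "numeric"))

setValidity("OverlapParams", function(object) {
  msg <- character()
  if (length(object@minOverlap) != 1L || is.na(object@minOverlap) ||
      object@minOverlap < 1L)
    msg <- c(msg, "'minOverlap' must be a single integer >= 1")
  if (length(object@minIdentity) != 1L || is.na(object@minIdentity) ||
      object@minIdentity <= 0 || object@minIdentity > 1)
    msg <- c(msg, "'minIdentity' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct overlap-clustering parameters
#'
#' Defaults follow the published thresholds (overlap > 30 bp, identity > 95%),
#' implemented as `>= 30` and `>= 0.95`; both are configurable because the
#' boundary semantics of the original assembler are not documented.
#'
#' @param minOverlap minimum overlap length in bp (default 30).
#' @param minIdentity minimum identity fraction (default 0.95).
#' @return An [OverlapParams-class] object.
#' @examples
#' overlapParams()
#' @export
overlapParams <- function(minOverlap = 30L, minIdentity = 0.95) {
  new("OverlapParams", minOverlap = as.integer(minOverlap),
      minIdentity = as.numeric(minIdentity))
}

setMethod("show", "OverlapParams", function(object) {
  cat("OverlapParams: minOverlap=", object@minOverlap,
      " bp, minIdentity=", object@minIdentity, "\n", sep = "")
})

#' Paired (or single-end) stranded reads
#'
#' Container for one library's reads with the mate labels kept explicit, so
#' that the stranded-library orientation contract (which mate carries the
#' transcript sense strand) can be enforced downstream. Either mate may be
#' absent (length-0 with the mate dropped from `mates`), supporting R2-only
#' analysis.
#'
#' @slot r1,r2 [Biostrings::DNAStringSet] of forward/reverse reads, named by
#'   read id (mate suffixes stripped).
#' @slot mates character vector of mates actually present.
#' @slot libraryId library of origin.
#' @name StrandedReadPairs-class
#' @exportClass StrandedReadPairs
setClass("StrandedReadPairs",
  representation(r1 = "DNAStringSet", r2 = "DNAStringSet",
                 mates = "character", libraryId = "character"))

setValidity("StrandedReadPairs", function(object) {
  msg <- character()
  if (!all(object@mates %in% c("R1", "R2")) || length(object@mates) < 1L)
    msg <- c(msg, "'mates' must be a non-empty subset of {R1, R2}")
  if (("R1" %in% object@mates) != (length(object@r1) > 0L) &&
      length(object@r2) > 0L)  # allow both-empty edge (empty library)
    msg <- c(msg, "'mates' inconsistent with slot lengths")
  if (all(c("R1", "R2") %in% object@mates) &&
      length(object@r1) != length(object@r2))
    msg <- c(msg, "paired mode requires equal R1/R2 lengths")
  if (length(object@libraryId) != 1L)
    msg <- c(msg, "'libraryId' must be a single string")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StrandedReadPairs", function(object) {
  n <- max(length(object@r1), length(object@r2))
  cat("StrandedReadPairs: ", n, " record(s), mates {",
      paste(object@mates, collapse = ","), "}, library '",
      object@libraryId, "'\n", sep = "")
})

#' @describeIn StrandedReadPairs-class number of read records
#' @param x a `StrandedReadPairs` object
#' @export
setMethod("length", "StrandedReadPairs", function(x)
  max(length(x@r1), length(x@r2)))

#' Assembled cluster consensus sequences
#'
#' One entry per read cluster: the majority-vote consensus (IUPAC ambiguity
#' codes at ties), per-column depth (number of non-N member bases covering
#' each column), and the member read ids with their layout offsets.
#'
#' @slot sequences [Biostrings::DNAStringSet] of consensus sequences, named
#'   by consensus id.
#' @slot depth list of integer vectors, one per consensus, each as long as
#'   its sequence.
#' @slot members list of data.frames with columns `id` and `offset` (1-based
#'   start of the member read on the consensus).
#' @name SLConsensusSet-class
#' @exportClass SLConsensusSet
setClass("SLConsensusSet",
  representation(sequences = "DNAStringSet", depth = "list",
                 members = "list"))

setValidity("SLConsensusSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@depth) != n || length(object@members) != n)
    msg <- c(msg, "'depth' and 'members' must parallel 'sequences'")
  else if (n > 0L) {
    w <- Biostrings::width(object@sequences)
    dl <- vapply(object@depth, length, integer(1))
    if (!all(dl == w))
      msg <- c(msg, "each depth vector must match its consensus length")
    if (any(vapply(object@depth, function(d) any(d < 0L), logical(1))))
      msg <- c(msg, "depth must be non-negative")
    if (any(vapply(object@members, nrow, integer(1)) < 1L))
      msg <- c(msg, "every cluster must have at least one member")
    if (any(vapply(object@members, function(m) min(m$offset), integer(1)) != 1L))
      msg <- c(msg, "each cluster layout must start at offset 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SLConsensusSet", function(object) {
  n <- length(object@sequences)
  cat("SLConsensusSet with ", n, " consensus sequence(s)\n", sep = "")
  if (n > 0L) {
    nm <- vapply(object@members, nrow, integer(1))
    cat("  lengths: ", paste(range(Biostrings::width(object@sequences)),
                             collapse = "-"), " bp; members per cluster: ",
        paste(range(nm), collapse = "-"), "\n", sep = "")
  }
})

#' @describeIn SLConsensusSet-class number of consensus sequences
#' @param x an `SLConsensusSet`
#' @export
setMethod("length", "SLConsensusSet", function(x) length(x@sequences))

#' @describeIn SLConsensusSet-class consensus ids
#' @export
setMethod("names", "SLConsensusSet", function(x) names(x@sequences))

#' Accessors for SLConsensusSet
#'
#' @param x an [SLConsensusSet-class] object.
#' @return `consensusSequences` returns a [Biostrings::DNAStringSet];
#'   `consensusDepth` a named list of integer vectors; `clusterMembers` a
#'   named list of data.frames with columns `id` and `offset`.
#' @name consensusSequences
#' @export
consensusSequences <- function(x) x@sequences

#' @rdname consensusSequences
#' @export
consensusDepth <- function(x) stats::setNames(x@depth, names(x@sequences))

#' @rdname consensusSequences
#' @export
clusterMembers <- function(x) stats::setNames(x@members, names(x@sequences))

#' Simulation configuration for planted SL libraries
#'
#' Defines the study conditions the simulator emulates: a TruSeq-stranded
#' library (R2 = transcript sense strand) of 100-nt paired reads with ~200 bp
#' inserts, over a census of planted single-SL, tandem-SL, and SL-like loci
#' plus random background (non-SL) read pairs.
#'
#' @slot nSingle,nTandem2,nTandem3,nSLLike planted locus counts per class.
#' @slot readLen read length in bp.
#' @slot insertMean,insertSd fragment insert size distribution (bp).
#' @slot depth read pairs drawn per locus.
#' @slot errorRate per-base substitution probability.
#' @slot backgroundReads number of random decoy read pairs.
#' @slot upstreamRange,intronRange bp ranges for SL-locus upstream extension
#'   and intron length.
#' @slot slLikeUpstreamRange,slLikeIntronRange bp ranges for SL-like loci.
#' @slot spacerRange bp range for random spacers between tandem units
#'   (`c(0L, 0L)` plants strictly adjacent units).
#' @slot seed integer seed governing all randomness.
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nSingle = "integer", nTandem2 = "integer",
                 nTandem3 = "integer", nSLLike = "integer",
                 readLen = "integer", insertMean = "numeric",
                 insertSd = "numeric", depth = "integer",
                 errorRate = "numeric", backgroundReads = "integer",
                 upstreamRange = "integer", intronRange = "integer",
                 slLikeUpstreamRange = "integer",
                 slLikeIntronRange = "integer", spacerRange = "integer",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nSingle, object@nTandem2, object@nTandem3, object@nSLLike,
           object@backgroundReads)
  if (any(is.na(cnt)) || any(cnt < 0L))
    msg <- c(msg, "locus and background counts must be >= 0")
  if (object@depth < 1L) msg <- c(msg, "'depth' must be >= 1")
  if (object@readLen < 50L) msg <- c(msg, "'readLen' must be >= 50")
  if (is.na(object@errorRate) || object@errorRate < 0 ||
      object@errorRate >= 0.5)
    msg <- c(msg, "'errorRate' must be in [0, 0.5)")
  for (s in c("upstreamRange", "intronRange", "slLikeUpstreamRange",
              "slLikeIntronRange", "spacerRange")) {
    v <- slot(object, s)
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2] || v[1] < 0L)
      msg <- c(msg, sprintf("'%s' must be an ordered non-negative pair", s))
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults reproduce the study census (16 single-SL, 1 two-unit tandem,
#' 1 three-unit tandem, 13 SL-like loci) with 100-nt reads and ~200 bp
#' inserts. Locus geometry defaults keep every planted locus within reach of
#' SL-anchored 100-nt reads (upstream extension 20-30 bp; SL intron
#' 62-75 bp; SL-like upstream 27-40 bp and downstream 34-50 bp), inside the
#' reported 103-292 bp locus length envelope.
#'
#' @param nSingle,nTandem2,nTandem3,nSLLike planted locus counts
#'   (defaults 16, 1, 1, 13).
#' @param readLen read length in bp (default 100).
#' @param insertMean mean insert size in bp (default 200).
#' @param insertSd insert size standard deviation (default 10% of the mean).
#' @param depth read pairs per locus (default 20).
#' @param errorRate per-base substitution probability (default 0.001,
#'   a typical Illumina error rate; set 0 for error-free truth checks).
#' @param backgroundReads random non-SL decoy read pairs (default 500).
#' @param upstreamRange,intronRange,slLikeUpstreamRange,slLikeIntronRange,spacerRange
#'   integer length-2 bp ranges, see [SimConfig-class].
#' @param seed integer seed (default 42).
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(nSingle = 16L, nTandem2 = 1L, nTandem3 = 1L,
                      nSLLike = 13L, readLen = 100L, insertMean = 200,
                      insertSd = insertMean * 0.1, depth = 20L,
                      errorRate = 0.001, backgroundReads = 500L,
                      upstreamRange = c(20L, 30L),
                      intronRange = c(62L, 75L),
                      slLikeUpstreamRange = c(27L, 40L),
                      slLikeIntronRange = c(34L, 50L),
                      spacerRange = c(4L, 8L), seed = 42L) {
  new("SimConfig", nSingle = as.integer(nSingle),
      nTandem2 = as.integer(nTandem2), nTandem3 = as.integer(nTandem3),
      nSLLike = as.integer(nSLLike), readLen = as.integer(readLen),
      insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
      depth = as.integer(depth), errorRate = as.numeric(errorRate),
      backgroundReads = as.integer(backgroundReads),
      upstreamRange = as.integer(upstreamRange),
      intronRange = as.integer(intronRange),
      slLikeUpstreamRange = as.integer(slLikeUpstreamRange),
      slLikeIntronRange = as.integer(slLikeIntronRange),
      spacerRange = as.integer(spacerRange), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nSingle, " single + ", object@nTandem2,
      " tandem2 + ", object@nTandem3, " tandem3 + ", object@nSLLike,
      " SL-like loci\n  readLen=", object@readLen, ", insert=",
      object@insertMean, "+/-", object@insertSd, ", depth=", object@depth,
      ", errorRate=", object@errorRate, ", background=",
      object@backgroundReads, ", seed=", object@seed, "\n", sep = "")
})
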