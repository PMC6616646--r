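# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed the RNG themselves.

randSeq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# Toy motif set over the {A,C} alphabet for exhaustive oracle checks:
# small enough that every string of length <= 12 can be enumerated.
toyMotifs <- function()
  slMotifs(sl = "ACAC", relict = "CAC", variant = "CCAA")

# Write a DNAStringSet (or named character) as FASTQ with constant quality.
writeTestFastq <- function(x, path, suffix = NULL) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!is.null(suffix)) names(x) <- paste0(names(x), suffix)
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  path
}

# Brute-force reimplementation of the ungapped best-overlap search, kept
# deliberately independent of the C++ kernel: explicit per-offset character
# comparison with the same (length, identity, smallest offset) preference.
oracleBestOverlap <- function(a, b, minOverlap, minIdentity) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  best <- NULL
  for (off in (-(lb - 1L)):(la - 1L)) {
    lo <- max(0L, off); hi <- min(la, off + lb)
    len <- hi - lo
    if (len < minOverlap) next
    ai <- (lo + 1L):hi; bi <- ai - off
    m <- sum(av[ai] == bv[bi] & av[ai] != "N")
    if (m + 1e-9 < minIdentity * len) next
    if (is.null(best) || len > best$overlapLen ||
        (len == best$overlapLen && m * best$overlapLen >
           best$matches * len))
      best <- list(offset = off, overlapLen = len,
                   identity = m / len, matches = m)
  }
  if (is.null(best)) NULL else best[c("offset", "overlapLen", "identity")]
}

# Independent unit-calling oracle: enumerate every exact motif placement,
# then select the leftmost-greedy non-overlapping calling with per-position
# priority FULL > VARIANT > RELICT.
oracleScan <- function(s, motifs) {
  pats <- c(FULL = motifs@sl, VARIANT = motifs@variant,
            RELICT = motifs@relict)
  prio <- c(FULL = 1L, VARIANT = 2L, RELICT = 3L)
  L <- nchar(s)
  cand <- do.call(rbind, lapply(names(pats), function(k) {
    n <- nchar(pats[[k]])
    if (n > L) return(NULL)
    pos <- which(vapply(seq_len(L - n + 1L), function(i)
      substr(s, i, i + n - 1L) == pats[[k]], logical(1)))
    if (!length(pos)) NULL else
      data.frame(pos = pos, kind = k, len = n, stringsAsFactors = FALSE)
  }))
  sel <- data.frame(pos = integer(0), kind = character(0), len = integer(0))
  nextFree <- 1L
  while (!is.null(cand)) {
    ok <- cand[cand$pos >= nextFree, , drop = FALSE]
    if (nrow(ok) == 0L) break
    ok <- ok[order(ok$pos, prio[ok$kind]), , drop = FALSE]
    sel <- rbind(sel, ok[1L, ])
    nextFree <- ok$pos[1L] + ok$len[1L]
  }
  sel
}

# scanSequence result as a plain comparable data.frame
scanAsDf <- function(m)
  data.frame(pos = IRanges::start(m),
             kind = as.character(S4Vectors::mcols(m)$kind),
             len = IRanges::width(m), stringsAsFactors = FALSE)

# Small end-to-end configuration used by several tests.
smallConfig <- function(seed = 11L)
  simConfig(nSingle = 3L, nTandem2 = 1L, nTandem3 = 1L, nSLLike = 2L,
            depth = 12L, errorRate = 0, backgroundReads = 50L, seed = seed)
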