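#' Best ungapped overlap between two sequences
#'
#' Considers every relative placement of `b` against `a`, including full
#' containment. For each placement the aligned columns are scored
#' (matches / columns; `N` matches nothing) and the best qualifying
#' placement is returned, maximising overlap length, then identity, then
#' the smallest offset. Ungapped alignment keeps the kernel exactly
#' testable against a brute-force enumeration oracle; reads from one locus
#' differ only by substitution errors at this scale, so gaps are not
#' modelled.
#'
#' @param a,b DNA sequences (character).
#' @param params an [OverlapParams-class] (default [overlapParams()]).
#' @return `NULL` if no placement reaches `minOverlap`/`minIdentity`,
#'   otherwise a list with `offset` (0-based start of `b` in `a`
#'   coordinates; negative when `b` hangs off the left end), `overlapLen`,
#'   and `identity`.
#' @examples
#' bestOverlap(strrep("ACGT", 20), paste0(strrep("ACGT", 10), "AAAA"))
#' @export
bestOverlap <- function(a, b, params = overlapParams()) {
  res <- cpp_best_overlap(toupper(as.character(a)), toupper(as.character(b)),
                          params@minOverlap, params@minIdentity)
  if (length(res) == 0L) NULL else res
}

# Majority-vote layout consensus. seqs: character vector; offsets: 1-based
# start of each member on the layout. Ties -> IUPAC ambiguity code; columns
# covered only by N get 'N' with depth 0.
.layoutConsensus <- function(seqs, offsets) {
  lens <- nchar(seqs)
  W <- max(offsets + lens - 1L)
  counts <- matrix(0L, nrow = 4L, ncol = W,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- offsets[i]:(offsets[i] + lens[i] - 1L)
    ok <- ch != "N"
    if (any(ok)) {
      # one member touches each cell at most once, so vectorised += is safe
      idx <- cbind(match(ch[ok], c("A", "C", "G", "T")), pos[ok])
      counts[idx] <- counts[idx] + 1L
    }
  }
  depth <- colSums(counts)
  mx <- apply(counts, 2, max)
  base <- character(W)
  simple <- depth > 0L & colSums(counts == rep(mx, each = 4L) & counts > 0L) == 1L
  if (any(simple))
    base[simple] <- rownames(counts)[apply(counts[, simple, drop = FALSE],
                                           2, which.max)]
  tied <- which(depth > 0L & !simple)
  if (length(tied)) {
    letters <- vapply(tied, function(j) {
      paste(sort(rownames(counts)[counts[, j] == mx[j]]), collapse = "")
    }, character(1))
    base[tied] <- as.character(Biostrings::mergeIUPACLetters(letters))
  }
  base[depth == 0L] <- "N"
  list(sequence = paste(base, collapse = ""), depth = as.integer(depth))
}

# Faster column accumulation for error-free member stacks would be possible,
# but cluster sizes here are tens of reads at most.

#' Compute the majority-vote consensus of one read cluster
#'
#' Column-wise majority over the member bases (`N` excluded from voting);
#' ties produce the IUPAC ambiguity code of the tied bases. Depth is the
#' number of non-N member bases covering each column.
#'
#' @param members data.frame with columns `id` and `offset` (1-based layout
#'   start of each member).
#' @param reads named [Biostrings::DNAStringSet] or character vector
#'   containing (at least) the member reads.
#' @return list with `sequence` (character) and `depth` (integer vector).
#' @export
clusterConsensus <- function(members, reads) {
  stopifnot(all(c("id", "offset") %in% names(members)),
            all(members$id %in% names(reads)))
  if (min(members$offset) < 1L)
    stop("inconsistent cluster layout: offsets must be >= 1")
  seqs <- as.character(reads[members$id])
  .layoutConsensus(unname(seqs), members$offset)
}

# Internal greedy agglomeration. Returns list of clusters, each
# list(members = data.frame(id, offset), consensus, depth).
.greedyCluster <- function(reads, params) {
  ids <- names(reads)
  seqs <- as.character(reads)
  ord <- order(-nchar(seqs), ids, method = "radix")
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      bo <- cpp_best_overlap(clusters[[ci]]$consensus, seqs[i],
                             params@minOverlap, params@minIdentity)
      if (length(bo)) {
        cl <- clusters[[ci]]
        off <- bo$offset + 1L                 # 1-based on current layout
        shift <- max(0L, 1L - off)
        cl$members$offset <- cl$members$offset + shift
        cl$members <- rbind(cl$members,
                            data.frame(id = ids[i], offset = off + shift))
        cons <- .layoutConsensus(seqs[cl$members$id], cl$members$offset)
        cl$consensus <- cons$sequence; cl$depth <- cons$depth
        clusters[[ci]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        members = data.frame(id = ids[i], offset = 1L),
        consensus = seqs[i], depth = rep(1L, nchar(seqs[i])))
    }
  }
  # merge phase on cluster consensi until fixed point
  repeat {
    merged <- FALSE
    nc <- length(clusters)
    if (nc < 2L) break
    for (ci in seq_len(nc - 1L)) {
      for (cj in (ci + 1L):nc) {
        bo <- cpp_best_overlap(clusters[[ci]]$consensus,
                               clusters[[cj]]$consensus,
                               params@minOverlap, params@minIdentity)
        if (length(bo)) {
          a <- clusters[[ci]]; b <- clusters[[cj]]
          off <- bo$offset
          shift <- max(0L, -off)
          a$members$offset <- a$members$offset + shift
          b$members$offset <- b$members$offset + off + shift
          a$members <- rbind(a$members, b$members)
          cons <- .layoutConsensus(seqs[a$members$id], a$members$offset)
          a$consensus <- cons$sequence; a$depth <- cons$depth
          clusters[[ci]] <- a
          clusters[[cj]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}

#' Greedy overlap clustering of reads
#'
#' Reads are processed in deterministic order (descending length, then
#' lexicographic id, C collation). Each read is placed into the first
#' existing cluster whose current consensus yields a qualifying
#' [bestOverlap()], at the returned offset; otherwise it seeds a new
#' cluster. After one pass, cluster consensi are repeatedly merged until no
#' pair qualifies. Every read ends up in exactly one cluster.
#'
#' @param reads named [Biostrings::DNAStringSet] or character vector of
#'   deduplicated reads.
#' @param params an [OverlapParams-class].
#' @return A named list of data.frames, one per cluster, with columns `id`
#'   and `offset` (1-based member start on the cluster layout).
#' @export
clusterReads <- function(reads, params = overlapParams()) {
  if (length(reads) == 0L) return(list())
  cl <- .greedyCluster(reads, params)
  out <- lapply(cl, `[[`, "members")
  names(out) <- sprintf("cluster%03d", seq_along(out))
  out
}

#' Assemble reads into consensus sequences
#'
#' Runs [clusterReads()] and [clusterConsensus()] in one step.
#'
#' @inheritParams clusterReads
#' @param prefix consensus id prefix (default `"SL"`), yielding ids like
#'   `SL.001`.
#' @return An [SLConsensusSet-class].
#' @export
assembleReads <- function(reads, params = overlapParams(), prefix = "SL") {
  if (length(reads) == 0L)
    return(new("SLConsensusSet", sequences = Biostrings::DNAStringSet(),
               depth = list(), members = list()))
  cl <- .greedyCluster(reads, params)
  ids <- sprintf("%s.%03d", prefix, seq_along(cl))
  seqs <- Biostrings::DNAStringSet(vapply(cl, `[[`, character(1), "consensus"))
  names(seqs) <- ids
  new("SLConsensusSet", sequences = seqs,
      depth = lapply(cl, `[[`, "depth"),
      members = lapply(cl, `[[`, "members"))
}
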