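test_that("bestOverlap finds the constructed suffix-prefix placement", {
  set.seed(21)
  a <- randSeq(60)
  b <- paste0(substr(a, 21, 60), randSeq(20))
  bo <- bestOverlap(a, b)
  expect_equal(bo$offset, 20L)
  expect_equal(bo$overlapLen, 40L)
  expect_equal(bo$identity, 1)
})

test_that("identity thresholding is exact arithmetic on the overlap", {
  set.seed(22)
  a <- randSeq(40)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  }
  b1 <- mut(a, 1)                       # 39/40 = 0.975 >= 0.95
  bo <- bestOverlap(a, b1)
  expect_equal(bo$identity, 0.975)
  b3 <- mut(a, 3)                       # 37/40 = 0.925 < 0.95
  # guard against a shifted placement scoring better by chance
  expect_true(is.null(bestOverlap(a, b3)) ||
                bestOverlap(a, b3)$overlapLen < 40)

  # a perfect overlap below the length floor is rejected
  short <- paste0(substr(a, 16, 40), randSeq(30))  # 25 shared columns
  expect_null(bestOverlap(a, short))
})

test_that("bestOverlap agrees with the exhaustive enumeration oracle", {
  set.seed(23)
  params <- overlapParams()
  for (i in 1:60) {
    la <- sample(30:80, 1); lb <- sample(30:80, 1)
    if (i %% 2 == 0) {                 # related pair: shared block
      core <- randSeq(sample(25:50, 1))
      a <- paste0(randSeq(la), core)
      b <- paste0(core, randSeq(lb))
    } else {
      a <- randSeq(la); b <- randSeq(lb)
    }
    got <- bestOverlap(a, b, params)
    want <- oracleBestOverlap(a, b, params@minOverlap, params@minIdentity)
    expect_identical(is.null(got), is.null(want), info = paste("pair", i))
    if (!is.null(got)) {
      expect_equal(got$offset, want$offset, info = paste("pair", i))
      expect_equal(got$overlapLen, want$overlapLen)
      expect_equal(got$identity, want$identity)
    }
  }
})

test_that("N columns never count as matches", {
  set.seed(28)
  a <- randSeq(40)
  b <- a
  substr(b, 11, 14) <- "NNNN"
  bo <- bestOverlap(a, b, overlapParams(minOverlap = 30, minIdentity = 0.8))
  expect_equal(bo$offset, 0L)
  expect_equal(bo$identity, 36 / 40)
  # at the default 95% threshold the N-laden placement no longer qualifies
  expect_null(bestOverlap(a, b))
})

test_that("reads tiling one locus form a single cluster", {
  set.seed(24)
  locus <- randSeq(150)
  reads <- Biostrings::DNAStringSet(c(
    r1 = substr(locus, 1, 70), r2 = substr(locus, 31, 100),
    r3 = substr(locus, 61, 150)))
  cl <- clusterReads(reads)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$id, c("r1", "r2", "r3"))

  cons <- clusterConsensus(cl[[1]], reads)
  expect_identical(cons$sequence, locus)
  expect_equal(length(cons$depth), 150L)
})

test_that("loci sharing only the 21-nt SL stay in separate clusters", {
  set.seed(25)
  m <- slMotifs()
  reads <- Biostrings::DNAStringSet(c(
    a = paste0(randSeq(40), m@sl, randSeq(39)),
    b = paste0(randSeq(40), m@sl, randSeq(39))))
  expect_length(clusterReads(reads), 2L)
})

test_that("a single read forms a singleton cluster equal to itself", {
  r <- Biostrings::DNAStringSet(c(solo = strrep("ACGGT", 12)))
  cons <- assembleReads(r)
  expect_equal(length(cons), 1L)
  expect_identical(as.character(consensusSequences(cons))[[1]],
                   as.character(r)[[1]])
  expect_true(all(consensusDepth(cons)[[1]] == 1L))
})

test_that("majority vote resolves columns and ties become IUPAC codes", {
  reads <- Biostrings::DNAStringSet(c(x = "AAG", y = "AAG", z = "GAG"))
  members <- data.frame(id = c("x", "y", "z"), offset = 1L)
  cons <- clusterConsensus(members, reads)
  expect_identical(cons$sequence, "AAG")   # {A,A,G} -> A
  expect_equal(cons$depth, c(3L, 3L, 3L))

  two <- clusterConsensus(data.frame(id = c("x", "z"), offset = 1L), reads)
  expect_identical(substr(two$sequence, 1, 1), "R")  # {A,G} -> R
  # N is excluded from voting and from depth
  nr <- Biostrings::DNAStringSet(c(p = "ANG", q = "AAG"))
  nc <- clusterConsensus(data.frame(id = c("p", "q"), offset = 1L), nr)
  expect_identical(nc$sequence, "AAG")
  expect_equal(nc$depth, c(2L, 1L, 2L))
})

test_that("every read lands in exactly one cluster (partition property)", {
  set.seed(26)
  m <- slMotifs()
  loci <- vapply(1:4, function(i)
    paste0(randSeq(30), m@sl, randSeq(70)), "")
  reads <- unlist(lapply(seq_along(loci), function(i) {
    starts <- seq(1, nchar(loci[i]) - 59, by = 15)
    stats::setNames(substring(loci[i], starts, starts + 59),
                    sprintf("L%d_r%02d", i, seq_along(starts)))
  }))
  reads <- Biostrings::DNAStringSet(reads)
  cons <- assembleReads(reads)
  got <- unlist(lapply(clusterMembers(cons), `[[`, "id"))
  expect_setequal(got, names(reads))
  expect_equal(length(got), length(reads))
  expect_equal(length(cons), 4L)
})

test_that("error-free tiling reads reproduce the locus consensus exactly", {
  set.seed(27)
  locus <- randSeq(140)
  starts <- c(1, seq(5, 41, by = 4))    # 10 reads, depth >= 8 over core
  reads <- Biostrings::DNAStringSet(
    stats::setNames(substring(locus, starts, starts + 99),
                    sprintf("r%02d", seq_along(starts))))
  cons <- assembleReads(reads)
  expect_equal(length(cons), 1L)
  expect_identical(as.character(consensusSequences(cons))[[1]],
                   substr(locus, 1, max(starts) + 99))
})
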