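motifs <- slMotifs()
SL <- motifs@sl
REL <- motifs@relict
VAR <- motifs@variant

test_that("unit scanning calls FULL, VARIANT and RELICT units as placed", {
  m <- scanSequence(paste0("AAAA", SL, "AAAA"), motifs)
  expect_equal(scanAsDf(m),
               data.frame(pos = 5L, kind = "FULL", len = 21L))

  tandem <- scanSequence(paste0(SL, SL), motifs)
  expect_identical(as.character(S4Vectors::mcols(tandem)$kind),
                   c("FULL", "FULL"))

  mix <- scanSequence(paste0(SL, REL), motifs)
  expect_identical(as.character(S4Vectors::mcols(mix)$kind),
                   c("FULL", "RELICT"))

  v <- scanSequence(VAR, motifs)
  expect_equal(scanAsDf(v), data.frame(pos = 1L, kind = "VARIANT",
                                       len = 21L))
  # the variant is the canonical SL with its first base C -> T
  expect_identical(substr(VAR, 2, 21), substr(SL, 2, 21))
})

test_that("the relict embedded in each full SL is not double-counted", {
  # the relict is a suffix of the SL, so a lone SL must yield exactly one
  # unit even though a relict placement exists inside it
  m <- scanSequence(SL, motifs)
  expect_equal(length(m), 1L)
  expect_identical(as.character(S4Vectors::mcols(m)$kind), "FULL")
})

test_that("scan spans stay in bounds, never overlap, and match exactly", {
  set.seed(31)
  for (i in 1:25) {
    s <- paste0(randSeq(sample(0:30, 1)), SL,
                randSeq(sample(0:10, 1)),
                sample(c(SL, REL, VAR), 1), randSeq(sample(0:30, 1)))
    m <- scanSequence(s, motifs)
    expect_gte(min(IRanges::start(m)), 1L)
    expect_lte(max(IRanges::end(m)), nchar(s))
    if (length(m) > 1L)
      expect_true(all(IRanges::start(m)[-1] >
                        IRanges::end(m)[-length(m)]))
    full <- which(S4Vectors::mcols(m)$kind == "FULL")
    for (j in full)
      expect_identical(substr(s, IRanges::start(m)[j], IRanges::end(m)[j]),
                       SL)
  }
})

test_that("mismatch tolerance applies to FULL units only", {
  mut <- SL
  substr(mut, 10, 10) <- "A"
  expect_equal(length(scanSequence(mut, motifs)), 0L)
  lax <- slMotifs(maxMismatches = 1L)
  m <- scanSequence(mut, lax)
  expect_equal(scanAsDf(m), data.frame(pos = 1L, kind = "FULL", len = 21L))
  expect_equal(S4Vectors::mcols(m)$mismatches, 1L)
  # N never matches, even with tolerance exhausted elsewhere
  nmut <- SL
  substr(nmut, 10, 11) <- "NN"
  expect_equal(length(scanSequence(nmut, lax)), 0L)
})

test_that("SL read selection partitions reads and counts FULL units", {
  set.seed(8)
  reads <- Biostrings::DNAStringSet(c(
    one = paste0(randSeq(20), SL, randSeq(30)),
    two = paste0(randSeq(10), SL, SL, randSeq(20)),
    none = randSeq(80),
    mixed = paste0(SL, REL, REL, randSeq(15)),
    like = paste0(randSeq(12), VAR, REL, randSeq(25)),
    lone_relict = paste0(randSeq(30), REL, randSeq(30))))
  sel <- selectSLReads(reads, motifs)
  expect_setequal(names(sel$slReads), c("one", "two", "mixed"))
  # reads with one FULL (plus any relicts) count under key "1"
  expect_equal(sel$histogram, c(`1` = 2L, `2` = 1L))
  expect_identical(names(sel$slLikeReads), "like")
})

test_that("random uniform reads essentially never contain the 21-nt SL", {
  set.seed(99)
  reads <- Biostrings::DNAStringSet(
    stats::setNames(vapply(1:1000, function(i) randSeq(100), ""),
                    paste0("r", 1:1000)))
  sel <- selectSLReads(reads, motifs)
  # analytic expectation 1000 * 80 * 4^-21 ~ 2e-8
  expect_equal(length(sel$slReads), 0L)
  expect_equal(length(sel$slLikeReads), 0L)
})

test_that("motif occurrence counting includes overlaps and edge cases", {
  expect_equal(countMotifOccurrences("AAAA", "AA"), 3L)
  expect_equal(countMotifOccurrences(SL, REL), 1L)
  expect_equal(countMotifOccurrences("ACG", "ACGT"), 0L)
  expect_equal(countMotifOccurrences("ANAA", "AA"), 1L)
})
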