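test_that("planted loci scan back to exactly their declared structure", {
  set.seed(61)
  cfg <- simConfig(seed = 61L)
  m <- slMotifs()
  pool <- new.env()
  single <- makeLocus("SINGLE_SL", cfg, m, locusId = "s1", seqPool = pool)
  tandem <- makeLocus("TANDEM_SL", cfg, m, nUnits = 3L, locusId = "t1",
                      seqPool = pool)
  like <- makeLocus("SL_LIKE", cfg, m, nUnits = 2L, locusId = "p1",
                    seqPool = pool)
  for (locus in list(single, tandem, like)) {
    sc <- scanSequence(locus$sequence, m)
    k <- table(factor(S4Vectors::mcols(sc)$kind,
                      c("FULL", "RELICT", "VARIANT")))
    expect_equal(unname(k[["FULL"]]), locus$n_full)
    expect_equal(unname(k[["RELICT"]]), locus$n_relict)
    expect_equal(unname(k[["VARIANT"]]), locus$n_variant)
    expect_equal(nchar(locus$sequence), locus$total_len)
    expect_lte(locus$total_len, 292L)
    expect_gte(locus$total_len, 103L - 10L)  # SL-like may sit slightly lower
  }
  # SL loci carry a splice donor; SL-like loci must not
  call <- classifyConsensus(single$sequence, m, "s1")
  expect_true(donorCheck(call)[["s1"]])
  callLike <- classifyConsensus(like$sequence, m, "p1")
  expect_false(donorCheck(callLike)[["p1"]])
  # the planted Sm-motif is present in the SL intron, absent from SL-like
  expect_gte(countMotifOccurrences(call$downstream_seq, "GTTTTC"), 1L)
})

test_that("locus generation is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 62L)
  set.seed(cfg@seed); a <- simulateLoci(cfg)
  set.seed(cfg@seed); b <- simulateLoci(cfg)
  expect_identical(a, b)
})

test_that("generated loci honour the cross-locus separability screen", {
  set.seed(63)
  loci <- simulateLoci(simConfig(nSingle = 4L, nTandem2 = 1L,
                                 nTandem3 = 1L, nSLLike = 4L, seed = 63L))
  for (i in seq_len(nrow(loci) - 1L))
    for (j in (i + 1L):nrow(loci))
      expect_null(bestOverlap(loci$sequence[i], loci$sequence[j]),
                  info = paste(loci$locus_id[i], loci$locus_id[j]))
})

test_that("error-free R2 reads are sense-strand substrings of their locus", {
  cfg <- smallConfig(seed = 64L)
  set.seed(cfg@seed)
  loci <- simulateLoci(cfg)
  reads <- simulateReads(loci, cfg)
  expect_equal(length(reads$r1), length(reads$r2))
  expect_identical(names(reads$r1), names(reads$r2))
  truth <- reads$truth
  fromLocus <- truth$locus_id != "background"
  for (i in which(fromLocus)[1:50]) {
    locus <- loci$sequence[loci$locus_id == truth$locus_id[i]]
    r2 <- as.character(reads$r2[[i]])
    expect_true(grepl(r2, locus, fixed = TRUE))
    # R1 is the reverse complement of the fragment 3' end
    r1rc <- as.character(Biostrings::reverseComplement(reads$r1[[i]]))
    expect_true(grepl(r1rc, locus, fixed = TRUE))
  }
})

test_that("the strand contract puts the SL in R2 and its rc in R1", {
  cfg <- smallConfig(seed = 65L)
  set.seed(cfg@seed)
  loci <- simulateLoci(cfg)
  reads <- simulateReads(loci, cfg)
  m <- slMotifs()
  slrc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(m@sl)))
  r2hits <- sum(Biostrings::vcountPattern(m@sl, reads$r2) > 0)
  r1hits <- sum(Biostrings::vcountPattern(slrc, reads$r1) > 0)
  expect_gt(r2hits, 0)
  expect_gt(r1hits, 0)
  # and never the other orientation in an error-free library
  expect_equal(sum(Biostrings::vcountPattern(slrc, reads$r2) > 0), 0)
  expect_equal(sum(Biostrings::vcountPattern(m@sl, reads$r1) > 0), 0)
})

test_that("surplus depth plants exact duplicates that dedup removes", {
  cfg <- simConfig(nSingle = 2L, nTandem2 = 0L, nTandem3 = 0L,
                   nSLLike = 0L, depth = 40L, errorRate = 0,
                   backgroundReads = 0L, seed = 66L)
  set.seed(cfg@seed)
  loci <- simulateLoci(cfg)
  reads <- simulateReads(loci, cfg)
  d <- dedupReads(reads$r2)
  expect_gt(d$nRemoved, 0L)
  # survivors are exactly the distinct fragment phases
  expect_equal(length(d$reads),
               length(unique(paste(reads$truth$locus_id,
                                   reads$truth$start))))
})

test_that("a simulated library is byte-identical under the same seed", {
  cfg <- simConfig(nSingle = 2L, nTandem2 = 1L, nTandem3 = 0L,
                   nSLLike = 1L, depth = 8L, backgroundReads = 30L,
                   seed = 67L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateSLLibrary(cfg, dir = d1)
  s2 <- simulateSLLibrary(cfg, dir = d2)
  for (f in c("r1", "r2", "truthReads", "truthLoci"))
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     info = f)
})
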