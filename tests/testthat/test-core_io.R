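test_that("paired FASTQ reading strips mate suffixes and keeps order", {
  d <- withr::local_tempdir()
  set.seed(1)
  seqs <- stats::setNames(vapply(1:3, function(i) randSeq(50), ""),
                          paste0("read", 1:3, " comment text"))
  f1 <- writeTestFastq(seqs, file.path(d, "r1.fastq"))
  f2 <- writeTestFastq(seqs, file.path(d, "r2.fastq"))
  p <- readFastqPairs(f1, f2, libraryId = "libA")
  expect_s4_class(p, "StrandedReadPairs")
  expect_equal(length(p), 3L)
  expect_identical(names(p@r2), paste0("read", 1:3))
  expect_identical(p@mates, c("R1", "R2"))
  expect_identical(unname(as.character(p@r2)), unname(seqs))

  # /1 and /2 suffixes are stripped to a common id
  seqs2 <- stats::setNames(c("ACGTN"), "x")
  g1 <- writeTestFastq(seqs2, file.path(d, "s1.fastq"), suffix = "/1")
  g2 <- writeTestFastq(seqs2, file.path(d, "s2.fastq"), suffix = "/2")
  q <- readFastqPairs(g1, g2)
  expect_identical(names(q@r1), "x")
  expect_identical(names(q@r2), "x")
})

test_that("empty FASTQ files yield an empty library without error", {
  f <- withr::local_tempfile(fileext = ".fastq")
  file.create(f)
  p <- readFastqPairs(pathR2 = f)
  expect_equal(length(p), 0L)
  expect_equal(length(senseReads(p)), 0L)
})

test_that("mismatched pair counts fail naming the record index", {
  d <- withr::local_tempdir()
  f1 <- writeTestFastq(c(a = "ACGTACGT", b = "ACGTACGA"),
                       file.path(d, "r1.fastq"))
  f2 <- writeTestFastq(c(a = "ACGTACGT"), file.path(d, "r2.fastq"))
  expect_error(readFastqPairs(f1, f2), "record index 2")
  # same count but shuffled ids is also a pairing error
  f3 <- writeTestFastq(c(b = "ACGTACGT", a = "ACGTACGA"),
                       file.path(d, "r3.fastq"))
  expect_error(readFastqPairs(f1, f3), "record 1")
})

test_that("sense-strand selection follows the library convention verbatim", {
  d <- withr::local_tempdir()
  f1 <- writeTestFastq(c(x = "AAAACCCC"), file.path(d, "r1.fastq"))
  f2 <- writeTestFastq(c(x = "GGGGTTTT"), file.path(d, "r2.fastq"))
  p <- readFastqPairs(f1, f2)
  expect_identical(as.character(senseReads(p, "R2")), c(x = "GGGGTTTT"))
  expect_identical(as.character(senseReads(p, "R1")), c(x = "AAAACCCC"))
  # the antisense mate must never be reverse-complemented in
  single <- readFastqPairs(pathR2 = f2)
  expect_error(senseReads(single, "R1"), "sense mate missing")
})

test_that("dedup keeps first occurrences, preserves order, is idempotent", {
  r <- Biostrings::DNAStringSet(c(a = "AAAA", b = "AAAA", c = "CCCC"))
  d <- dedupReads(r)
  expect_identical(names(d$reads), c("a", "c"))
  expect_equal(d$nRemoved, 1L)

  distinct <- Biostrings::DNAStringSet(c(a = "AAAA", b = "CCCC"))
  expect_equal(dedupReads(distinct)$nRemoved, 0L)

  set.seed(5)
  base <- vapply(1:70, function(i) randSeq(40), "")
  dups <- sample(base, 30, replace = TRUE)
  reads <- Biostrings::DNAStringSet(
    stats::setNames(sample(c(base, dups)), paste0("r", 1:100)))
  d1 <- dedupReads(reads)
  expect_equal(length(d1$reads), length(unique(as.character(reads))))
  d2 <- dedupReads(d1$reads)
  expect_identical(as.character(d2$reads), as.character(d1$reads))
  expect_equal(d2$nRemoved, 0L)
})

test_that("FASTA round-trips byte-exactly and the locus table is stable", {
  d <- withr::local_tempdir()
  set.seed(2)
  x <- stats::setNames(vapply(1:4, function(i) randSeq(80), ""),
                       paste0("cons", 1:4))
  fa <- writeFasta(x, file.path(d, "out.fasta"))
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(stats::setNames(as.character(back), names(back)), x)

  tsv <- file.path(d, "empty.tsv")
  writeLocusTable(data.frame(), tsv)
  lines <- readLines(tsv)
  expect_length(lines, 1L)
  expect_match(lines, "^consensus_id\tgene_class\t")
})

test_that("GFF output is 1-based with the unit span as called", {
  d <- withr::local_tempdir()
  m <- slMotifs()
  cons <- paste0(strrep("A", 10), m@sl, strrep("C", 20))
  gff <- file.path(d, "units.gff3")
  writeGff(scanSequences(c(locusA = cons)), gff)
  rows <- grep("^[^#]", readLines(gff), value = TRUE)
  expect_length(rows, 1L)
  f <- strsplit(rows, "\t")[[1]]
  expect_identical(f[1], "locusA")
  expect_equal(as.integer(f[4]), 11L)  # unit at 0-based offset 10
  expect_equal(as.integer(f[5]), 31L)
})
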