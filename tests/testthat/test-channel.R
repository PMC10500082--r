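# Channel simulator: error injection, quality emission, sampling, filtering.

test_that("a noiseless channel returns the pool verbatim", {
  p0 <- channelParams(subRate = 0, insRate = 0, delRate = 0,
                      artifactRate = 0)
  oligos <- vapply(1:20, function(i) randomDNA(152, seed = i), "")
  cr <- corruptOligos(oligos, p0, seed = 1)
  expect_identical(cr$seq, oligos)
  expect_true(all(nchar(cr$qual) == 152L))
})

test_that("degenerate rates behave as specified", {
  oligo <- randomDNA(152, seed = 9)
  allDel <- channelParams(subRate = 0, insRate = 0, delRate = 1,
                          artifactRate = 0)
  cr <- corruptOligos(oligo, allDel, seed = 1)
  expect_identical(nchar(cr$seq), 0L)
})

test_that("observed substitution frequency matches the configured rate", {
  oligo <- randomDNA(152, seed = 10)
  pSub <- channelParams(subRate = 0.01, insRate = 0, delRate = 0,
                        artifactRate = 0, lastBaseMultiplier = 1)
  cr <- corruptOligos(rep(oligo, 10000), pSub, seed = 2)
  src <- strsplit(oligo, "")[[1]]
  obs <- vapply(strsplit(cr$seq, ""), function(s) sum(s != src), 0L)
  nBases <- 10000 * 152
  phat <- sum(obs) / nBases
  expect_lt(abs(phat - 0.01), 3 * sqrt(0.01 * 0.99 / nBases))
})

test_that("sampling is deterministic, linked to ground truth, and exhibits
           occupancy-law dropout", {
  codec <- smallCodec()
  pool <- encodeFile(randomBytes(2000, 11), codec)
  p0 <- channelParams(subRate = 0, insRate = 0, delRate = 0,
                      artifactRate = 0)
  r1 <- sampleReads(pool, 500, p0, seed = 21)
  r2 <- sampleReads(pool, 500, p0, seed = 21)
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(S4Vectors::mcols(r1)$sourceOrdinal,
                   S4Vectors::mcols(r2)$sourceOrdinal)
  # with zero errors every read RS-decodes to its source ordinal
  cl <- indexCluster(r1, codec)
  expect_true(all(cl$status == "ok"))
  expect_identical(cl$ordinal - 1L, S4Vectors::mcols(r1)$sourceOrdinal)
  # unseen-oligo count close to the occupancy formula n(1 - 1/n)^N
  nOligo <- 256; N <- 200
  unseen <- vapply(1:30, function(i) {
    r <- sampleReads(pool, N, p0, seed = 1000 + i)
    nOligo - length(unique(S4Vectors::mcols(r)$sourceOrdinal))
  }, 0)
  expected <- nOligo * (1 - 1 / nOligo)^N
  sdOne <- sqrt(nOligo * (1 - 1 / nOligo)^N *
                  (1 - (1 - 1 / nOligo)^N)) # binomial-style bound
  expect_lt(abs(mean(unseen) - expected), 3 * sdOne / sqrt(30))
  expect_identical(length(sampleReads(pool, 0, p0, seed = 1)), 0L)
})

test_that("the default channel meets the merged-Illumina calibration bands", {
  codec <- smallCodec()
  pool <- encodeFile(randomBytes(2000, 12), codec)
  reads <- sampleReads(pool, 100000, channelParams(), seed = 31)
  w <- Biostrings::width(reads)
  frac152 <- mean(w == 152)
  expect_gte(frac152, 0.91)
  expect_lte(frac152, 0.95)
  fracVL <- mean(w %in% c(150, 151))
  expect_gt(fracVL, 0.005) # shortened reads present at the ~1.3% scale
  expect_lt(fracVL, 0.025)
  q <- utf8ToInt(paste(as.character(Biostrings::quality(reads)),
                       collapse = "")) - 33L
  q30 <- mean(q >= 30)
  expect_gte(q30, 0.94)
  expect_lte(q30, 0.98)
})

test_that("the length filter keeps exactly the usable lengths", {
  reads <- makeReads(c(strrep("A", 149), strrep("C", 150), strrep("G", 151),
                       strrep("T", 152), strrep("A", 153)))
  kept <- lengthFilter(reads)
  expect_identical(nchar(kept$seq), c(150L, 151L, 152L))
  expect_equal(attr(kept, "keptFraction"), 3 / 5)
  clean <- makeReads(rep(strrep("A", 152), 4))
  expect_equal(attr(lengthFilter(clean), "keptFraction"), 1)
  vlOff <- lengthFilter(reads, keep = 152L)
  expect_identical(nchar(vlOff$seq), 152L)
})

test_that("FASTQ output round-trips reads and qualities", {
  codec <- smallCodec()
  pool <- encodeFile(randomBytes(500, 13), codec)
  reads <- sampleReads(pool, 50, channelParams(), seed = 41)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeReadsFastq(reads, fq)
  back <- readReadsFastq(fq)
  expect_identical(as.character(back), as.character(reads))
  expect_identical(as.character(Biostrings::quality(back)),
                   as.character(Biostrings::quality(reads)))
})
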