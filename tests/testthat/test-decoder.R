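# Clustering, eviction, routing, alignment, vote counting, LLRs,
# iterative re-decoding, finalization.

test_that("edit distance equals the brute-force recursion", {
  expect_identical(editDistance("GATTACA", "GATTACA"), 0L)
  expect_identical(editDistance("GATTACA", "GACTACA"), 1L)
  expect_identical(editDistance("ACGT", ""), 4L)
  withr::with_seed(1, {
    for (t in 1:60) {
      a <- randomDNA(sample(0:6, 1))
      b <- randomDNA(sample(0:6, 1))
      expect_identical(editDistance(a, b), levRecursive(a, b))
    }
  })
})

test_that("index clustering survives two-symbol index corruption", {
  codec <- smallCodec()
  pool <- as.character(encodeFile(randomBytes(2000, 2), codec))
  clean <- makeReads(pool[5])
  cl <- indexCluster(clean, codec)
  expect_identical(cl$ordinal, 5L)
  expect_identical(cl$status, "ok")
  # corrupt two full symbols (bases 1-2 and 9-10) of the index region
  s <- pool[5]
  sub <- chartr("ACGT", "CAAT", substr(s, 1, 2))
  s2 <- paste0(sub, substr(s, 3, 8), chartr("ACGT", "GGTC", substr(s, 9, 10)),
               substr(s, 11, 152))
  cl2 <- indexCluster(makeReads(s2), codec)
  expect_identical(cl2$ordinal, 5L)
  expect_identical(cl2$status, "corrected")
  # an unclusterable read (garbage index region) is discarded
  junk <- makeReads(paste0(strrep("ACGT", 4), substr(s, 17, 152)))
  clj <- indexCluster(junk, codec)
  expect_true(is.na(clj$ordinal) || clj$ordinal != 5L)
})

test_that("abnormal reads are evicted by the minimum-ED rule", {
  base <- randomDNA(152, seed = 3)
  far <- randomDNA(152, seed = 4)
  keep <- edFilter(c(base, base, base, far), dTh = 10)
  expect_identical(keep, c(TRUE, TRUE, TRUE, FALSE))
  # two reads at small mutual distance: both kept
  near <- paste0("TTT", substr(base, 4, 152))
  expect_identical(edFilter(c(base, near), dTh = 10), c(TRUE, TRUE))
  # two reads at mutual distance above the threshold: both fall
  expect_identical(edFilter(c(base, far), dTh = 10), c(FALSE, FALSE))
  expect_identical(edFilter(base, dTh = 10), TRUE) # singleton passes
})

test_that("clusters route to the six conditions correctly", {
  expect_identical(routeCluster(c(152L, 152L, 152L)), "direct")
  expect_identical(routeCluster(151L), "singleton_vl")
  expect_identical(routeCluster(c(152L, 151L)), "msa")
  expect_error(routeCluster(integer(0)), "empty")
})

test_that("singleton variable-length reads rescue only a confident last base", {
  r <- paste0(randomDNA(150, seed = 5), "T")
  v <- singletonVLVotes(r, 35)
  expect_identical(v$positions, c(271L, 272L))
  expect_identical(v$bits, c(1L, 1L)) # T = 11
  expect_null(singletonVLVotes(r, 30)) # strictly above 30
  r150 <- paste0(randomDNA(149, seed = 6), "A")
  v2 <- singletonVLVotes(r150, 40)
  expect_identical(v2$bits, c(0L, 0L)) # A = 00
})

test_that("center-star alignment recovers interior deletions", {
  s <- randomDNA(152, seed = 7)
  al <- msaAlign(c(s, s))
  expect_identical(al$L, 152L)
  expect_identical(al$rows, c(s, s))
  # one interior deletion: the shorter row gains exactly one gap
  short <- paste0(substr(s, 1, 79), substr(s, 81, 152))
  al2 <- msaAlign(c(s, short))
  expect_identical(al2$L, 152L)
  expect_identical(al2$rows[1], s)
  expect_identical(sum(strsplit(al2$rows[2], "")[[1]] == "-"), 1L)
  expect_identical(gsub("-", "", al2$rows[2]), short)
  # unrelated sequences still return a consistent alignment frame
  u <- msaAlign(c(randomDNA(152, seed = 8), randomDNA(150, seed = 9)))
  expect_true(all(nchar(u$rows) == u$L))
  expect_error(msaAlign("ACGT"), "at least two")
})

test_that("vote counting respects gaps and the last-two-bit quality gate", {
  codec <- smallCodec()
  pool <- as.character(encodeFile(randomBytes(2000, 10), codec))
  q38 <- phredChar(rep(38, 152))
  # four clean full-length reads of oligo 3: every position gets 4 votes
  reads <- makeReads(rep(pool[4], 4), rep(q38, 4))
  cnt <- accumulateCounts(reads, codec)
  expect_true(all(cnt$k0[4, ] + cnt$k1[4, ] == 4L))
  expect_true(all(cnt$ke[4, ] == 0L))
  expect_true(all(cnt$k0[-4, ] + cnt$k1[-4, ] == 0L))
  # bits voted match the encoded payload bits
  bits <- basesToBits(substr(pool[4], 17, 152))
  expect_identical(as.integer(cnt$k1[4, ] == 4L), bits)
  # a last-base Phred of 18 turns that read's last-two-bit votes to erasure
  qlow <- phredChar(c(rep(38, 151), 18))
  mixed <- makeReads(rep(pool[4], 4), c(rep(q38, 3), qlow))
  cm <- accumulateCounts(mixed, codec)
  expect_true(all(cm$k0[4, 1:270] + cm$k1[4, 1:270] == 4L))
  expect_true(all(cm$k0[4, 271:272] + cm$k1[4, 271:272] == 3L))
  expect_true(all(cm$ke[4, 271:272] == 1L))
  # without the quality gate all four votes count everywhere
  cq <- accumulateCounts(mixed, codec, useQscore = FALSE)
  expect_true(all(cq$k0[4, ] + cq$k1[4, ] == 4L))
  # an aligned gap votes erasure at the two bits of its position
  # a deletion aligns to one gap column, voting erasure at that base's two
  # bits (the exact column may shift within a repeat run)
  del40 <- paste0(substr(pool[4], 1, 39), substr(pool[4], 41, 152))
  vl <- makeReads(c(pool[4], del40), rep(q38, 2))
  cg <- accumulateCounts(vl, codec)
  gapBits <- which(cg$ke[4, ] == 1L)
  expect_identical(length(gapBits), 2L)
  base <- (gapBits[1] + 1L) %/% 2L
  expect_identical(gapBits, c(2L * base - 1L, 2L * base)) # one payload base
  expect_true(all(cg$k0[4, setdiff(1:272, gapBits)] +
                    cg$k1[4, setdiff(1:272, gapBits)] == 2L))
})

test_that("vote bookkeeping: k0 + k1 + ke equals contributing reads", {
  codec <- smallCodec()
  pool <- encodeFile(randomBytes(2000, 11), codec)
  reads <- sampleReads(pool, 700, channelParams(), seed = 12)
  cnt <- accumulateCounts(lengthFilter(reads), codec)
  tot <- cnt$k0 + cnt$k1 + cnt$ke
  expect_true(all(tot == matrix(cnt$contributors, nrow(tot), 272)))
  expect_true(all(cnt$ke >= 0L))
})

test_that("the LLR closed form and its schedule behave as specified", {
  expect_equal(computeLLR(2, 2, i = 0), 0)
  expect_equal(computeLLR(3, 0, i = 0), 3 * log(0.98 / 0.02))
  expect_equal(computeLLR(3, 0, i = 1), 3 * log(0.985 / 0.015))
  # |LLR| strictly increasing in the re-decode round for k0 != k1
  mags <- vapply(0:3, function(i) abs(computeLLR(0, 2, i = i)), 0)
  expect_true(all(diff(mags) > 0))
  expect_error(computeLLR(1, 0, i = 4), "exhausted")
  expect_error(computeLLR(1, 0, i = 0, epsilon0 = 0.6, epsilonEnd = 0),
               "exhausted")
})

test_that("re-decoding reprocesses only failed codewords and can rescue them", {
  code <- toyCode()
  info <- c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 0L)
  cw <- ldpcEncode(code, info)
  # fixture: vote margins that fail BP at eps = 0.02 but converge at 0.015
  d <- c(2, 0, -1, 1, 0, -1, -2, 0, 1, 1, 2, 0, 1, -2, 0, 1)
  expect_false(bpDecode(code, d * log(0.98 / 0.02), maxIter = 30)$converged)
  clean <- (1 - 2 * cw) * 3
  counts <- list(k0 = cbind(pmax(clean, 0), pmax(d, 0)),
                 k1 = cbind(pmax(-clean, 0), pmax(-d, 0)))
  rr <- iterativeRedecode(counts, code, maxIter = 30)
  expect_true(all(rr$converged))
  expect_identical(rr$redecodeRounds, 1L)
  expect_identical(rr$bits[, 1], cw) # the healthy codeword is untouched
  # epsilonEnd = epsilon0 allows a single pass only
  one <- iterativeRedecode(counts, code, epsilonEnd = 0.02, maxIter = 30)
  expect_identical(one$redecodeRounds, 0L)
  expect_identical(one$failedColumns, 2L)
  # noiseless counts converge with no re-decoding at all
  ok <- iterativeRedecode(list(k0 = cbind(pmax(clean, 0)),
                               k1 = cbind(pmax(-clean, 0))), code)
  expect_true(all(ok$converged))
  expect_identical(ok$redecodeRounds, 0L)
})

test_that("decoding round-trips files exactly and flags corruption", {
  codec <- smallCodec()
  p0 <- channelParams(subRate = 0, insRate = 0, delRate = 0,
                      artifactRate = 0)
  for (bytes in list(raw(0), randomBytes(3000, 13))) {
    pool <- encodeFile(bytes, codec)
    reads <- sampleReads(pool, 512, p0, seed = 14) # coverage 2
    res <- decodeReads(reads, codec)
    expect_true(res$success)
    expect_identical(res$bytes, bytes)
    expect_true(res$report$crcOK)
  }
  # a single flipped payload bit after decoding trips the CRC
  bytes <- randomBytes(3000, 13)
  mat <- LDPCStorage:::packPayload(bytes, codec)
  mat[1, 5] <- 1L - mat[1, 5]
  expect_false(LDPCStorage:::unpackPayload(mat, codec)$crcOK)
})

test_that("decoding a noisy corpus with variable-length reads succeeds", {
  codec <- smallCodec()
  bytes <- randomBytes(5000, 15)
  pool <- encodeFile(bytes, codec)
  reads <- sampleReads(pool, 1536, channelParams(), seed = 16) # coverage 6
  res <- decodeReads(reads, codec)
  expect_true(res$success)
  expect_identical(res$bytes, bytes)
  rpt <- res$report
  expect_lte(rpt$usedReads, rpt$keptReads)
  expect_lte(rpt$keptReads, rpt$totalReads)
  # every oligo is either routed through exactly one condition or an erasure
  expect_identical(sum(rpt$conditions[c("direct", "singleton", "msa")]) +
                     rpt$erasureSequences, 256L)
})

test_that("FASTQ-to-file decoding works through the sidecar interface", {
  codec <- smallCodec()
  bytes <- randomBytes(1200, 17)
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "pool.fasta")
  meta <- file.path(dir, "pool.json")
  pool <- encodeFile(bytes, codec, fastaOut = fasta, metaOut = meta)
  reads <- sampleReads(Biostrings::readDNAStringSet(fasta), 1024,
                       channelParams(), seed = 18)
  fq <- file.path(dir, "reads.fastq")
  writeReadsFastq(reads, fq)
  out <- file.path(dir, "recovered.bin")
  res <- decodeFile(fq, meta, out = out)
  expect_true(res$success)
  expect_identical(readBin(out, "raw", file.size(out)), bytes)
})
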