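# Randomization, base mapping, index generation, payload packing, assembly.

test_that("randomization is an involution with a balanced keystream", {
  withr::with_seed(1, b <- sample(0:1, 500, replace = TRUE))
  expect_identical(randomizeBits(randomizeBits(b, 77), 77), as.integer(b))
  ks <- randomizeBits(integer(100000), 77) # keystream prefix
  # ones fraction within 3 sigma of 1/2
  expect_lt(abs(mean(ks) - 0.5), 3 * 0.5 / sqrt(100000))
  expect_false(identical(randomizeBits(integer(64), 1),
                         randomizeBits(integer(64), 2)))
})

test_that("the 2-bit base map and its inverse agree", {
  expect_identical(bitsToBases(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L)), "ACGT")
  withr::with_seed(2, b <- sample(0:1, 272, replace = TRUE))
  s <- bitsToBases(b)
  expect_identical(nchar(s), 136L)
  expect_identical(basesToBits(s), as.integer(b))
  expect_error(bitsToBases(c(0L, 1L, 0L)), "even")
  expect_error(basesToBits("ACGN"), "invalid base")
})

test_that("index generation matches exhaustive and DP homopolymer counts", {
  # dynamic-programming count of 8-mers with no run above 3
  f <- c(4, 16, 64)
  for (nn in 4:8) f <- c(f, 3 * sum(f[(nn - 3):(nn - 1)]))
  # exhaustive enumeration, written independently of the generator
  alph <- c("A", "C", "G", "T")
  all8 <- do.call(paste0, rev(expand.grid(rep(list(alph), 8))[8:1]))
  maxRun <- function(s) max(rle(strsplit(s, "")[[1]])$lengths)
  hasRun4 <- grepl("A{4}|C{4}|G{4}|T{4}", all8)
  expect_identical(sum(!hasRun4), as.integer(f[8])) # 61,452 both ways
  idx <- generateIndices(18432)
  expect_identical(length(unique(idx)), 18432L)
  expect_true(all(!grepl("A{4}|C{4}|G{4}|T{4}", idx)))
  gc <- nchar(gsub("[AT]", "", idx))
  expect_true(all(gc >= 2 & gc <= 6))
  expect_false("AAAAGCGT" %in% idx) # run of four
  expect_identical(idx, generateIndices(18432)) # deterministic
})

test_that("payload packing fills capacity exactly and round-trips", {
  codec <- smallCodec()
  k <- payloadOligos(codec)
  maxBytes <- capacityBytes(codec)
  full <- packPayload(randomBytes(maxBytes, 3), codec)
  expect_identical(dim(full), c(k, 272L))
  expect_identical(length(full), k * 272L) # maximal file fills every bit
  expect_error(packPayload(randomBytes(maxBytes + 1, 3), codec),
               "capacity")
  empty <- packPayload(raw(0), codec)
  expect_identical(dim(empty), c(k, 272L))
  for (bytes in list(raw(0), randomBytes(1000, 4))) {
    up <- LDPCStorage:::unpackPayload(packPayload(bytes, codec), codec)
    expect_true(up$crcOK)
    expect_identical(up$bytes, bytes)
  }
})

test_that("inter-oligo encoding yields syndrome-free columns", {
  codec <- smallCodec()
  code <- codec@code
  zero <- interOligoEncode(matrix(0L, infoLength(code), 272), code)
  expect_true(all(zero == 0L))
  payload <- packPayload(randomBytes(2000, 5), codec)
  cm <- interOligoEncode(payload, code)
  expect_identical(nrow(cm) - nrow(payload), numChecks(code))
  expect_true(all(ldpcSyndrome(code, cm) == 0L))
  expect_error(interOligoEncode(payload[-1, ], code), "matrix must be")
})

test_that("assembled oligos carry a decodable RS-protected index", {
  codec <- smallCodec()
  cm <- interOligoEncode(packPayload(randomBytes(2000, 6), codec),
                         codec@code)
  pool <- assembleOligos(cm, codec)
  expect_true(all(Biostrings::width(pool) == 152L))
  flanked <- assembleOligos(cm, codec, withPrimers = TRUE)
  expect_true(all(Biostrings::width(flanked) == 199L))
  expect_true(all(startsWith(as.character(flanked),
                             "GTTCAGAGTTCTACAGTCCGACGATC")))
  expect_true(all(endsWith(as.character(flanked), "TGGAATTCTCGGGTGCCAAGG")))
  # the first 16 nt of every record RS-decode cleanly to the record's index
  first16 <- substr(as.character(pool), 1, 16)
  dec <- rsDecodeIndex(LDPCStorage:::indexToSymbols(first16))
  expect_true(all(dec$status == "ok"))
  expect_identical(LDPCStorage:::symbolsToBases(dec$info), codec@indices)
})

test_that("encoding is deterministic end to end", {
  codec <- smallCodec()
  bytes <- randomBytes(1500, 7)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  encodeFile(bytes, codec, fastaOut = f1)
  encodeFile(bytes, codec, fastaOut = f2)
  expect_identical(readLines(f1), readLines(f2))
  pool <- Biostrings::readDNAStringSet(f1)
  expect_identical(length(pool), 256L)
})
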