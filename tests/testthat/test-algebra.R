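# Finite-field arithmetic, the (8,4) RS index code, CRC-32.

test_that("GF(16) is a field: commutative, distributive, invertible", {
  g <- expand.grid(a = 0:15, b = 0:15, c = 0:15)
  expect_identical(gf16Mul(g$a, g$b), gf16Mul(g$b, g$a))
  expect_identical(gf16Mul(g$a, bitwXor(g$b, g$c)),
                   bitwXor(gf16Mul(g$a, g$b), gf16Mul(g$a, g$c)))
  nz <- 1:15
  expect_true(all(gf16Mul(nz, gf16Inv(nz)) == 1L))
  # multiplicative group has order 15: a^15 = 1 for every nonzero a
  p <- rep(1L, 15L)
  for (i in 1:15) p <- gf16Mul(p, nz)
  expect_true(all(p == 1L))
  # cross-check the table arithmetic against shift-and-reduce multiplication
  expect_identical(gf16Mul(g$a, g$b),
                   mapply(peasantMul, g$a, g$b, USE.NAMES = FALSE))
})

test_that("RS encoding is systematic and matches the interpolation oracle", {
  expect_identical(rsEncodeIndex(c(0, 0, 0, 0)), rep(0L, 8))
  expect_identical(rsEncodeIndex(c(1, 2, 3, 4)),
                   c(1L, 2L, 3L, 4L, 2L, 9L, 11L, 12L)) # frozen from oracle
  withr::with_seed(11, {
    for (t in 1:25) {
      info <- sample(0:15, 4, replace = TRUE)
      cw <- rsEncodeIndex(info)
      expect_identical(cw[1:4], as.integer(info))
      expect_identical(cw, rsOracle(as.integer(info)))
    }
  })
})

test_that("the index code is MDS with minimum distance 5", {
  d <- rsMinDistance()
  expect_identical(d, 5L)
  expect_identical(d, 8L - 4L + 1L) # Singleton bound met
  # a subcode restricted to one free info symbol keeps weight >= 5
  sub <- rsEncodeIndex(rbind(1:15, 0L, 0L, 0L))
  expect_true(all(colSums(sub != 0L) >= 5L))
})

test_that("bounded-distance decoding corrects <= 2 symbol errors", {
  withr::with_seed(3, {
    for (t in 1:10) {
      info <- sample(0:15, 4, replace = TRUE)
      cw <- rsEncodeIndex(info)
      clean <- rsDecodeIndex(cw)
      expect_identical(clean$status, "ok")
      expect_identical(clean$info, as.integer(info))
      # every 2-position, random-magnitude error pattern
      for (i in 1:7) for (j in (i + 1):8) {
        e <- integer(8)
        e[c(i, j)] <- sample(1:15, 2, replace = TRUE)
        dec <- rsDecodeIndex(bitwXor(cw, e))
        expect_identical(dec$status, "corrected")
        expect_identical(dec$info, as.integer(info))
      }
    }
  })
})

test_that("3-symbol corruptions never silently pass as guaranteed decoding", {
  all_cw <- allRSCodewords()
  withr::with_seed(4, {
    for (t in 1:20) {
      info <- sample(0:15, 4, replace = TRUE)
      cw <- rsEncodeIndex(info)
      pos <- sample(8, 3)
      e <- integer(8)
      e[pos] <- sample(1:15, 3, replace = TRUE)
      rx <- bitwXor(cw, e)
      dec <- rsDecodeIndex(rx)
      nn <- as.integer(min(colSums(all_cw != rx))) # brute-force nearest
      if (dec$status == "fail") {
        expect_gte(nn, 3L) # fails only when no codeword within radius 2
      } else {
        # returned codeword is a valid codeword within the decoding radius
        expect_lte(sum(dec$codeword != rx), 2L)
        expect_identical(nn, sum(dec$codeword != rx))
        expect_identical(rsEncodeIndex(dec$info), dec$codeword)
      }
    }
  })
})

test_that("CRC-32 matches the standard check value and detects bit flips", {
  expect_equal(crc32Bits(bytesToBits(charToRaw("123456789"))), 3421780262)
  withr::with_seed(5, {
    b <- sample(0:1, 40, replace = TRUE)
    tagged <- crc32Append(b)
    expect_length(tagged, 72L)
    expect_true(crc32Check(tagged))
    for (i in seq_along(tagged)) { # exhaustive single-bit flips
      flip <- tagged
      flip[i] <- 1L - flip[i]
      expect_false(crc32Check(flip))
    }
    # affine structure: crc(a + b) + crc(a) + crc(b) = crc(0) at fixed length
    asBits <- LDPCStorage:::uint32ToBits
    for (t in 1:10) {
      a <- sample(0:1, 64, replace = TRUE)
      bb <- sample(0:1, 64, replace = TRUE)
      lhs <- bitwXor(bitwXor(asBits(crc32Bits(bitwXor(a, bb))),
                             asBits(crc32Bits(a))),
                     asBits(crc32Bits(bb)))
      expect_identical(lhs, asBits(crc32Bits(integer(64))))
    }
  })
})

test_that("CRC round trip holds for arbitrary bit streams", {
  withr::with_seed(6, {
    for (len in c(1, 7, 8, 33, 256)) {
      b <- sample(0:1, len, replace = TRUE)
      expect_true(crc32Check(crc32Append(b)))
    }
  })
  expect_error(crc32Bits(integer(0)), "nonempty")
})
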