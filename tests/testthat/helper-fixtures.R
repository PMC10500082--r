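# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

# toy code small enough for exhaustive maximum-likelihood decoding
toyCode <- function() {
  if (is.null(.fixtures$toy))
    .fixtures$toy <- ldpcCode(16, 8, columnWeight = 2, seed = 1)
  .fixtures$toy
}

# small codec for fast end-to-end pipelines (256 oligos, rate ~0.81)
smallCodec <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- storageCodec(
      ldpcCode(256, 208, columnWeight = 3, seed = 5), prbsSeed = 99)
  .fixtures$small
}

# mid-size codec in the full design's rate regime (0.899), capacity > 50 KB
scaledCodec <- function() {
  if (is.null(.fixtures$scaled))
    .fixtures$scaled <- storageCodec(
      ldpcCode(2048, 1842, columnWeight = 4, seed = 11), prbsSeed = 17)
  .fixtures$scaled
}

randomBytes <- function(n, seed = 1) {
  withr::with_seed(seed, as.raw(sample(0:255, n, replace = TRUE)))
}

randomDNA <- function(len, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), len, TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# --- independent GF(16) oracle (russian-peasant multiplication, no tables) --
peasantMul <- function(a, b) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L)) r <- bitwXor(r, a)
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, 16L)) a <- bitwXor(a, 19L)
    b <- bitwShiftR(b, 1L)
  }
  r
}

peasantPow <- function(a, e) {
  r <- 1L
  for (i in seq_len(e)) r <- peasantMul(r, a)
  r
}

# Lagrange-interpolation systematic RS oracle: the codeword is the unique
# degree-<=3 polynomial through (alpha^0..alpha^3, info), evaluated at
# alpha^0..alpha^7.
rsOracle <- function(info) {
  pts <- vapply(0:7, function(e) peasantPow(2L, e), 0L)
  ev <- integer(8L)
  ev[1:4] <- info
  for (j in 5:8) {
    acc <- 0L
    for (i in 1:4) {
      num <- 1L; den <- 1L
      for (t in setdiff(1:4, i)) {
        num <- peasantMul(num, bitwXor(pts[j], pts[t]))
        den <- peasantMul(den, bitwXor(pts[i], pts[t]))
      }
      acc <- bitwXor(acc, peasantMul(info[i],
                                     peasantMul(num, peasantPow(den, 14L))))
    }
    ev[j] <- acc
  }
  ev
}

# all 65,536 RS codewords as an 8 x 65536 matrix (cached)
allRSCodewords <- function() {
  if (is.null(.fixtures$rsAll)) {
    v <- 0:65535
    info <- rbind(v %% 16L, (v %/% 16L) %% 16L,
                  (v %/% 256L) %% 16L, (v %/% 4096L) %% 16L)
    .fixtures$rsAll <- rsEncodeIndex(info)
  }
  .fixtures$rsAll
}

# plain-recursion Levenshtein oracle (exponential; tiny strings only)
levRecursive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(levRecursive(substr(a, 2, nchar(a)), b) + 1L,
      levRecursive(a, substr(b, 2, nchar(b))) + 1L,
      levRecursive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# exhaustive ML decoding on the toy code: codeword minimizing sum of
# llr[bit == 1] (LLR convention: positive favours 0); returns the hard
# decision and whether the minimizer is unique
mlDecodeToy <- function(code, llr) {
  if (is.null(.fixtures$toyCW)) {
    k <- infoLength(code)
    infos <- sapply(0:(2^k - 1), function(v) (v %/% 2^(0:(k - 1))) %% 2)
    .fixtures$toyCW <- ldpcEncode(code, infos)
  }
  cw <- .fixtures$toyCW
  cost <- colSums(cw * llr)
  best <- which(cost == min(cost))
  list(bits = cw[, best[1L]], unique = length(best) == 1L)
}

# reads as a plain list container accepted by the decoder
makeReads <- function(seq, qual = NULL) {
  if (is.null(qual)) qual <- vapply(nchar(seq), function(w)
    paste(rep(rawToChar(as.raw(33L + 38L)), w), collapse = ""), "")
  list(seq = seq, qual = qual)
}

phredChar <- function(q) rawToChar(as.raw(33L + as.integer(q)))
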